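test_that("angle_records computes one record per rail row and excludes choice rows", {
  target <- c(10, 40)
  feet <- rbind(
    cdo_projection("1:1", target),
    cdo_projection("4:1", target),
    cdo_projection("0:1", target)
  )
  df <- make_intake_df(
    species = "fly",
    treatment = c("rail", "rail", "rail", "choice", "choice"),
    rail = c("1:1", "4:1", "0:1", NA, NA),
    protein = c(feet[, 1], 9, 11),
    carbohydrate = c(feet[, 2], 39, 41)
  )
  rec <- angle_records(intake_dataset(df))
  expect_equal(nrow(rec), 3)
  # all rows sit at their CDO feet, so every deviation is zero
  expect_equal(rec$deviation_deg, rep(0, 3), tolerance = 1e-9)
  expect_equal(as.character(rec$position), rep("on", 3))
  expect_equal(attr(rec, "targets")$fly, c(nutrient_a = 10, nutrient_b = 40))
})

test_that("records coinciding with the target are dropped with a warning", {
  df <- make_intake_df(
    species = "fly", treatment = c("rail", "rail"),
    rail = c("1:4", "1:1"), protein = c(10, 25), carbohydrate = c(40, 25)
  )
  expect_warning(
    rec <- angle_records(intake_dataset(df), target = c(10, 40)),
    "dropped"
  )
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "dropped"), 1)
})

test_that("pooled cell-means interval matches the one-sample t oracle", {
  rec <- make_records("x", rep("1:1", 3), c(-10, 0, 10))
  est <- estimate_rail_deviations(rec)
  # closed form: sd 10, se 10/sqrt(3), t(2, .975)
  half <- qt(0.975, 2) * 10 / sqrt(3)
  expect_equal(est$mean_dev, 0, tolerance = 1e-12)
  expect_equal(est$lwr95, -half, tolerance = 1e-8)
  expect_equal(est$upr95, half, tolerance = 1e-8)
  expect_equal(round(half, 2), 24.84)
  expect_true(est$cdo_consistent)
  expect_equal(est$n, 3L)
})

test_that("pooled estimates agree with independent closed-form arithmetic", {
  set.seed(21)
  rails <- rep(c("1:4", "1:1", "4:1"), times = c(5, 7, 6))
  dev <- rnorm(length(rails), mean = rep(c(-3, 0, 4), times = c(5, 7, 6)), sd = 2)
  est <- estimate_rail_deviations(make_records("x", rails, dev))
  # oracle: cell means and pooled residual variance computed by hand
  means <- tapply(dev, rails, mean)
  resid2 <- sum((dev - means[rails])^2)
  dfres <- length(dev) - 3
  s2 <- resid2 / dfres
  for (r in names(means)) {
    i <- which(est$rail == r)
    nr <- sum(rails == r)
    half <- qt(0.975, dfres) * sqrt(s2 / nr)
    expect_equal(est$mean_dev[i], unname(means[r]), tolerance = 1e-8)
    expect_equal(est$lwr95[i], unname(means[r]) - half, tolerance = 1e-8)
    expect_equal(est$upr95[i], unname(means[r]) + half, tolerance = 1e-8)
  }
  # zero-variance rail in a zero-variance dataset: width 0
  flat <- suppressWarnings(
    estimate_rail_deviations(make_records("x", rep(c("1:1", "2:1"), each = 2), rep(c(3, 5), each = 2)))
  )
  expect_equal(flat$lwr95, flat$mean_dev)
  expect_equal(flat$upr95, flat$mean_dev)
})

test_that("per-rail (unpooled) intervals match t.test", {
  set.seed(8)
  dev <- rnorm(12)
  rails <- rep(c("1:2", "2:1"), each = 6)
  est <- estimate_rail_deviations(make_records("x", rails, dev), pooled = FALSE)
  for (r in unique(rails)) {
    tt <- t.test(dev[rails == r])
    i <- which(est$rail == r)
    expect_equal(est$lwr95[i], tt$conf.int[1], tolerance = 1e-10)
    expect_equal(est$upr95[i], tt$conf.int[2], tolerance = 1e-10)
  }
})

test_that("estimates are order-invariant and pool-shrink under duplication", {
  set.seed(31)
  rails <- rep(c("1:4", "1:1"), each = 100)
  dev <- rnorm(200, sd = 6)
  rec <- make_records("x", rails, dev)
  est <- estimate_rail_deviations(rec)
  perm <- sample(nrow(rec))
  expect_equal(
    estimate_rail_deviations(rec[perm, ])$mean_dev, est$mean_dev,
    tolerance = 1e-12
  )
  dup <- estimate_rail_deviations(rbind(rec, rec))
  expect_equal(dup$mean_dev, est$mean_dev, tolerance = 1e-12)
  # large n: interval half-width shrinks by ~ 1/sqrt(2)
  ratio <- (dup$upr95 - dup$lwr95) / (est$upr95 - est$lwr95)
  expect_equal(ratio, rep(1 / sqrt(2), 2), tolerance = 0.02)
})

test_that("single observation everywhere leaves no residual df and errors", {
  rec <- make_records("x", c("1:1", "1:2"), c(1, 2))
  expect_error(estimate_rail_deviations(rec), "residual degree")
})

test_that("omnibus rail F matches the sums-of-squares oracle", {
  expect_equal(
    omnibus_rail_test(make_records("x", rep(c("1:1", "1:2"), each = 2), c(-1, 1, -1, 1)))$F,
    0
  )
  res <- omnibus_rail_test(
    make_records("x", rep(c("1:1", "1:2"), each = 2), c(0, 2, 10, 12))
  )
  # SSB = 100, SSW = 4 -> F = (100/1)/(4/2) = 50 on (1, 2) df
  expect_equal(res$F, 50, tolerance = 1e-8)
  expect_equal(c(res$df1, res$df2), c(1, 2))
  expect_equal(res$p, pf(50, 1, 2, lower.tail = FALSE), tolerance = 1e-10)
  expect_error(
    omnibus_rail_test(make_records("x", rep("1:1", 4), rnorm(4))),
    "two rail levels"
  )
})

test_that("identical species profiles give a null interaction", {
  set.seed(55)
  rails <- rep(c("1:5", "1:1", "5:1"), each = 8)
  dev <- rnorm(24)
  rec <- rbind(
    make_records("a", rails, dev),
    make_records("b", rails, dev)
  )
  res <- interaction_test(rec)
  expect_equal(res$F, 0, tolerance = 1e-10)
  expect_equal(res$df1, 2) # (2-1) * (3-1)
})

test_that("interaction test uses shared rails and sequential sums of squares", {
  set.seed(56)
  rec <- rbind(
    make_records("a", rep(c("1:5", "1:1", "2:1"), each = 6), rnorm(18, c(-5, 0, 5))),
    make_records("b", rep(c("1:1", "2:1", "5:1"), each = 6), rnorm(18, c(2, 0, -2)))
  )
  res <- interaction_test(rec)
  # oracle: sequential anova on the shared-rail subset
  sub <- rec[rec$rail %in% c("1:1", "2:1"), ]
  tab <- anova(lm(deviation_deg ~ factor(species) * factor(rail), data = sub))
  expect_equal(res$F, tab$`F value`[3], tolerance = 1e-10)
  expect_equal(res$df1, tab$Df[3])
  expect_equal(res$df2, tab$Df[4])

  rec_disjoint <- rbind(
    make_records("a", rep(c("1:5", "1:2"), each = 3), rnorm(6)),
    make_records("b", rep(c("2:1", "5:1"), each = 3), rnorm(6))
  )
  expect_error(interaction_test(rec_disjoint), "share fewer than two")
  expect_error(interaction_test(rec, species_pair = c("a")), "exactly two")
})

test_that("summarize_array bundles estimates and tests", {
  set.seed(77)
  rails <- rep(c("1:2", "2:1"), each = 10)
  rec <- rbind(
    make_records("a", rails, rnorm(20)),
    make_records("b", rails, rnorm(20, mean = rep(c(-4, 4), each = 10)))
  )
  s <- summarize_array(rec)
  expect_s3_class(s, "array_summary")
  expect_equal(nrow(s$estimates), 4)
  expect_named(s$omnibus, c("a", "b"))
  expect_s3_class(s$interaction, "beta_ftest")
  expect_lt(s$interaction$p, 0.01)
  expect_output(print(s), "Per-rail deviation")
})
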