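test_that("identity misclassification leaves labels and estimates untouched", {
  sim <- balanced_logistic_sim(400, seed = 80)
  I2 <- misclass_matrix(diag(2))
  sets <- simulate_label_noise(sim$true_class, I2, lambda = 1.5, B = 5, seed = 81)
  expect_true(all(sets == sim$true_class))

  fit <- mcsimex(sim, "true_class", I2, "logistic", B = 10, seed = 82)
  expect_equal(unname(fit$corrected), unname(fit$naive$coefficients),
               tolerance = 1e-10)
  # every per-lambda mean equals the naive estimate
  expect_lt(max(abs(sweep(fit$mean_estimates, 2, fit$naive$coefficients))), 1e-12)
  # jackknife SE reduces to the naive model SE when no noise is added
  expect_lt(max(abs(fit$std_error / fit$naive$std_error - 1)), 0.1)
  expect_true(all(fit$std_error > 0))
})

test_that("label noise realises the prescribed flip rate", {
  labs <- rep(1:2, each = 5e4)
  sets <- simulate_label_noise(labs, flip_matrix(0.2), lambda = 1, B = 1,
                               seed = 83)
  flip <- mean(sets[, 1] != labs)
  expect_lt(abs(flip - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
  expect_error(simulate_label_noise(labs, flip_matrix(0.2), 1, B = 0), "B")
})

test_that("averaging refits is permutation-invariant and reduces to a single fit", {
  sim <- balanced_logistic_sim(300, seed = 84)
  one <- matrix(sim$true_class, ncol = 1)
  rep5 <- one[, rep(1, 5)]
  avg <- fit_noisy_average(sim, rep5, "logistic")
  single <- fit_class_model(sim, "true_class", "logistic")
  expect_equal(unname(avg$mean), unname(single$coefficients), tolerance = 1e-12)

  sets <- simulate_label_noise(sim$true_class, flip_matrix(0.2), 1, B = 6,
                               seed = 85)
  a <- fit_noisy_average(sim, sets, "logistic")
  b <- fit_noisy_average(sim, sets[, 6:1], "logistic")
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
})

test_that("the class effect attenuates monotonically with added noise", {
  d <- simulate_flipped_labels(20000, 0.2, seed = 86)
  fit <- mcsimex(d, "obs_class", flip_matrix(0.2), "logistic",
                 lambda = c(0.5, 1, 1.5, 2), B = 20, seed = 87)
  traj <- abs(fit$mean_estimates[, "class2"])
  expect_true(all(diff(traj) < 0))
})

test_that("extrapolant fitting recovers exact curves and flags singular grids", {
  g <- c(1.5, -0.8, 0.3)
  lam <- c(0, 0.5, 1, 1.5, 2)
  y <- g[1] + g[2] * lam + g[3] * lam^2
  ex <- fit_extrapolant(lam, y, "quadratic")
  expect_equal(unname(ex$gamma[, 1]), g, tolerance = 1e-8)
  expect_equal(extrapolate(ex, -1)[1, 1], g[1] - g[2] + g[3], tolerance = 1e-8)

  # three points determine the parabola exactly
  ex3 <- fit_extrapolant(c(0, 1, 2), y[c(1, 3, 5)], "quadratic")
  resid <- extrapolate(ex3, c(0, 1, 2))[, 1] - y[c(1, 3, 5)]
  expect_lt(max(abs(resid)), 1e-10)

  # constant estimates: corrected equals the constant
  exc <- fit_extrapolant(lam, rep(2.2, 5), "quadratic")
  expect_equal(extrapolate(exc, -1)[1, 1], 2.2, tolerance = 1e-10)
  expect_lt(max(abs(exc$gamma[2:3, 1])), 1e-10)

  expect_error(fit_extrapolant(c(1, 1, 1), c(1, 2, 3), "quadratic"), "distinct")
  lin <- fit_extrapolant(c(0, 1), c(1, 0.5), "linear")
  expect_equal(extrapolate(lin, -1)[1, 1], 1.5, tolerance = 1e-10)
  ll <- fit_extrapolant(c(0, 1, 2), 2 * exp(-0.3 * c(0, 1, 2)), "loglinear")
  expect_equal(extrapolate(ll, -1)[1, 1], 2 * exp(0.3), tolerance = 1e-6)
  expect_error(fit_extrapolant(c(0, 1, 2), c(1, -1, 1), "loglinear"), "sign")
})

test_that("mcsimex is deterministic given a seed and records its pieces", {
  d <- simulate_flipped_labels(400, 0.2, seed = 88)
  f1 <- mcsimex(d, "obs_class", flip_matrix(0.2), B = 15, seed = 89)
  f2 <- mcsimex(d, "obs_class", flip_matrix(0.2), B = 15, seed = 89)
  expect_identical(f1$corrected, f2$corrected)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(dim(f1$estimates), c(15L, 4L, 2L))
  # corrected = extrapolant at -1, by definition
  expect_equal(unname(f1$corrected),
               unname(drop(extrapolate(f1$extrapolant, -1))), tolerance = 1e-10)
  td <- tidy(f1)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high",
                     "naive"))
  expect_equal(glance(f1)$B, 15)
  expect_error(mcsimex(d, "obs_class", flip_matrix(0.2), lambda = c(1, 0.5)),
               "increasing")
})

test_that("jackknife variance requires replicates and stays positive", {
  d <- simulate_flipped_labels(500, 0.2, seed = 90)
  expect_error(mcsimex(d, "obs_class", flip_matrix(0.2), B = 1,
                       variance = "jackknife", seed = 91), "B >= 2")
  fit <- mcsimex(d, "obs_class", flip_matrix(0.2), B = 30, seed = 92)
  expect_true(all(fit$std_error > 0))
  expect_identical(unname(mcsimex_jackknife_se(fit)), unname(fit$std_error))
})

test_that("simex curve data exposes replicates, means, curve and corrected point", {
  d <- simulate_flipped_labels(400, 0.2, seed = 93)
  fit <- mcsimex(d, "obs_class", flip_matrix(0.2), B = 10, seed = 94)
  cd <- simex_curve(fit, n_curve = 101)
  expect_equal(nrow(cd$means), 2 * 5)          # naive point + 4 levels, 2 terms
  expect_equal(nrow(cd$curve), 2 * 101)
  expect_equal(cd$corrected$estimate,
               unname(fit$corrected[cd$corrected$term]))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("full bootstrap propagates misclassification-matrix uncertainty", {
  # imbalanced survival scenario with a per-replicate re-estimated matrix
  sim <- simulate_mixture(two_class_mixture(0.2), 400, seed = 95) |>
    add_survival_outcome(0.5, seed = 96)
  ca <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 97),
                      sim$true_class)
  boot <- suppressWarnings(
    mcsimex_boot(sim, ca$labels, "cox", n_boot = 50, B = 20, seed = 100))
  td <- tidy(boot)
  expect_true(td$conf.low <= td$estimate & td$estimate <= td$conf.high)
  expect_true(all(is.finite(boot$estimates$estimate)))
  # the bootstrap saw genuinely different matrices, so its spread reflects
  # their estimation and not only data resampling
  expect_lt(max(abs(colSums(boot$average_pi) - 1)), 1e-10)
  expect_gt(stats::sd(boot$estimates$estimate), 0)
  expect_s3_class(boot$full_fit, "mcsimex_fit")
  # reproducible given the seed
  b2 <- suppressWarnings(
    mcsimex_boot(sim, ca$labels, "cox", n_boot = 50, B = 20, seed = 100))
  expect_identical(boot$point, b2$point)

  # degenerate, perfectly separated data: every replicate sees ~identity
  # matrices and the bootstrap collapses onto the naive fit's neighbourhood
  ssep <- separated_sim(250, seed = 101) |>
    add_survival_outcome(0.5, seed = 102)
  casep <- align_classes(cluster_classes(ssep, "gmm", k = 2, seed = 103),
                         ssep$true_class)
  bsep <- suppressWarnings(
    mcsimex_boot(ssep, casep$labels, "cox", n_boot = 20, B = 10, seed = 104))
  naive <- fit_class_model(ssep, casep$labels, "cox")
  expect_lt(abs(bsep$point[["class2"]] - naive$coefficients[["class2"]]), 0.5)
})
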