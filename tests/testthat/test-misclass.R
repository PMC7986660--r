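test_that("misclass_matrix validates the column-stochastic contract", {
  expect_s3_class(flip_matrix(0.2), "misclass_matrix")
  expect_error(misclass_matrix(matrix(c(0.8, 0.1, 0.2, 0.8), 2)), "sum to 1")
  expect_error(misclass_matrix(matrix(c(1.2, -0.2, 0.2, 0.8), 2)), "\\[0, 1\\]")
  expect_error(misclass_matrix(matrix(1, 2, 3)), "square")
})

test_that("matrix powers match trivial and repeated-multiplication oracles", {
  Pi <- flip_matrix(0.2)
  expect_lt(max(abs(misclass_power(Pi, 0) - diag(2))), 1e-10)
  expect_lt(max(abs(misclass_power(Pi, 1) - Pi)), 1e-10)
  # 0.8^2 + 0.2^2 = 0.68 on the diagonal of the square
  sq <- misclass_power(Pi, 2)
  expect_equal(unclass(sq), unclass(Pi) %*% unclass(Pi), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sq[1, 1], 0.68, tolerance = 1e-10)
  expect_equal(sq[2, 1], 0.32, tolerance = 1e-10)

  # integer powers vs repeated multiplication for a non-symmetric matrix
  P3 <- misclass_matrix(rbind(c(0.7, 0.1, 0.1),
                              c(0.2, 0.8, 0.1),
                              c(0.1, 0.1, 0.8)))
  acc <- diag(3)
  for (k in 1:4) {
    acc <- acc %*% unclass(P3)
    expect_lt(max(abs(misclass_power(P3, k) - acc)), 1e-8)
  }
})

test_that("matrix powers satisfy the semigroup property", {
  set.seed(99)
  for (rep in 1:5) {
    d <- stats::runif(2, 0.6, 0.95)
    Pi <- misclass_matrix(rbind(c(d[1], 1 - d[2]), c(1 - d[1], d[2])))
    for (ab in list(c(0.5, 0.5), c(0.3, 1.2), c(1, 1), c(0.25, 0.75))) {
      lhs <- misclass_power(Pi, sum(ab))
      rhs <- unclass(misclass_power(Pi, ab[1])) %*% unclass(misclass_power(Pi, ab[2]))
      expect_lt(max(abs(lhs - rhs)), 1e-8)
    }
  }
})

test_that("existence diagnostics flag negative eigenvalues", {
  expect_true(misclass_existence(diag(2))$ok)
  expect_true(misclass_existence(flip_matrix(0.2), lambda_max = 4)$ok)
  bad <- misclass_existence(flip_matrix(0.6))   # eigenvalues 1 and -0.2
  expect_false(bad$ok)
  expect_false(bad$eigen_ok)
  expect_error(misclass_power(flip_matrix(0.6), 0.5), "non-positive eigenvalues")
})

test_that("Monte Carlo misclassification estimate matches the Gaussian overlap", {
  # separable clusters: essentially no misclassification
  ssep <- separated_sim(300, seed = 30)
  casep <- align_classes(cluster_classes(ssep, "gmm", k = 2, seed = 31),
                         ssep$true_class)
  Pi_sep <- estimate_misclass(casep, n_mc = 20000, seed = 32)
  expect_lt(max(abs(Pi_sep - diag(2))), 0.001)

  # balanced overlap scenario: diagonal ~ 1 - Phi(-1) = 0.841
  sim <- simulate_mixture(two_class_mixture(0.5), 1000, seed = 33)
  ca <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 34),
                      sim$true_class)
  Pi <- estimate_misclass(ca, n_mc = 1e5, seed = 35)
  expect_lt(max(abs(diag(Pi) - stats::pnorm(1))), 0.03)
  expect_lt(max(abs(colSums(Pi) - 1)), 1e-12)

  km <- align_classes(cluster_classes(sim, "kmeans", k = 2, seed = 36),
                      sim$true_class)
  Pi_km <- estimate_misclass(km, n_mc = 2e4, seed = 37)
  expect_lt(max(abs(colSums(Pi_km) - 1)), 1e-12)
  expect_gt(min(diag(Pi_km)), 0.7)

  expect_error(estimate_misclass(ca, n_mc = 0), "n_mc")
  cm <- cluster_classes(sim, "cmeans", k = 2, seed = 38)
  expect_error(estimate_misclass(cm), "generative")
})

test_that("Monte Carlo error of the estimate shrinks as 1/sqrt(n_mc)", {
  sim <- simulate_mixture(two_class_mixture(0.5), 800, seed = 40)
  ca <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 41),
                      sim$true_class)
  ent <- function(n_mc) vapply(1:30, function(s)
    estimate_misclass(ca, n_mc = n_mc, seed = 100 + s)[1, 1], numeric(1))
  ratio <- stats::sd(ent(400)) / stats::sd(ent(6400))
  expect_gt(ratio, 2.2)  # theoretical ratio 4 under 16x more draws
  expect_lt(ratio, 7)
})

test_that("misclassification matrices round-trip through CSV", {
  Pi <- misclass_matrix(rbind(c(0.8, 0.25), c(0.2, 0.75)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_misclass(Pi, path)
  back <- read_misclass(path)
  expect_equal(unclass(back), unclass(Pi), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("out-of-bag bootstrap matrices are column-stochastic and reproducible", {
  sim <- separated_sim(250, seed = 50)
  ca <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 51),
                      sim$true_class)
  oob <- estimate_misclass_oob(sim, ca$labels, n_boot = 8, k = 2, seed = 52)
  expect_length(oob$matrices, 8)
  for (m in oob$matrices) {
    expect_lt(max(abs(m - diag(2))), 0.05)  # separable: near identity
    expect_lt(max(abs(colSums(m) - 1)), 1e-10)
  }
  expect_lt(max(abs(colSums(oob$average) - 1)), 1e-10)

  o1 <- estimate_misclass_oob(sim, ca$labels, n_boot = 1, k = 2, seed = 7)
  o2 <- estimate_misclass_oob(sim, ca$labels, n_boot = 1, k = 2, seed = 7)
  expect_identical(o1$matrices, o2$matrices)
})
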