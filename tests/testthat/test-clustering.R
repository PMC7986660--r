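test_that("well-separated components are recovered perfectly by all methods", {
  sim <- separated_sim(400, seed = 1)
  for (method in c("gmm", "kmeans", "cmeans")) {
    ca <- align_classes(cluster_classes(sim, method, k = 2, seed = 2),
                        sim$true_class)
    expect_identical(ca$labels, sim$true_class)
    if (method == "cmeans") {
      own <- ca$posterior[cbind(seq_len(ca$n), ca$labels)]
      expect_gte(stats::median(own), 0.99)
      expect_true(all(own >= 0.95))
    }
  }
})

test_that("posterior matrices are row-stochastic with argmax hard labels", {
  sim <- simulate_mixture(two_class_mixture(), 300, seed = 3)
  for (method in c("gmm", "kmeans", "cmeans")) {
    ca <- cluster_classes(sim, method, k = 2, seed = 4)
    expect_lt(max(abs(rowSums(ca$posterior) - 1)), 1e-8)
    expect_identical(ca$labels, max.col(ca$posterior, ties.method = "first"))
    td <- tidy(ca)
    expect_identical(td$.class, ca$labels)
  }
})

test_that("GMM misclassification approaches the Gaussian overlap rate", {
  # equal-prior components at distance 2 with unit covariance: the optimal
  # rule errs with probability Phi(-1)
  sim <- simulate_mixture(two_class_mixture(0.5), 1000, seed = 5)
  ca <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 6),
                      sim$true_class)
  err <- mean(ca$labels != sim$true_class)
  expect_lt(abs(err - stats::pnorm(-1)), 0.03)
})

test_that("GMM posteriors agree with a direct Bayes-rule computation", {
  sim <- simulate_mixture(two_class_mixture(), 400, seed = 7)
  ca <- cluster_classes(sim, "gmm", k = 2, seed = 8)
  X <- as.matrix(sim[, c("z1", "z2")])
  dens <- vapply(1:2, function(j) {
    s <- ca$model$sigma[[j]]
    mu <- ca$model$mean[j, ]
    cent <- sweep(X, 2, mu)
    q <- rowSums((cent %*% solve(s)) * cent)
    ca$model$pro[j] * exp(-q / 2) / (2 * pi * sqrt(det(s)))
  }, numeric(nrow(X)))
  manual <- dens / rowSums(dens)
  expect_lt(max(abs(manual - ca$posterior)), 1e-6)
})

test_that("degenerate clustering inputs are rejected", {
  sim <- simulate_mixture(two_class_mixture(), 100, seed = 9)
  expect_error(cluster_classes(sim, "gmm", k = 1), ">= 2")
  same <- tibble::tibble(z1 = rep(1, 50), z2 = rep(2, 50))
  expect_error(cluster_classes(same, "kmeans", k = 2), "distinct")
  expect_error(cluster_classes(sim, "cmeans", k = 2, fuzzifier = 1), "fuzzifier")
})

test_that("a large fuzzifier flattens memberships toward 1/k", {
  sim <- simulate_mixture(two_class_mixture(), 200, seed = 10)
  ca <- cluster_classes(sim, "cmeans", k = 2, fuzzifier = 1000, seed = 11)
  # memberships flatten except at points sitting essentially on a center
  expect_lt(mean(abs(ca$posterior - 0.5)), 0.02)
  expect_lt(stats::quantile(abs(ca$posterior - 0.5), 0.9), 0.02)
})

test_that("k-means drifts toward uniform cluster sizes on imbalanced data", {
  sim <- simulate_mixture(two_class_mixture(0.2), 2000, seed = 12)
  ca <- cluster_classes(sim, "kmeans", k = 2, seed = 13)
  shares <- tabulate(ca$labels, 2) / ca$n
  expect_gt(min(shares), 0.25)  # true minority share is 0.20
})

test_that("GMM and k-means approximate the same boundary on balanced data", {
  sim <- simulate_mixture(two_class_mixture(0.5), 1000, seed = 14)
  g <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 15),
                     sim$true_class)
  k <- align_classes(cluster_classes(sim, "kmeans", k = 2, seed = 16),
                     sim$true_class)
  expect_gte(mean(g$labels == k$labels), 0.9)
})

test_that("alignment undoes label switching and is idempotent and optimal", {
  sim <- separated_sim(200, seed = 17)
  ca <- cluster_classes(sim, "gmm", k = 2, seed = 18)
  swapped <- ifelse(sim$true_class == 1L, 2L, 1L)
  a1 <- align_classes(ca, swapped)
  expect_identical(a1$labels, swapped)
  a2 <- align_classes(a1, swapped)
  expect_identical(a1, a2)
  # aligning to itself is the identity permutation
  self <- align_classes(ca, ca$labels)
  expect_identical(self$labels, ca$labels)
  expect_identical(self$posterior, ca$posterior)

  # three-class case: the achieved confusion trace matches the best of all
  # 3! permutations (brute-force oracle)
  mix3 <- mixture_model(rep(1 / 3, 3), rbind(c(0, 0), c(1.5, 0), c(0, 1.5)))
  s3 <- simulate_mixture(mix3, 300, seed = 19)
  c3 <- cluster_classes(s3, "gmm", k = 3, seed = 20)
  aligned <- align_classes(c3, s3$true_class)
  conf <- table(factor(c3$labels, 1:3), factor(s3$true_class, 1:3))
  best <- max(apply(perms_oracle(3), 1, function(p) sum(conf[cbind(1:3, p)])))
  achieved <- sum(diag(table(factor(aligned$labels, 1:3),
                             factor(s3$true_class, 1:3))))
  expect_identical(achieved, best)
  expect_error(align_classes(ca, rep(1L, 10)), "per clustered observation")
})

test_that("predict applies the fitted rule to new data", {
  sim <- separated_sim(300, seed = 21)
  ca <- align_classes(cluster_classes(sim, "gmm", k = 2, seed = 22),
                      sim$true_class)
  new <- separated_sim(100, seed = 23)
  pred <- predict(ca, new)
  expect_identical(pred$labels, new$true_class)
  expect_lt(max(abs(rowSums(pred$posterior) - 1)), 1e-8)
})
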