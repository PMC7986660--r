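#' Full-bootstrap mcsimex with out-of-bag misclassification estimation
#'
#' The jackknife variance of [mcsimex()] ignores the uncertainty of the
#' estimated misclassification matrix and is anticonservative. This routine
#' propagates both sources: for each bootstrap replicate it (i) resamples
#' rows with replacement, (ii) refits the clustering on the in-bag rows and
#' aligns it to the reference labels, (iii) estimates the misclassification
#' matrix from the out-of-bag rows (predicted in-bag-model class versus
#' reference class), and (iv) runs mcsimex on the in-bag data with that
#' matrix. The distribution of corrected coefficients over replicates gives
#' percentile confidence intervals; the point estimate is reported as the
#' bootstrap median alongside the full-data plug-in fit.
#'
#' A cheaper alternative is also returned: a single mcsimex fit on the full
#' data using the element-wise average of the bootstrap misclassification
#' matrices (`average_mc`).
#'
#' @param data Data frame with feature and outcome columns.
#' @param reference Column name or integer vector of reference labels
#'   (typically the full-data clustering, aligned as desired).
#' @param kind `"logistic"` or `"cox"`.
#' @param n_boot Bootstrap replicates (>= 2).
#' @param k Number of classes.
#' @param features Feature column names (default `z*`).
#' @param clustering Clustering method refitted per replicate.
#' @param lambda,B,extrapolant Passed to [mcsimex()] (B defaults lower than
#'   in a single fit because the outer bootstrap already averages).
#' @param conf_level Percentile interval level.
#' @param seed Optional integer seed.
#' @return Object of class `mcsimex_boot`: tibble `estimates` (replicate,
#'   term, estimate), `point` (bootstrap medians), `conf_low`/`conf_high`
#'   (percentile limits), `full_fit` (plug-in [mcsimex()] on the full data
#'   with the average matrix), `average_pi`, and `n_failed`. Supports
#'   [tidy()].
#' @export
mcsimex_boot <- function(data, reference, kind = c("logistic", "cox"),
                         n_boot = 200, k = 2, features = NULL,
                         clustering = "gmm", lambda = c(0.5, 1, 1.5, 2),
                         B = 50, extrapolant = "quadratic",
                         conf_level = 0.95, seed = NULL) {
  kind <- match.arg(kind)
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  ref <- check_labels(pull_labels(data, reference), k, "reference")
  X <- extract_features(data, features)
  n <- nrow(X)
  seeds <- derive_seeds(seed, n_boot + 1L)
  rows <- vector("list", n_boot)
  pis <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    res <- tryCatch(
      with_seed_if(seeds[b], {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) < k) abort("Too few out-of-bag rows.")
        inbag <- as.data.frame(X[idx, , drop = FALSE])
        fit <- cluster_classes(inbag, method = clustering, k = k)
        fit <- align_classes(fit, ref[idx])
        pred <- predict(fit, X[oob, , drop = FALSE])$labels
        conf <- table(factor(pred, seq_len(k)), factor(ref[oob], seq_len(k)))
        counts <- matrix(as.numeric(conf), k, k)
        tot <- colSums(counts)
        if (any(tot == 0)) abort("Out-of-bag class with zero members.")
        pi_b <- misclass_matrix(sweep(counts, 2L, tot, "/"))
        boot_data <- dplyr::slice(as_tibble(data), idx)
        mc <- mcsimex(boot_data, fit$labels, pi_b, kind = kind,
                      lambda = lambda, B = B, extrapolant = extrapolant,
                      variance = "none")
        list(est = mc$corrected, pi = pi_b)
      }),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      rows[[b]] <- res$est
      pis[[b]] <- res$pi
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (sum(ok) < 2L) abort("Fewer than two bootstrap replicates succeeded.")
  if (n_failed > 0L) {
    warn(sprintf("%d of %d bootstrap replicates failed and were dropped.",
                 n_failed, n_boot))
  }
  est_mat <- do.call(rbind, rows[ok])
  terms <- colnames(est_mat)
  alpha <- (1 - conf_level) / 2
  point <- setNames(apply(est_mat, 2L, stats::median), terms)
  ci <- vapply(seq_along(terms), function(j) {
    stats::quantile(est_mat[, j], c(alpha, 1 - alpha), names = FALSE)
  }, numeric(2))
  colnames(ci) <- terms
  avg_pi <- misclass_matrix(
    apply(simplify2array(lapply(pis[ok], unclass)), c(1, 2), mean))
  full_assign <- with_seed_if(seeds[n_boot + 1L], {
    fit <- cluster_classes(as.data.frame(X), method = clustering, k = k)
    align_classes(fit, ref)
  })
  full_fit <- mcsimex(as_tibble(data), full_assign$labels, avg_pi, kind = kind,
                      lambda = lambda, B = B, extrapolant = extrapolant,
                      variance = "none", seed = seeds[n_boot + 1L])
  estimates <- purrr::map_dfr(seq_along(terms), function(j) {
    tibble(replicate = which(ok), term = terms[j], estimate = est_mat[, j])
  })
  structure(
    list(estimates = estimates, point = point,
         conf_low = ci[1L, ], conf_high = ci[2L, ],
         full_fit = full_fit, average_pi = avg_pi,
         n_boot = n_boot, n_failed = n_failed, kind = kind,
         conf_level = conf_level),
    class = "mcsimex_boot"
  )
}

#' @export
print.mcsimex_boot <- function(x, ...) {
  cat(sprintf("<mcsimex_boot> %s, %d replicates (%d failed)\n",
              x$kind, x$n_boot, x$n_failed))
  print(tidy(x))
  invisible(x)
}

#' Tidy a bootstrap mcsimex result
#'
#' @param x An `mcsimex_boot`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (bootstrap median), percentile
#'   `conf.low`/`conf.high`, and `full_data` (plug-in estimate with the
#'   average misclassification matrix).
#' @export
tidy.mcsimex_boot <- function(x, ...) {
  tibble(term = names(x$point),
         estimate = unname(x$point),
         conf.low = unname(x$conf_low),
         conf.high = unname(x$conf_high),
         full_data = unname(x$full_fit$corrected[names(x$point)]))
}
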