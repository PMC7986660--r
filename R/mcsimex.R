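#' Simulate label sets with added misclassification noise
#'
#' The simulation half of the mcsimex algorithm: given current labels and a
#' misclassification matrix \eqn{\Pi}, draws `B` corrupted label sets where
#' each observation's new label is sampled from the column of
#' \eqn{\Pi^\lambda} indexed by its current label, independently across
#' observations and replicates. With \eqn{\Pi = I} the labels are returned
#' unchanged for every \eqn{\lambda}.
#'
#' @param labels Integer labels in 1..m.
#' @param pi A [misclass_matrix()].
#' @param lambda Noise exponent (>= 0).
#' @param B Number of corrupted label sets.
#' @param seed Optional integer seed.
#' @return An n x B integer matrix, one corrupted label set per column.
#' @export
simulate_label_noise <- function(labels, pi, lambda, B, seed = NULL) {
  pi <- as_misclass(pi)
  k <- ncol(pi)
  labels <- check_labels(labels, k)
  B <- check_count(B, "B")
  check_scalar_number(lambda, "lambda", 0, Inf)
  P <- unclass(misclass_power(pi, lambda))
  cum <- apply(P, 2L, cumsum)
  cum[k, ] <- 1  # guard against round-off in the last bin
  CC <- cum[-k, labels, drop = FALSE]            # (k-1) x n cut points
  n <- length(labels)
  with_seed_if(seed, {
    out <- matrix(0L, n, B)
    for (b in seq_len(B)) {
      u <- matrix(runif(n), k - 1L, n, byrow = TRUE)
      out[, b] <- 1L + colSums(CC < u)
    }
    out
  })
}

#' Average refits over corrupted label sets
#'
#' The estimation half of an mcsimex noise level: refits the outcome model
#' on each corrupted label set and averages the coefficient vectors.
#' Individual refits that fail (e.g. separation under heavy label noise) are
#' dropped with a warning and the divisor reduced; a failure rate above
#' `max_fail` aborts.
#'
#' @param data Data frame with the outcome columns.
#' @param label_sets n x B integer matrix of label sets (see
#'   [simulate_label_noise()]).
#' @param kind `"logistic"` or `"cox"`.
#' @param m Number of classes.
#' @param max_fail Maximum tolerated fraction of failed refits.
#' @return List with `mean` (averaged coefficient vector), `estimates`
#'   (B x p matrix, `NA` rows for failures), `se2` (model-based variances,
#'   same shape) and `n_failed`.
#' @export
fit_noisy_average <- function(data, label_sets, kind = c("logistic", "cox"),
                              m = NULL, max_fail = 0.2) {
  kind <- match.arg(kind)
  label_sets <- as.matrix(label_sets)
  B <- ncol(label_sets)
  if (B < 1L) abort("Need at least one label set.")
  m <- m %||% max(label_sets)
  out <- extract_outcome(data, kind)
  p <- m - 1L + (kind == "logistic")
  est <- matrix(NA_real_, B, p)
  se2 <- matrix(NA_real_, B, p)
  for (b in seq_len(B)) {
    fit <- tryCatch(
      fit_design(class_design(check_labels(label_sets[, b], m), m,
                              intercept = kind == "logistic"), out, kind),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      est[b, ] <- fit$coefficients
      se2[b, ] <- fit$std_error^2
      if (b == 1L || is.null(colnames(est))) {
        colnames(est) <- colnames(se2) <- names(fit$coefficients)
      }
    }
  }
  n_failed <- sum(is.na(est[, 1L]))
  if (n_failed == B) abort("All refits on corrupted label sets failed.")
  if (n_failed / B > max_fail) {
    abort(sprintf("%d of %d refits failed (> %.0f%% tolerated): the noise level is too high for stable estimation.",
                  n_failed, B, 100 * max_fail))
  }
  if (n_failed > 0L) {
    warn(sprintf("%d of %d refits failed and were dropped from the average.",
                 n_failed, B))
  }
  list(mean = colMeans(est, na.rm = TRUE), estimates = est, se2 = se2,
       n_failed = n_failed)
}

#' Fit the simulation-extrapolation curve
#'
#' Least-squares fit of a parametric curve \eqn{G(\lambda, \gamma)} through
#' the naive estimate (at \eqn{\lambda = 0}) and the mean estimates at each
#' positive noise level, separately per regression coefficient. Supported
#' forms: `"quadratic"` \eqn{\gamma_0 + \gamma_1\lambda + \gamma_2\lambda^2}
#' (the default and the only form with three parameters), `"linear"`, and
#' `"loglinear"` \eqn{s\,\exp(\gamma_0 + \gamma_1\lambda)} with `s` the sign
#' of the estimates (which must not change along the grid).
#'
#' @param lambda Numeric vector of noise levels, including 0.
#' @param estimates Matrix with one row per lambda and one column per
#'   coefficient (a vector is treated as a single coefficient).
#' @param kind Extrapolant form.
#' @return Object of class `simex_extrapolant`: `gamma` (one column per
#'   coefficient), `kind`, `sign`. Evaluate with [extrapolate()].
#' @export
fit_extrapolant <- function(lambda, estimates,
                            kind = c("quadratic", "linear", "loglinear")) {
  kind <- match.arg(kind)
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1L)
  if (length(lambda) != nrow(estimates)) {
    abort("`lambda` and rows of `estimates` must match.")
  }
  n_par <- if (kind == "quadratic") 3L else 2L
  if (length(unique(lambda)) < n_par) {
    abort(sprintf("The %s extrapolant needs >= %d distinct lambda values.",
                  kind, n_par))
  }
  X <- switch(kind,
              quadratic = cbind(1, lambda, lambda^2),
              cbind(1, lambda))
  p <- ncol(estimates)
  sgn <- rep(1, p)
  Y <- estimates
  if (kind == "loglinear") {
    sgn <- sign(estimates[1L, ])
    if (any(sgn == 0) || any(sweep(sign(estimates), 2L, sgn, "!=") & estimates != 0)) {
      abort("Log-linear extrapolation requires estimates of constant non-zero sign; use the quadratic form.")
    }
    Y <- log(abs(estimates))
  }
  gamma <- matrix(qr.solve(X, Y), nrow = n_par, ncol = p,
                  dimnames = list(NULL, colnames(estimates)))
  structure(list(gamma = gamma, kind = kind, sign = sgn),
            class = "simex_extrapolant")
}

#' Evaluate a fitted extrapolation curve
#'
#' @param extr A [fit_extrapolant()] result.
#' @param lambda Numeric vector of evaluation points; the mcsimex estimate
#'   is the value at `lambda = -1` (the level of no misclassification).
#' @return Matrix with one row per `lambda` and one column per coefficient.
#' @export
extrapolate <- function(extr, lambda = -1) {
  stopifnot(inherits(extr, "simex_extrapolant"))
  X <- switch(extr$kind,
              quadratic = cbind(1, lambda, lambda^2),
              cbind(1, lambda))
  pred <- X %*% extr$gamma
  if (extr$kind == "loglinear") {
    pred <- sweep(exp(pred), 2L, extr$sign, "*")
  }
  pred
}

#' Misclassification simulation-extrapolation (mcsimex)
#'
#' Corrects a regression on misclassified class labels by simulation and
#' extrapolation. Writing \eqn{\beta(\Pi^{1+\lambda})} for the limit of the
#' estimator when the labels carry misclassification \eqn{\Pi^{1+\lambda}},
#' the observed (naive) estimate sits at \eqn{\lambda = 0} and the target at
#' \eqn{\lambda = -1}. The algorithm:
#'
#' 1. for each \eqn{\lambda} on a grid, simulate `B` label sets with extra
#'    noise \eqn{\Pi^\lambda} ([simulate_label_noise()]);
#' 2. refit the model on each and average per \eqn{\lambda}
#'    ([fit_noisy_average()]);
#' 3. fit the extrapolant curve through the naive point at \eqn{\lambda = 0}
#'    and the per-\eqn{\lambda} means ([fit_extrapolant()]);
#' 4. report the curve's value at \eqn{\lambda = -1}.
#'
#' With \eqn{\Pi = I} every refit reproduces the naive estimate and the
#' corrected estimate equals the naive one — the algorithm's fixed point.
#'
#' @param data Data frame with outcome columns (`y`, or `time`/`status`).
#' @param labels Label column name or integer vector (the error-prone
#'   labels, e.g. from clustering).
#' @param pi A [misclass_matrix()] describing their misclassification.
#' @param kind `"logistic"` or `"cox"`.
#' @param lambda Increasing positive noise grid.
#' @param B Refits per noise level.
#' @param extrapolant Curve family, see [fit_extrapolant()].
#' @param variance `"jackknife"` (default; known to understate the true
#'   variance, so coverage of its intervals runs below nominal) or
#'   `"none"`. For a variance that also reflects estimation of `pi`, see
#'   [mcsimex_boot()].
#' @param seed Optional integer seed.
#' @param conf_level Confidence level for Wald intervals.
#' @param max_fail Maximum tolerated fraction of failed refits per level.
#' @return Object of class `mcsimex_fit`: the naive `class_fit`, per-level
#'   estimates (`estimates`: B x nlambda x p array), per-level means
#'   (`mean_estimates`, including the naive row at lambda 0), the fitted
#'   `extrapolant`, `corrected` coefficients, standard errors and confidence
#'   limits. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' Pi <- misclass_matrix(matrix(c(0.8, 0.2, 0.2, 0.8), 2))
#' d <- simulate_flipped_labels(500, 0.2, seed = 1)
#' fit <- mcsimex(d, "obs_class", Pi, B = 20, seed = 2)
#' tidy(fit)
#' @export
mcsimex <- function(data, labels, pi, kind = c("logistic", "cox"),
                    lambda = c(0.5, 1, 1.5, 2), B = 100,
                    extrapolant = c("quadratic", "linear", "loglinear"),
                    variance = c("jackknife", "none"), seed = NULL,
                    conf_level = 0.95, max_fail = 0.2) {
  kind <- match.arg(kind)
  extrapolant <- match.arg(extrapolant)
  variance <- match.arg(variance)
  pi <- as_misclass(pi)
  if (!length(lambda) || any(lambda <= 0) || is.unsorted(lambda, strictly = TRUE)) {
    abort("`lambda` must be a non-empty strictly increasing grid of positive values.")
  }
  B <- check_count(B, "B")
  m <- ncol(pi)
  lab <- check_labels(pull_labels(data, labels), m)
  naive <- fit_class_model(data, lab, kind, m = m, conf_level = conf_level)
  p <- length(naive$coefficients)
  n_lam <- length(lambda)
  seeds <- derive_seeds(seed, n_lam)
  est <- array(NA_real_, c(B, n_lam, p),
               dimnames = list(NULL, NULL, names(naive$coefficients)))
  se2 <- est
  n_failed <- integer(n_lam)
  for (kix in seq_len(n_lam)) {
    sets <- simulate_label_noise(lab, pi, lambda[kix], B, seed = seeds[kix])
    step <- fit_noisy_average(data, sets, kind, m = m, max_fail = max_fail)
    est[, kix, ] <- step$estimates
    se2[, kix, ] <- step$se2
    n_failed[kix] <- step$n_failed
  }
  lambda_all <- c(0, lambda)
  mean_est <- rbind(naive$coefficients,
                    apply(est, c(2, 3), mean, na.rm = TRUE))
  rownames(mean_est) <- NULL
  extr <- fit_extrapolant(lambda_all, mean_est, extrapolant)
  corrected <- drop(extrapolate(extr, -1))
  names(corrected) <- names(naive$coefficients)
  se <- rep(NA_real_, p)
  if (variance == "jackknife") {
    se <- jackknife_se(naive, est, se2, lambda_all, extrapolant)
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(naive = naive, lambda = lambda, lambda_all = lambda_all, B = B,
         estimates = est, se2 = se2, mean_estimates = mean_est,
         extrapolant = extr, corrected = corrected,
         std_error = setNames(se, names(corrected)),
         conf_low = corrected - zq * se, conf_high = corrected + zq * se,
         variance = variance, kind = kind, m = m, n = naive$n, pi = pi,
         n_failed = n_failed, conf_level = conf_level, seed = seed),
    class = "mcsimex_fit"
  )
}

# SIMEX jackknife variance: per noise level, the model-based variance minus
# the between-replicate sample variance estimates the sampling-variance
# component; the component at lambda = 0 is the naive model variance. The
# components are extrapolated to lambda = -1 with the same curve family.
# Known to understate the truth; negative extrapolations are clipped at 0
# with a warning.
jackknife_se <- function(naive, est, se2, lambda_all, extrapolant) {
  B <- dim(est)[1L]
  if (B < 2L) abort("Jackknife variance needs B >= 2 refits per level.")
  vhat <- apply(se2, c(2, 3), mean, na.rm = TRUE)
  svar <- apply(est, c(2, 3), var, na.rm = TRUE)
  comp <- rbind(naive$std_error^2, vhat - svar)
  kind <- if (extrapolant == "loglinear") "quadratic" else extrapolant
  v <- tryCatch(
    drop(extrapolate(fit_extrapolant(lambda_all, comp, kind), -1)),
    error = function(e) {
      warn("Variance extrapolation failed; standard errors unavailable.")
      rep(NA_real_, ncol(comp))
    }
  )
  if (any(v < 0, na.rm = TRUE)) {
    warn("Jackknife variance extrapolated below zero for some coefficients; clipped at 0.")
    v <- pmax(v, 0)
  }
  sqrt(v)
}

#' Recompute jackknife standard errors from a fitted mcsimex object
#'
#' Uses the per-replicate estimates retained in the fit; see [mcsimex()].
#'
#' @param fit An `mcsimex_fit`.
#' @return Named vector of standard errors.
#' @export
mcsimex_jackknife_se <- function(fit) {
  stopifnot(inherits(fit, "mcsimex_fit"))
  jackknife_se(fit$naive, fit$estimates, fit$se2, fit$lambda_all,
               fit$extrapolant$kind)
}

#' @export
print.mcsimex_fit <- function(x, ...) {
  cat(sprintf("<mcsimex_fit> %s, n = %d, B = %d, lambda = (%s), %s extrapolant\n",
              x$kind, x$n, x$B, paste(x$lambda, collapse = ", "),
              x$extrapolant$kind))
  print(tidy(x))
  invisible(x)
}

#' Tidy an mcsimex fit
#'
#' @param x An `mcsimex_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (corrected), `std.error`,
#'   `conf.low`, `conf.high` and `naive` (the uncorrected estimate).
#' @export
tidy.mcsimex_fit <- function(x, ...) {
  tibble(term = names(x$corrected),
         estimate = unname(x$corrected),
         std.error = unname(x$std_error),
         conf.low = unname(x$conf_low),
         conf.high = unname(x$conf_high),
         naive = unname(x$naive$coefficients))
}

#' @describeIn tidy.mcsimex_fit One-row summary of the fit settings.
#' @export
glance.mcsimex_fit <- function(x, ...) {
  tibble(kind = x$kind, n = x$n, B = x$B, n_lambda = length(x$lambda),
         extrapolant = x$extrapolant$kind, variance = x$variance,
         n_failed = sum(x$n_failed))
}

#' Extrapolation-curve data for an mcsimex fit
#'
#' Long-format data behind the classic simulation-extrapolation picture:
#' individual refit estimates per noise level, their means, the fitted
#' curve over `[-1, max(lambda)]` and the corrected point at
#' \eqn{\lambda = -1}.
#'
#' @param fit An `mcsimex_fit`.
#' @param n_curve Number of curve evaluation points.
#' @return List of tibbles `replicates`, `means`, `curve`, `corrected`,
#'   each keyed by `term` and `lambda`.
#' @export
simex_curve <- function(fit, n_curve = 401) {
  stopifnot(inherits(fit, "mcsimex_fit"))
  terms <- names(fit$corrected)
  reps <- purrr::map_dfr(seq_along(terms), function(j) {
    tibble(term = terms[j],
           lambda = rep(fit$lambda, each = fit$B),
           estimate = as.vector(fit$estimates[, , j]))
  })
  means <- purrr::map_dfr(seq_along(terms), function(j) {
    tibble(term = terms[j], lambda = fit$lambda_all,
           estimate = fit$mean_estimates[, j])
  })
  grid <- seq(-1, max(fit$lambda), length.out = n_curve)
  curve_vals <- extrapolate(fit$extrapolant, grid)
  curve <- purrr::map_dfr(seq_along(terms), function(j) {
    tibble(term = terms[j], lambda = grid, estimate = curve_vals[, j])
  })
  corrected <- tibble(term = terms, lambda = -1,
                      estimate = unname(fit$corrected))
  list(replicates = dplyr::filter(reps, !is.na(.data$estimate)),
       means = means, curve = curve, corrected = corrected)
}

#' Plot the simulation-extrapolation curve
#'
#' @param object An `mcsimex_fit`.
#' @param ... Unused.
#' @return A ggplot: gray points are individual refits, black points the
#'   per-level means (including the naive estimate at 0), the line the
#'   fitted extrapolant and the open point its value at \eqn{\lambda = -1}
#'   (the corrected estimate), faceted by coefficient.
#' @export
autoplot.mcsimex_fit <- function(object, ...) {
  cd <- simex_curve(object)
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$lambda, y = .data$estimate)) +
    ggplot2::geom_point(data = cd$replicates, colour = "grey70", size = 0.6,
                        alpha = 0.5) +
    ggplot2::geom_line(data = cd$curve) +
    ggplot2::geom_point(data = cd$means, size = 2) +
    ggplot2::geom_point(data = cd$corrected, shape = 21, fill = "white",
                        size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = expression(lambda), y = "estimate",
                  title = "Simulation and extrapolation") +
    ggplot2::theme_minimal()
}
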