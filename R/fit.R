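# Shared fitting path for logistic and Cox models on an explicit design
# matrix. Both the naive (indicator) and regression-calibration (posterior
# probability) designs go through this function, so that degenerate 0/1
# posteriors reproduce the naive fit bit for bit.
fit_design <- function(X, outcome, kind) {
  if (kind == "logistic") {
    y <- outcome
    if (length(unique(y)) < 2L) {
      abort("Logistic fit failed: the outcome is constant (complete separation).")
    }
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    coefs <- fit$coefficients
    if (!fit$converged || anyNA(coefs) || any(abs(coefs) > 12)) {
      abort("Logistic fit failed: non-convergence or separation (unbounded estimates).")
    }
    p <- ncol(X)
    cov_un <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    se <- sqrt(diag(cov_un))
    ll <- -fit$deviance / 2
  } else {
    if (sum(outcome[, 2L]) < 1) abort("Cox fit requires at least one event.")
    fit <- coxph.fit(X, outcome, strata = NULL, offset = NULL, init = NULL,
                     control = coxph.control(), weights = NULL,
                     method = "efron", rownames = NULL)
    coefs <- fit$coefficients
    if (anyNA(coefs) || any(!is.finite(coefs)) || any(abs(coefs) > 12)) {
      abort("Cox fit failed: non-convergence or monotone likelihood.")
    }
    se <- sqrt(diag(as.matrix(fit$var)))
    ll <- fit$loglik[length(fit$loglik)]
  }
  names(coefs) <- colnames(X)
  list(coefficients = coefs, std_error = setNames(se, colnames(X)), loglik = ll)
}

new_class_fit <- function(fit, kind, n, method, conf_level) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(coefficients = fit$coefficients,
         std_error = fit$std_error,
         conf_low = fit$coefficients - zq * fit$std_error,
         conf_high = fit$coefficients + zq * fit$std_error,
         loglik = fit$loglik, kind = kind, n = n, method = method,
         conf_level = conf_level),
    class = "class_fit"
  )
}

#' Fit the outcome regression on class labels
#'
#' Fits the outcome model with treatment-contrast class encoding (class 1 is
#' the reference level): logistic regression of a binary `y` with an
#' intercept plus indicators for classes 2..m, or a Cox proportional-hazards
#' model of `(time, status)` with the class indicators only (Efron handling
#' of ties). Applied to labels inferred by clustering this is the "naive"
#' estimator, biased toward zero by label misclassification; applied to the
#' true labels it is the benchmark.
#'
#' @param data Data frame with the outcome columns (`y` for logistic;
#'   `time`, `status` for cox) and the label column.
#' @param labels Name of the label column, or an integer vector.
#' @param kind `"logistic"` or `"cox"`.
#' @param m Number of classes; defaults to the largest label.
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `class_fit` with coefficients, Wald standard
#'   errors, confidence limits and log-likelihood. Coefficient names are
#'   `(Intercept)` and `class2`, ..., `classm`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' sim <- simulate_mixture(two_class_mixture(), 500, seed = 1) |>
#'   add_logistic_outcome(c(-1, 2), seed = 2)
#' tidy(fit_class_model(sim, "true_class", "logistic"))
#' @export
fit_class_model <- function(data, labels = "true_class",
                            kind = c("logistic", "cox"), m = NULL,
                            conf_level = 0.95) {
  kind <- match.arg(kind)
  lab <- pull_labels(data, labels)
  m <- m %||% max(lab)
  if (m < 2L) abort("Need at least two classes.")
  lab <- check_labels(lab, m)
  X <- class_design(lab, m, intercept = kind == "logistic")
  out <- extract_outcome(data, kind)
  fit <- fit_design(X, out, kind)
  new_class_fit(fit, kind, length(lab), "naive", conf_level)
}

#' Regression calibration on posterior class probabilities
#'
#' Replaces the class indicators of the naive design with their conditional
#' expectation given the features — the posterior class probabilities from
#' the clustering — and fits the outcome model on this calibrated design
#' (for two classes, the regression is on the probability of class 2).
#' Standard errors are the model-based Wald errors of the fitted regression;
#' no additional variance is added for the estimated probabilities.
#'
#' With degenerate 0/1 probabilities (e.g. from k-means) the calibrated
#' design equals the indicator design and the result is identical to
#' [fit_class_model()]; soft probabilities are what carry the correction, so
#' use a GMM or fuzzy c-means assignment.
#'
#' The assignment must be aligned (see [align_classes()]) so that its class
#' order matches the interpretation of the coefficients.
#'
#' @param data Data frame with the outcome columns.
#' @param assignment A [cluster_classes()] result carrying posterior
#'   probabilities, or directly an n x m row-stochastic matrix.
#' @param kind `"logistic"` or `"cox"`.
#' @param conf_level Confidence level for Wald intervals.
#' @return A `class_fit` (method `"rc"`).
#' @export
fit_rc <- function(data, assignment, kind = c("logistic", "cox"),
                   conf_level = 0.95) {
  kind <- match.arg(kind)
  post <- rc_posterior(assignment, nrow(data))
  X <- rc_design(post, intercept = kind == "logistic")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("Calibrated design is not identifiable: posterior probability columns are constant or collinear.")
  }
  out <- extract_outcome(data, kind)
  fit <- fit_design(X, out, kind)
  new_class_fit(fit, kind, nrow(X), "rc", conf_level)
}

rc_posterior <- function(assignment, n) {
  post <- if (inherits(assignment, "class_assignment")) {
    assignment$posterior
  } else if (is.matrix(assignment)) {
    assignment
  } else {
    abort("`assignment` must be a class_assignment or a posterior matrix; hard labels alone carry no probabilities (fit a GMM or fuzzy c-means).")
  }
  if (nrow(post) != n) abort("Posterior rows must match `data` rows.")
  if (max(abs(rowSums(post) - 1)) > 1e-6 || min(post) < -1e-8) {
    abort("Posterior matrix must be row-stochastic.")
  }
  post
}

# Calibrated design: soft indicators for classes 2..m.
rc_design <- function(post, intercept = TRUE) {
  m <- ncol(post)
  X <- post[, -1L, drop = FALSE]
  colnames(X) <- paste0("class", 2:m)
  if (intercept) X <- cbind(`(Intercept)` = rep(1, nrow(post)), X)
  X
}

extract_outcome <- function(data, kind) {
  if (kind == "logistic") {
    if (!"y" %in% names(data)) abort("Logistic models need a binary `y` column.")
    y <- data$y
    if (any(!y %in% c(0, 1))) abort("`y` must be 0/1.")
    as.numeric(y)
  } else {
    if (!all(c("time", "status") %in% names(data))) {
      abort("Cox models need `time` and `status` columns.")
    }
    if (any(data$time <= 0)) abort("Survival times must be positive.")
    if (any(!data$status %in% c(0, 1))) abort("`status` must be 0/1.")
    Surv(data$time, data$status)
  }
}

#' @export
print.class_fit <- function(x, ...) {
  cat(sprintf("<class_fit> %s (%s), n = %d\n", x$kind, x$method, x$n))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted class regression
#'
#' @param x A `class_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.class_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$std_error),
         conf.low = unname(x$conf_low),
         conf.high = unname(x$conf_high))
}

#' @describeIn tidy.class_fit One-row model summary.
#' @export
glance.class_fit <- function(x, ...) {
  tibble(kind = x$kind, method = x$method, n = x$n, logLik = x$loglik,
         conf.level = x$conf_level)
}
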