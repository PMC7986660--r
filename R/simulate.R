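#' Specify a Gaussian mixture model
#'
#' Container for the generating (or fitted) parameters of an m-component
#' Gaussian mixture: class prior probabilities, component means and
#' component covariance matrices. This is the data-generating model of the
#' simulation studies: features cluster around class-specific means and the
#' class membership is latent.
#'
#' @param priors Numeric vector of class prior probabilities; must be
#'   non-negative and sum to 1. Length m >= 2.
#' @param means Matrix with one row per class (m x p), or a list of m numeric
#'   vectors of common length p.
#' @param covariances A single p x p positive-definite matrix recycled to all
#'   classes, or a list of m such matrices. Defaults to identity.
#' @return An object of class `mixture_model` with elements `priors`, `means`
#'   (m x p matrix), `covariances` (list of m matrices), `m` and `p`.
#' @examples
#' mixture_model(c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)))
#' @export
mixture_model <- function(priors, means, covariances = NULL) {
  if (!is.numeric(priors) || length(priors) < 2L) {
    abort("`priors` must be a numeric vector of length >= 2.")
  }
  if (any(priors < 0) || any(priors > 1) || abs(sum(priors) - 1) > 1e-8) {
    abort("`priors` must be probabilities summing to 1.")
  }
  if (is.list(means)) means <- do.call(rbind, means)
  means <- as.matrix(means)
  m <- length(priors)
  if (nrow(means) != m) abort("`means` must supply one mean vector per class.")
  p <- ncol(means)
  if (is.null(covariances)) covariances <- diag(p)
  if (!is.list(covariances)) covariances <- rep(list(as.matrix(covariances)), m)
  if (length(covariances) != m) {
    abort("`covariances` must be a single matrix or a list of one per class.")
  }
  for (j in seq_len(m)) {
    s <- as.matrix(covariances[[j]])
    if (!all(dim(s) == c(p, p)) || max(abs(s - t(s))) > 1e-8) {
      abort("Each covariance must be a symmetric p x p matrix.")
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("Each covariance must be positive-definite.")
    covariances[[j]] <- s
  }
  structure(
    list(priors = as.numeric(priors), means = means,
         covariances = covariances, m = m, p = p),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture model: %d classes, %d features\n", x$m, x$p))
  cat("priors:", format(x$priors, digits = 3), "\n")
  invisible(x)
}

#' Two-class study mixture
#'
#' The canonical two-class bivariate scenario used throughout the simulation
#' studies: means (-1, 0) and (1, 0) with identity covariances, so the
#' classes overlap with Bayes error \eqn{\Phi(-1) \approx 0.159} when
#' balanced.
#'
#' @param prior1 Prior probability of class 1 (0.5 balanced, 0.2 imbalanced).
#' @return A [mixture_model()].
#' @export
two_class_mixture <- function(prior1 = 0.5) {
  check_scalar_number(prior1, "prior1", 0, 1)
  mixture_model(c(prior1, 1 - prior1), rbind(c(-1, 0), c(1, 0)))
}

#' Simulate features and latent class labels from a Gaussian mixture
#'
#' Draws class labels from the mixture priors and features from the
#' corresponding Gaussian component.
#'
#' @param model A [mixture_model()].
#' @param n Number of observations.
#' @param seed Optional integer seed; the draw is bit-reproducible given the
#'   seed and leaves the session RNG untouched.
#' @return A tibble with columns `z1..zp` (features) and `true_class`
#'   (integer labels in 1..m).
#' @examples
#' simulate_mixture(two_class_mixture(), n = 5, seed = 1)
#' @export
simulate_mixture <- function(model, n, seed = NULL) {
  if (!inherits(model, "mixture_model")) abort("`model` must be a mixture_model.")
  n <- check_count(n, "n")
  with_seed_if(seed, {
    labels <- sample.int(model$m, n, replace = TRUE, prob = model$priors)
    feats <- matrix(0, n, model$p)
    for (j in seq_len(model$m)) {
      idx <- which(labels == j)
      if (length(idx)) {
        feats[idx, ] <- rmvnorm_chol(length(idx), model$means[j, ],
                                     model$covariances[[j]])
      }
    }
    colnames(feats) <- paste0("z", seq_len(model$p))
    out <- as_tibble(feats)
    out$true_class <- labels
    out
  })
}

#' Attach a logistic (binary) outcome
#'
#' Generates `y ~ Bernoulli(expit(x_h' beta))` where `x_h` is the
#' treatment-contrast encoding of the class label: intercept plus indicators
#' for classes 2..m, class 1 being the reference level.
#'
#' @param data Data frame containing the label column.
#' @param beta Coefficient vector on the log-odds scale: intercept followed
#'   by m - 1 class effects.
#' @param labels Name of the class-label column (default `"true_class"`).
#' @param seed Optional integer seed.
#' @return `data` with a `y` column (0/1) appended.
#' @examples
#' simulate_mixture(two_class_mixture(), 100, seed = 1) |>
#'   add_logistic_outcome(beta = c(-1, 2), seed = 2)
#' @export
add_logistic_outcome <- function(data, beta, labels = "true_class", seed = NULL) {
  lab <- pull_labels(data, labels)
  m <- length(beta)
  if (m < 2L) abort("`beta` must contain an intercept and >= 1 class effect.")
  lab <- check_labels(lab, m, labels)
  eta <- class_design(lab, m, intercept = TRUE) %*% beta
  out <- as_tibble(data)
  out$y <- with_seed_if(seed, rbinom(length(lab), 1L, plogis(drop(eta))))
  out
}

#' Attach a right-censored survival outcome
#'
#' Event times are exponential with rate equal to the numeric class label
#' (rate 1 for class 1, rate 2 for class 2, giving a true hazard ratio of 2
#' and true log-hazard effect log 2); censoring times are exponential with
#' rate `censor_rate`, independent of the event time. The observed time is
#' the minimum of the two and `status` indicates an observed event.
#'
#' @param data Data frame containing the label column.
#' @param censor_rate Rate of the exponential censoring distribution (> 0);
#'   0.5 in the reference survival scenario.
#' @param labels Name of the class-label column.
#' @param seed Optional integer seed.
#' @return `data` with `time` (> 0) and `status` (1 = event, 0 = censored)
#'   appended.
#' @export
add_survival_outcome <- function(data, censor_rate = 0.5, labels = "true_class",
                                 seed = NULL) {
  check_scalar_number(censor_rate, "censor_rate", 0, Inf, strict_lower = TRUE)
  lab <- pull_labels(data, labels)
  lab <- check_labels(lab, max(lab), labels)
  out <- as_tibble(data)
  with_seed_if(seed, {
    event_time <- rexp(length(lab), rate = lab)
    censor_time <- rexp(length(lab), rate = censor_rate)
    out$time <- pmin(event_time, censor_time)
    out$status <- as.integer(event_time <= censor_time)
  })
  out
}

#' Simulate binary labels with known random flips
#'
#' The worked illustration of the mcsimex idea: true labels are drawn with
#' `P(class 2) = 0.5`, observed labels flip independently with probability
#' `flip_prob` (a symmetric misclassification matrix with diagonal
#' `1 - flip_prob`), and a binary outcome follows a logistic model in the
#' TRUE label.
#'
#' @param n Number of observations.
#' @param flip_prob Flip probability in `[0, 0.5)`; at 0.5 the labels carry
#'   no information and the misclassification model is not identifiable.
#' @param beta Length-2 log-odds coefficients (intercept, class-2 effect).
#'   The class effect is interpreted on the log-odds scale.
#' @param seed Optional integer seed.
#' @return Tibble with `true_class`, `obs_class` (both in \{1, 2\}) and `y`.
#' @export
simulate_flipped_labels <- function(n, flip_prob, beta = c(-1, 2), seed = NULL) {
  n <- check_count(n, "n")
  check_scalar_number(flip_prob, "flip_prob", 0, 0.5)
  if (flip_prob >= 0.5) {
    abort("`flip_prob` must be < 0.5: at 0.5 the observed labels are pure noise.")
  }
  if (length(beta) != 2L) abort("`beta` must have length 2.")
  with_seed_if(seed, {
    true_class <- sample.int(2L, n, replace = TRUE)
    flip <- runif(n) < flip_prob
    obs_class <- ifelse(flip, 3L - true_class, true_class)
    eta <- beta[1] + beta[2] * (true_class == 2L)
    tibble(true_class = true_class, obs_class = as.integer(obs_class),
           y = rbinom(n, 1L, plogis(eta)))
  })
}

# Extract an integer label vector from a data frame column (by name) or pass
# through a bare vector of the right length.
pull_labels <- function(data, labels) {
  if (is.character(labels) && length(labels) == 1L) {
    if (!labels %in% names(data)) {
      abort(sprintf("Column `%s` not found in `data`.", labels))
    }
    data[[labels]]
  } else if (is.numeric(labels) && length(labels) == nrow(data)) {
    labels
  } else {
    abort("`labels` must name a column of `data` or be a vector of length nrow(data).")
  }
}
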