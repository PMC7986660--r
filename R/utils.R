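# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when one is supplied, leaving the
# global RNG state untouched; with seed = NULL the current stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Draw `n_streams` independent sub-seeds from a master seed. Keeps derived
# seeds within the 32-bit integer range.
derive_seeds <- function(seed, n_streams) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n_streams))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf("`%s` must be in %s%s, %s].", name,
                  if (strict_lower) "(" else "[", lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# All permutations of 1..k as a k! x k matrix (k is a small class count).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}

# Row-wise argmax with ties broken toward the lowest index.
row_argmax <- function(m) {
  max.col(m, ties.method = "first")
}

# Log-density of a multivariate normal, x an n x p matrix.
dmvnorm_log <- function(x, mean, sigma) {
  p <- length(mean)
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("Covariance matrix is not positive-definite.")
  })
  centered <- sweep(x, 2L, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

# Draw n samples from N(mean, sigma).
rmvnorm_chol <- function(n, mean, sigma) {
  p <- length(mean)
  ch <- chol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% ch, 2L, mean, "+")
}

# Treatment-contrast design for class labels 1..m: intercept column (when
# `intercept`) plus indicator columns for classes 2..m.
class_design <- function(labels, m, intercept = TRUE) {
  n <- length(labels)
  cols <- lapply(2:m, function(h) as.numeric(labels == h))
  X <- do.call(cbind, cols)
  colnames(X) <- paste0("class", 2:m)
  if (intercept) {
    X <- cbind(`(Intercept)` = rep(1, n), X)
  }
  X
}

check_labels <- function(labels, m, name = "labels") {
  if (!is.numeric(labels) || any(!is.finite(labels)) ||
      any(labels != floor(labels)) || any(labels < 1L) || any(labels > m)) {
    abort(sprintf("`%s` must be integers in 1..%d.", name, m))
  }
  as.integer(labels)
}
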