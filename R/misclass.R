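#' Misclassification matrix
#'
#' A column-stochastic m x m matrix \eqn{\Pi} with entry (i, j) equal to
#' \eqn{\pi_{ij} = P(H^* = i \mid H = j)}: the probability that the
#' clustering reports class i when the true class is j. Columns (true
#' classes) sum to 1.
#'
#' Note the orientation: conditioning is on the TRUE class, so columns are
#' distributions. Some software uses the transposed (row-stochastic)
#' convention; use [t()] to convert.
#'
#' @param x Square numeric matrix with entries in `[0, 1]` and columns
#'   summing to 1 (within 1e-8).
#' @return The validated matrix with class `misclass_matrix`.
#' @examples
#' misclass_matrix(matrix(c(0.8, 0.2, 0.2, 0.8), 2))
#' @export
misclass_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) abort("A misclassification matrix must be square.")
  if (any(!is.finite(x)) || any(x < -1e-10) || any(x > 1 + 1e-10)) {
    abort("Misclassification probabilities must lie in [0, 1].")
  }
  if (max(abs(colSums(x) - 1)) > 1e-8) {
    abort("Each column of a misclassification matrix must sum to 1 (column-stochastic: columns condition on the true class).")
  }
  x[x < 0] <- 0
  structure(x, class = c("misclass_matrix", "matrix", "array"))
}

#' @export
print.misclass_matrix <- function(x, ...) {
  cat(sprintf("Misclassification matrix (column-stochastic, %d classes)\n", ncol(x)))
  print(unclass(x), digits = 4)
  invisible(x)
}

#' Real matrix power of a misclassification matrix
#'
#' Computes \eqn{\Pi^\lambda = E \Lambda^\lambda E^{-1}} through the spectral
#' decomposition, the machinery that lets the mcsimex algorithm dial label
#' noise continuously: \eqn{\lambda = 0} gives the identity, \eqn{\lambda = 1}
#' the observed misclassification, larger \eqn{\lambda} more noise, and
#' \eqn{\lambda = -1} the (formal) inverse.
#'
#' The power is only defined when all eigenvalues are real and strictly
#' positive (see [misclass_existence()]). Tiny negative entries from
#' floating-point round-off (> -1e-10) are clipped to 0 and columns
#' renormalised; genuinely negative entries raise an error for
#' `lambda >= 0`.
#'
#' @param pi A [misclass_matrix()] (or coercible matrix).
#' @param lambda Real exponent >= -1.
#' @return For `lambda >= 0` a `misclass_matrix`; for negative exponents a
#'   plain matrix (the inverse direction need not be stochastic).
#' @examples
#' Pi <- misclass_matrix(matrix(c(0.8, 0.2, 0.2, 0.8), 2))
#' misclass_power(Pi, 0.5)
#' @export
misclass_power <- function(pi, lambda) {
  pi <- as_misclass(pi)
  check_scalar_number(lambda, "lambda", -1, Inf)
  dec <- spectral_decompose(pi)
  out <- dec$vectors %*% diag(dec$values^lambda, length(dec$values)) %*% dec$inverse
  out <- Re(out)
  if (lambda >= 0) {
    if (min(out) < -1e-10) {
      abort(sprintf(
        "Pi^%g has negative entries (min %.3g): the power is not a misclassification matrix; see misclass_existence().",
        lambda, min(out)))
    }
    out[out < 0] <- 0
    out <- sweep(out, 2L, colSums(out), "/")
    out <- misclass_matrix(out)
  }
  out
}

# Eigendecomposition with the existence checks required for real powers:
# all eigenvalues real (imaginary part below tolerance) and strictly positive.
spectral_decompose <- function(pi, tol = 1e-10) {
  dec <- eigen(unclass(pi))
  if (max(abs(Im(dec$values))) > tol) {
    abort("Power undefined: the misclassification matrix has complex eigenvalues (existence criterion violated).")
  }
  values <- Re(dec$values)
  if (min(values) <= tol) {
    abort("Power undefined: the misclassification matrix has non-positive eigenvalues (existence criterion violated).")
  }
  vectors <- Re(dec$vectors)
  list(values = values, vectors = vectors, inverse = solve(vectors))
}

#' Existence diagnostics for misclassification-matrix powers
#'
#' Reports whether \eqn{\Pi^\lambda} exists and remains a misclassification
#' matrix over a grid of exponents in `[0, lambda_max]`: eigenvalues must be
#' real and strictly positive, and every power on the grid must have
#' non-negative entries. A 2 x 2 matrix with both diagonal entries above 0.5
#' always passes; a diagonal below 0.5 yields a negative eigenvalue and
#' fails.
#'
#' @param pi Matrix to check (square, column-stochastic).
#' @param lambda_max Largest exponent of interest (e.g. the top of the
#'   mcsimex grid).
#' @param n_grid Number of grid points.
#' @return List with `ok` (logical), `eigenvalues`, `eigen_ok`, and `grid`
#'   (a tibble of `lambda` and the minimum matrix entry at that power).
#' @export
misclass_existence <- function(pi, lambda_max = 2, n_grid = 81) {
  pi <- as_misclass(pi)
  check_scalar_number(lambda_max, "lambda_max", 0, Inf, strict_lower = TRUE)
  dec <- eigen(unclass(pi), only.values = TRUE)
  eigen_ok <- max(abs(Im(dec$values))) <= 1e-10 && min(Re(dec$values)) > 1e-10
  lam <- seq(0, lambda_max, length.out = n_grid)
  if (eigen_ok) {
    full <- spectral_decompose(pi)
    min_entry <- vapply(lam, function(l) {
      m <- Re(full$vectors %*% diag(full$values^l, length(full$values)) %*% full$inverse)
      min(m)
    }, numeric(1))
  } else {
    min_entry <- rep(NA_real_, n_grid)
  }
  grid <- tibble(lambda = lam, min_entry = min_entry)
  ok <- eigen_ok && all(min_entry > -1e-10)
  list(ok = ok, eigenvalues = dec$values, eigen_ok = eigen_ok, grid = grid)
}

#' Estimate the misclassification matrix from a fitted clustering
#'
#' Monte Carlo procedure: for each class j, draw `n_mc` feature vectors from
#' the inferred class-j Gaussian (the mixture component for a GMM; for
#' k-means, the class-conditional Gaussian estimated by EM from the
#' partition), classify each draw under the inferred class model (maximum
#' posterior for GMM; shortest distance to the inferred class means for
#' k-means), and set \eqn{\pi_{ij}} to the fraction of class-j draws
#' assigned to class i. Columns sum to 1 by construction.
#'
#' Align the assignment to reference classes first if downstream results
#' must be expressed in reference class order.
#'
#' @param assignment A fitted [cluster_classes()] result (`"gmm"` or
#'   `"kmeans"`; fuzzy c-means carries no generative model).
#' @param n_mc Monte Carlo draws per class (default 100000).
#' @param seed Optional integer seed.
#' @return A [misclass_matrix()].
#' @export
estimate_misclass <- function(assignment, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(assignment, "class_assignment"))
  n_mc <- check_count(n_mc, "n_mc")
  mod <- assignment$model
  k <- assignment$k
  if (assignment$method == "cmeans" || is.null(mod$sigma)) {
    abort("The fitted clustering has no generative model; use \"gmm\" or \"kmeans\".")
  }
  means <- mod$mean
  with_seed_if(seed, {
    cols <- vapply(seq_len(k), function(j) {
      draws <- rmvnorm_chol(n_mc, means[j, ], mod$sigma[[j]])
      colnames(draws) <- assignment$features
      pred <- if (assignment$method == "kmeans") {
        # shortest distance to the inferred class means
        row_argmax(-center_dist2(draws, means))
      } else {
        predict(assignment, draws)$labels
      }
      tabulate(pred, k) / n_mc
    }, numeric(k))
    misclass_matrix(cols)
  })
}

#' Out-of-bag bootstrap estimation of the misclassification matrix
#'
#' For each bootstrap replicate, rows are resampled with replacement, a GMM
#' is fitted to the in-bag rows and aligned to the reference labels, the
#' out-of-bag rows are classified by the in-bag fit, and the confusion of
#' predicted versus reference labels on the out-of-bag rows is
#' column-normalised into a misclassification matrix. Because the matrix is
#' re-estimated on fresh resamples, averaging over replicates ("average MC")
#' or feeding each replicate's matrix into a full bootstrap propagates the
#' uncertainty of the matrix itself.
#'
#' A reference class that never appears out-of-bag leaves its column
#' undefined; such columns are imputed with the element-wise average of the
#' other replicates, with a warning.
#'
#' @param data Data frame with feature columns.
#' @param reference Integer reference labels in 1..k (e.g. the full-data
#'   clustering), length nrow(data).
#' @param n_boot Number of bootstrap replicates.
#' @param k Number of classes.
#' @param features Feature column names (default `z*` columns).
#' @param method Clustering method refitted per replicate.
#' @param seed Optional integer seed.
#' @return List with `matrices` (length `n_boot` list of
#'   [misclass_matrix()]) and `average` (their element-wise mean, itself
#'   column-stochastic).
#' @export
estimate_misclass_oob <- function(data, reference, n_boot, k = 2,
                                  features = NULL, method = "gmm",
                                  seed = NULL) {
  n_boot <- check_count(n_boot, "n_boot")
  X <- extract_features(data, features)
  n <- nrow(X)
  reference <- check_labels(pull_labels(data, reference), k, "reference")
  seeds <- derive_seeds(seed, n_boot)
  raw <- vector("list", n_boot)
  n_imputed <- 0L
  for (b in seq_len(n_boot)) {
    raw[[b]] <- with_seed_if(seeds[b], {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      fit <- cluster_classes(as.data.frame(X[idx, , drop = FALSE]),
                             method = method, k = k)
      fit <- align_classes(fit, reference[idx])
      pred <- predict(fit, X[oob, , drop = FALSE])$labels
      conf <- table(factor(pred, seq_len(k)), factor(reference[oob], seq_len(k)))
      counts <- matrix(as.numeric(conf), k, k)
      tot <- colSums(counts)
      out <- sweep(counts, 2L, pmax(tot, 1), "/")
      out[, tot == 0] <- NA_real_
      out
    })
  }
  mean_mat <- apply(simplify2array(raw), c(1, 2), mean, na.rm = TRUE)
  matrices <- lapply(raw, function(m) {
    bad <- which(is.na(m[1, ]))
    if (length(bad)) {
      n_imputed <<- n_imputed + length(bad)
      m[, bad] <- mean_mat[, bad]
    }
    misclass_matrix(m)
  })
  if (n_imputed > 0L) {
    warn(sprintf("%d out-of-bag column(s) had no observations and were imputed with the across-replicate average.",
                 n_imputed))
  }
  avg <- apply(simplify2array(lapply(matrices, unclass)), c(1, 2), mean)
  list(matrices = matrices, average = misclass_matrix(avg))
}

as_misclass <- function(pi) {
  if (inherits(pi, "misclass_matrix")) pi else misclass_matrix(pi)
}

#' Read or write a misclassification matrix as CSV
#'
#' Plain CSV with class labels as header row and first column; entries are
#' the column-stochastic probabilities \eqn{P(H^* = i \mid H = j)}. Matrices
#' stored in the transposed (row-stochastic) convention can be converted
#' with [t()] before writing or after reading.
#'
#' @param path File path.
#' @return `read_misclass()` returns a [misclass_matrix()];
#'   `write_misclass()` invisibly returns `path`.
#' @export
read_misclass <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  misclass_matrix(m)
}

#' @rdname read_misclass
#' @param pi A [misclass_matrix()] (or coercible matrix).
#' @export
write_misclass <- function(pi, path) {
  pi <- as_misclass(pi)
  m <- unclass(pi)
  dimnames(m) <- list(paste0("class", seq_len(nrow(m))),
                      paste0("class", seq_len(ncol(m))))
  utils::write.csv(as.data.frame(m), path)
  invisible(path)
}
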