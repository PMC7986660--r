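#' Cluster observations and return labels with class probabilities
#'
#' Fits one of three unsupervised clustering procedures to the feature
#' columns of `data` and returns hard class labels together with an
#' n x k row-stochastic matrix of class probabilities:
#'
#' * `"gmm"` — Gaussian mixture with unconstrained covariances, fitted by EM
#'   (k-means partition as starting values); probabilities are the posterior
#'   component responsibilities.
#' * `"kmeans"` — k-means with multiple restarts; probabilities are one-hot
#'   (a hard algorithm). The fitted object additionally records per-cluster
#'   proportions and centers, plus class-conditional Gaussian parameters
#'   estimated by EM from the k-means partition, so that a misclassification
#'   matrix can be estimated from the fit (raw member moments would be
#'   truncated at the cluster boundary and understate within-class spread).
#' * `"cmeans"` — fuzzy c-means; probabilities are the fuzzy memberships.
#'
#' Hard labels are the row-wise argmax of the probability matrix, ties
#' broken toward the lowest class index. Cluster indices are arbitrary until
#' aligned to a reference with [align_classes()].
#'
#' @param data Data frame with feature columns.
#' @param method One of `"gmm"`, `"kmeans"`, `"cmeans"`.
#' @param k Number of classes (>= 2).
#' @param features Character vector of feature column names; defaults to all
#'   columns named `z1`, `z2`, ...
#' @param fuzzifier Fuzzy c-means fuzzification exponent (> 1); the
#'   conventional default is 2. As the fuzzifier grows, memberships flatten
#'   toward 1/k.
#' @param nstart Number of random restarts for the k-means step.
#' @param max_iter Maximum EM / Lloyd / c-means iterations.
#' @param seed Optional integer seed (restart randomness).
#' @return An object of class `class_assignment`: list with `labels`
#'   (integer vector), `posterior` (n x k matrix, rows summing to 1),
#'   `model` (method-specific fitted parameters), `method`, `k`,
#'   `features`, `n`.
#' @examples
#' sim <- simulate_mixture(two_class_mixture(), 200, seed = 1)
#' ca <- cluster_classes(sim, "gmm", k = 2, seed = 1)
#' table(ca$labels, sim$true_class)
#' @export
cluster_classes <- function(data, method = c("gmm", "kmeans", "cmeans"), k = 2,
                            features = NULL, fuzzifier = 2, nstart = 10,
                            max_iter = 500, seed = NULL) {
  method <- match.arg(method)
  k <- check_count(k, "k", min = 2L)
  X <- extract_features(data, features)
  n <- nrow(X)
  if (n <= k) abort("Need more observations than classes.")
  if (!all(is.finite(X))) abort("Features must be finite.")
  if (nrow(unique(X)) < k) {
    abort("Fewer distinct feature rows than classes; clustering is degenerate.")
  }
  fit <- with_seed_if(seed, switch(
    method,
    gmm = fit_gmm_em(X, k, nstart, max_iter),
    kmeans = fit_kmeans_gauss(X, k, nstart, max_iter),
    cmeans = fit_cmeans(X, k, fuzzifier, max_iter)
  ))
  posterior <- fit$posterior
  colnames(posterior) <- paste0("class", seq_len(k))
  structure(
    list(labels = row_argmax(posterior), posterior = posterior,
         model = fit$model, method = method, k = k,
         features = colnames(X), n = n),
    class = "class_assignment"
  )
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("<class_assignment> %s, %d classes, n = %d\n", x$method, x$k, x$n))
  cat("cluster sizes:", tabulate(x$labels, x$k), "\n")
  invisible(x)
}

#' @describeIn cluster_classes Per-observation tibble: `.class` plus one
#'   probability column per class.
#' @param x,object A `class_assignment`.
#' @param ... Unused.
#' @export
tidy.class_assignment <- function(x, ...) {
  out <- as_tibble(x$posterior, .name_repair = "minimal")
  names(out) <- paste0(".p", seq_len(x$k))
  dplyr::bind_cols(tibble(.class = x$labels), out)
}

# EM fit of a k-component Gaussian mixture, covariance structure selected by
# BIC among spherical (EII), diagonal (EEI), shared (EEE) and unconstrained
# (VVV) parameterisations, starting from a multi-restart k-means partition.
fit_gmm_em <- function(X, k, nstart, max_iter,
                       models = c("EII", "EEI", "EEE", "VVV")) {
  km <- kmeans(X, k, nstart = nstart, iter.max = 50L)
  em_from_partition(X, km$cluster, k, max_iter, models)
}

em_from_partition <- function(X, labels, k, max_iter,
                              models = c("EII", "EEI", "EEE", "VVV")) {
  z0 <- mclust::unmap(labels, groups = seq_len(k))
  ctrl <- mclust::emControl(itmax = max_iter)
  best <- NULL
  best_bic <- -Inf
  for (mod in models) {
    fit <- tryCatch(
      do.call(utils::getFromNamespace(paste0("me", mod), "mclust"),
              list(data = X, z = z0, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik %||% NA_real_) ||
        anyNA(fit$parameters$pro)) next
    b <- as.numeric(mclust::bic(mod, fit$loglik, n = nrow(X), d = ncol(X), G = k))
    if (is.finite(b) && b > best_bic) {
      best_bic <- b
      best <- fit
      best$modelName <- mod
    }
  }
  if (is.null(best)) {
    abort(sprintf("EM for the Gaussian mixture failed to converge within %d iterations.",
                  max_iter))
  }
  post <- best$z
  post <- post / rowSums(post)
  model <- list(
    pro = best$parameters$pro,
    mean = t(best$parameters$mean),                 # k x p
    sigma = lapply(seq_len(k), function(j) best$parameters$variance$sigma[, , j]),
    loglik = best$loglik, model_name = best$modelName
  )
  list(posterior = post, model = model)
}

fit_kmeans_gauss <- function(X, k, nstart, max_iter) {
  km <- kmeans(X, k, nstart = nstart, iter.max = max_iter)
  labels <- km$cluster
  post <- mclust::unmap(labels, groups = seq_len(k))
  # Class-conditional Gaussians for misclassification estimation come from
  # an EM fit started at the k-means partition: raw member moments are
  # truncated at the cluster boundary and understate the within-class
  # spread. The classification rule stays nearest-center.
  em <- tryCatch(em_from_partition(X, labels, k, max_iter),
                 error = function(e) NULL)
  if (!is.null(em)) {
    # match EM components to k-means clusters by label agreement
    em_lab <- row_argmax(em$posterior)
    conf <- table(factor(em_lab, seq_len(k)), factor(labels, seq_len(k)))
    perms <- all_permutations(k)
    scores <- apply(perms, 1L, function(p) sum(conf[cbind(seq_len(k), p)]))
    perm <- perms[which.max(scores), ]
    inv <- order(perm)
    means <- em$model$mean[inv, , drop = FALSE]
    covs <- em$model$sigma[inv]
  } else {
    means <- km$centers
    covs <- lapply(seq_len(k), function(j) {
      members <- X[labels == j, , drop = FALSE]
      cov(members)
    })
  }
  model <- list(centers = km$centers, pro = tabulate(labels, k) / nrow(X),
                mean = means, sigma = covs, withinss = km$tot.withinss)
  list(posterior = post, model = model)
}

fit_cmeans <- function(X, k, fuzzifier, max_iter) {
  if (!is.numeric(fuzzifier) || length(fuzzifier) != 1L || fuzzifier <= 1) {
    abort("`fuzzifier` must be a single number > 1.")
  }
  fit <- e1071::cmeans(X, centers = k, m = fuzzifier, iter.max = max_iter)
  post <- fit$membership
  post <- post / rowSums(post)
  list(posterior = post,
       model = list(centers = fit$centers, fuzzifier = fuzzifier))
}

#' Align cluster indices to reference classes
#'
#' Cluster labels are only identified up to permutation; before comparing a
#' fitted clustering with reference classes (e.g. the generating classes in
#' a simulation) the indices must be matched. This permutes labels,
#' probability columns and fitted-model components jointly to maximise
#' agreement with the reference, by exhaustive search over all k!
#' permutations of the confusion matrix (k is small).
#'
#' @param assignment A [cluster_classes()] result.
#' @param reference Integer reference labels in 1..k, length n.
#' @return The aligned `class_assignment`. Idempotent: aligning twice to the
#'   same reference changes nothing.
#' @export
align_classes <- function(assignment, reference) {
  stopifnot(inherits(assignment, "class_assignment"))
  k <- assignment$k
  reference <- check_labels(reference, k, "reference")
  if (length(reference) != assignment$n) {
    abort("`reference` must have one label per clustered observation.")
  }
  if (k > 8L) abort("Exhaustive alignment supports at most 8 classes.")
  conf <- table(factor(assignment$labels, seq_len(k)),
                factor(reference, seq_len(k)))
  perms <- all_permutations(k)
  scores <- apply(perms, 1L, function(p) sum(conf[cbind(seq_len(k), p)]))
  perm <- perms[which.max(scores), ]   # new index for each old cluster
  permute_assignment(assignment, perm)
}

# Relabel clusters: old cluster j becomes class perm[j].
permute_assignment <- function(assignment, perm) {
  inv <- order(perm)
  assignment$labels <- perm[assignment$labels]
  assignment$posterior <- assignment$posterior[, inv, drop = FALSE]
  colnames(assignment$posterior) <- paste0("class", seq_along(perm))
  mod <- assignment$model
  for (fld in c("pro", "loglik_contrib")) {
    if (!is.null(mod[[fld]])) mod[[fld]] <- mod[[fld]][inv]
  }
  if (!is.null(mod$mean)) mod$mean <- mod$mean[inv, , drop = FALSE]
  if (!is.null(mod$centers)) mod$centers <- mod$centers[inv, , drop = FALSE]
  if (!is.null(mod$sigma)) mod$sigma <- mod$sigma[inv]
  assignment$model <- mod
  assignment
}

#' Classify new observations under a fitted clustering
#'
#' Applies the fitted rule of a `class_assignment` to new feature vectors:
#' Bayes posterior under the fitted mixture for `"gmm"`, nearest center for
#' `"kmeans"`, and the standard membership formula for `"cmeans"`.
#'
#' @param object A `class_assignment`.
#' @param newdata Matrix or data frame of features (same columns as used in
#'   the fit).
#' @param ... Unused.
#' @return List with `labels` and `posterior` for the new observations.
#' @export
predict.class_assignment <- function(object, newdata, ...) {
  X <- extract_features(newdata, object$features)
  post <- switch(
    object$method,
    gmm = gmm_posterior(X, object$model),
    kmeans = {
      d2 <- center_dist2(X, object$model$centers)
      mclust::unmap(row_argmax(-d2), groups = seq_len(object$k))
    },
    cmeans = {
      d2 <- center_dist2(X, object$model$centers)
      cmeans_membership(d2, object$model$fuzzifier)
    }
  )
  colnames(post) <- paste0("class", seq_len(object$k))
  list(labels = row_argmax(post), posterior = post)
}

gmm_posterior <- function(X, model) {
  k <- length(model$pro)
  logd <- vapply(seq_len(k), function(j) {
    log(model$pro[j]) + dmvnorm_log(X, model$mean[j, ], model$sigma[[j]])
  }, numeric(nrow(X)))
  logd <- logd - apply(logd, 1L, max)
  w <- exp(logd)
  w / rowSums(w)
}

center_dist2 <- function(X, centers) {
  d2 <- matrix(0, nrow(X), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d2[, j] <- rowSums(sweep(X, 2L, centers[j, ])^2)
  }
  d2
}

cmeans_membership <- function(d2, fuzzifier) {
  d2 <- pmax(d2, 1e-300)
  u <- d2^(-1 / (fuzzifier - 1))
  u / rowSums(u)
}

extract_features <- function(data, features = NULL) {
  if (is.matrix(data)) {
    X <- data
    if (!is.null(features) && !is.null(colnames(X))) {
      X <- X[, features, drop = FALSE]
    }
    return(X)
  }
  if (is.null(features)) {
    features <- grep("^z[0-9]+$", names(data), value = TRUE)
    if (!length(features)) {
      abort("No feature columns found; name them z1, z2, ... or pass `features`.")
    }
  }
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    abort(sprintf("Feature column(s) not found: %s.", paste(missing, collapse = ", ")))
  }
  as.matrix(data[features])
}
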