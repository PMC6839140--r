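## cluster_purity: Ward hierarchical clustering of samples on signature
## probes, dendrogram cutting with the purity statistic over cutoffs 1..K,
## and PCA projection with a linear separation check.

#' Hierarchical clustering of samples
#'
#' Samples (columns) are clustered with Ward linkage on either the Euclidean
#' distance or the correlation distance 1 - r between sample profiles.
#' Merge heights follow the Lance-Williams Ward recurrence on distances
#' (hclust `ward.D2`).
#'
#' @param betas probes x samples matrix restricted to the signature probes.
#' @param distance `"euclidean"` or `"one_minus_r"`.
#' @return an `hclust` object over samples.
#' @export
hierarchical_cluster <- function(betas, distance = c("euclidean", "one_minus_r")) {
  distance <- match.arg(distance)
  if (ncol(betas) < 2) stop("need >= 2 samples", call. = FALSE)
  if (nrow(betas) < 1) stop("need >= 1 probe", call. = FALSE)
  X <- t(betas)
  if (distance == "euclidean") {
    d <- stats::dist(X)
  } else {
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) {
      stop("correlation distance undefined for constant sample(s): ",
           paste(rownames(X)[sds == 0], collapse = ", "), call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(betas))
  }
  stats::hclust(d, method = "ward.D2")
}

#' Cluster purity over dendrogram cutoffs 1..max_k
#'
#' At each cutoff k the tree is cut into k clusters; each cluster is
#' assigned its most represented label and its purity is the fraction of
#' members carrying that label. Majority ties are broken by the declared
#' label order (TN > HER2p > luminal, or the factor level order of
#' `labels`). Both the size-weighted mean purity and the maximum cluster
#' purity are reported per cutoff.
#'
#' @param hc `hclust` object from [hierarchical_cluster()].
#' @param labels named factor of sample labels (three-class subtype or a
#'   binary TN / non-TN factor).
#' @param max_k largest cutoff (default 10, truncated to n samples).
#' @return list with `per_cutoff` (data.frame cutoff, cluster_id, size,
#'   majority_class, purity_fraction) and `summary` (data.frame cutoff,
#'   overall_weighted_purity, max_cluster_purity).
#' @export
purity_curve <- function(hc, labels, max_k = 10) {
  lab <- labels[hc$labels]
  if (anyNA(lab)) stop("labels must cover every clustered sample", call. = FALSE)
  n <- length(lab)
  max_k <- min(max_k, n)
  per <- list(); summ <- list()
  for (k in seq_len(max_k)) {
    cl <- stats::cutree(hc, k = k)
    rows <- lapply(sort(unique(cl)), function(ci) {
      members <- lab[cl == ci]
      counts <- table(members)            # table order = factor level order,
      maj <- names(counts)[which.max(counts)]  # so which.max ties break by it
      data.frame(cutoff = k, cluster_id = ci, size = length(members),
                 majority_class = maj,
                 purity_fraction = max(counts) / length(members),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    per[[k]] <- rows
    summ[[k]] <- data.frame(
      cutoff = k,
      overall_weighted_purity = sum(rows$size * rows$purity_fraction) / n,
      max_cluster_purity = max(rows$purity_fraction))
  }
  list(per_cutoff = do.call(rbind, per), summary = do.call(rbind, summ))
}

#' PCA projection of samples
#'
#' Probe-wise centered PCA of the samples via singular value decomposition.
#' For determinism each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param betas probes x samples matrix.
#' @param k number of components (truncated to the matrix rank with a
#'   warning).
#' @return list with `scores` (samples x k), `explained` (variance
#'   fractions, non-increasing) and `loadings` (probes x k).
#' @export
pca_project <- function(betas, k = 3) {
  if (ncol(betas) < 2) stop("need >= 2 samples", call. = FALSE)
  X <- t(betas)                      # samples x probes
  Xc <- scale(X, center = TRUE, scale = FALSE)
  s <- svd(Xc)
  pos <- s$d > max(s$d) * 1e-10
  rank <- sum(pos)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncating")
    k <- rank
  }
  d <- s$d[seq_len(k), drop = FALSE]
  U <- s$u[, seq_len(k), drop = FALSE]
  V <- s$v[, seq_len(k), drop = FALSE]
  ## sign convention: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- sweep(U, 2, s$d[seq_len(k)], `*`)
  rownames(scores) <- colnames(betas)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(V) <- rownames(betas)
  colnames(V) <- colnames(scores)
  explained <- s$d^2 / sum(s$d^2)
  list(scores = scores, explained = explained[seq_len(k)], loadings = V)
}

#' Linear separation of two classes in PCA score space
#'
#' Fits a maximum-margin style linear boundary (L2-regularized squared-hinge
#' loss, the smooth SVM surrogate, minimized with BFGS; deterministic) in
#' the first `n_components` scores and reports the fraction of training
#' samples on the correct side.
#'
#' @param projection result of [pca_project()].
#' @param binary_labels named factor/character with exactly two classes
#'   over the projected samples; the first factor level is coded -1.
#' @param n_components number of leading components to use (2 or 3).
#' @param lambda ridge penalty on the weights (default 1e-3).
#' @return list with `w` (weights), `b` (intercept), `accuracy`, and
#'   `predicted` (named class labels).
#' @export
linear_separation <- function(projection, binary_labels, n_components = 2,
                              lambda = 1e-3) {
  S <- projection$scores
  n_components <- min(n_components, ncol(S))
  X <- S[, seq_len(n_components), drop = FALSE]
  lab <- factor(binary_labels[rownames(X)])
  if (nlevels(lab) != 2 || anyNA(lab)) {
    stop("binary_labels must give exactly two classes over all samples",
         call. = FALSE)
  }
  y <- ifelse(as.integer(lab) == 1, -1, 1)
  sc <- apply(X, 2, function(c) max(stats::sd(c), 1e-12))
  Xs <- sweep(X, 2, sc, `/`)
  obj <- function(par) {
    w <- par[-1]; b <- par[1]
    m <- 1 - y * (Xs %*% w + b)
    sum(pmax(m, 0)^2) / nrow(Xs) + lambda * sum(w^2)
  }
  grad <- function(par) {
    w <- par[-1]; b <- par[1]
    m <- as.vector(1 - y * (Xs %*% w + b))
    act <- m > 0
    gw <- -2 * t(Xs[act, , drop = FALSE]) %*% (y[act] * m[act]) / nrow(Xs) +
      2 * lambda * w
    gb <- -2 * sum(y[act] * m[act]) / nrow(Xs)
    c(gb, as.vector(gw))
  }
  fit <- stats::optim(rep(0, n_components + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- fit$par[-1] / sc
  b <- fit$par[1]
  side <- as.vector(X %*% w + b)
  pred_class <- levels(lab)[ifelse(side >= 0, 2, 1)]
  list(w = w, b = b,
       accuracy = mean(pred_class == as.character(lab)),
       predicted = setNames(pred_class, rownames(X)))
}
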