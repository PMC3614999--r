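group_stats <- function(X, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  g <- length(groups)
  n <- nrow(X); p <- ncol(X)
  if (g < 2L) stop("CVA needs at least 2 groups")
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes < 2L)) stop("every group needs at least 2 members")
  if (n - g < 1L) stop("too few specimens for a within-group covariance")
  means <- matrix(0, g, p, dimnames = list(groups, colnames(X)))
  W <- matrix(0, p, p)
  for (gi in seq_len(g)) {
    Xi <- X[labels == groups[gi], , drop = FALSE]
    means[gi, ] <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, means[gi, ]))
  }
  list(groups = groups, sizes = as.integer(sizes), means = means,
       W = W / (n - g))
}

# Pairwise squared Mahalanobis distances between group means in the pooled
# within-group metric (Cholesky solve; no explicit inverse).
mahalanobis_matrix <- function(means, W) {
  g <- nrow(means)
  R <- chol(W)
  D2 <- matrix(0, g, g, dimnames = list(rownames(means), rownames(means)))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    d <- backsolve(R, means[i, ] - means[j, ], transpose = TRUE)
    D2[i, j] <- D2[j, i] <- sum(d^2)
  }
  D2
}

#' Canonical variate analysis
#'
#' Linear ordination maximizing between-group relative to pooled within-group
#' variance: solves the generalized eigenproblem of the between-group
#' covariance against the pooled within-group covariance (divisor \eqn{n-g})
#' by Cholesky whitening.  When the within-group covariance is singular
#' (\eqn{p > n-g} or collinear variables), features are first projected onto
#' their principal components, retaining components with eigenvalue >
#' \code{pc_tol}, as geometric-morphometric practice dictates for shape data.
#'
#' @param features \code{n x p} numeric matrix (e.g. the W' partial-warp
#'   scores) or a \code{partial_warp_matrix}.
#' @param labels Group labels, length \code{n}.
#' @param pc_tol Eigenvalue threshold for the rank-reduction step (default 1e-10).
#' @return A \code{cva_result}: \code{canonical_axes} (coefficients in the
#'   original feature space, pooled within-group variance of each score = 1),
#'   \code{scores} (\code{n x} axes, centered on the grand mean),
#'   \code{eigenvalues}, \code{group_means} (canonical space),
#'   \code{mahalanobis} (\code{g x g} distances, not squared) and bookkeeping.
#' @export
fit_cva <- function(features, labels, pc_tol = 1e-10) {
  if (inherits(features, "partial_warp_matrix")) {
    if (missing(labels) || is.null(labels)) labels <- features$taxon
    features <- features$scores
  }
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("label count mismatch")
  grand <- colMeans(X)
  Xc <- sweep(X, 2, grand)
  st <- group_stats(Xc, labels)
  P <- NULL
  if (min(eigen(st$W, symmetric = TRUE, only.values = TRUE)$values) < pc_tol) {
    # rank reduction on the total covariance when the within metric is singular
    pca <- eigen(stats::cov(Xc), symmetric = TRUE)
    keep <- which(pca$values > pc_tol)
    n_g <- nrow(X) - length(st$groups)
    keep <- keep[seq_len(min(length(keep), n_g))]
    if (length(keep) < 1L) stop("rank deficiency: no usable feature dimensions")
    P <- pca$vectors[, keep, drop = FALSE]
    Xc <- Xc %*% P
    st <- group_stats(Xc, labels)
    if (min(eigen(st$W, symmetric = TRUE, only.values = TRUE)$values) < pc_tol) {
      stop("rank deficiency: within-group covariance singular even after ",
           "principal-component reduction; reduce dimensions")
    }
  }
  g <- length(st$groups); n <- nrow(Xc); p <- ncol(Xc)
  B <- crossprod(st$means * sqrt(st$sizes)) / (n - 1)
  Rw <- chol(st$W)
  M <- backsolve(Rw, t(backsolve(Rw, B, transpose = TRUE)), transpose = TRUE)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(g - 1L, p)
  A <- backsolve(Rw, eig$vectors[, seq_len(n_axes), drop = FALSE])
  if (!is.null(P)) A <- P %*% A
  colnames(A) <- paste0("CV", seq_len(n_axes))
  scores <- sweep(X, 2, grand) %*% A
  group_means <- apply(scores, 2, function(s) tapply(s, factor(labels, levels = st$groups), mean))
  D2 <- mahalanobis_matrix(st$means, st$W)
  structure(list(canonical_axes = A,
                 scores = scores,
                 eigenvalues = eig$values[seq_len(n_axes)],
                 group_means = group_means,
                 mahalanobis = sqrt(D2),
                 groups = st$groups,
                 labels = labels,
                 grand_mean = grand,
                 reduction = P),
            class = "cva_result")
}

#' Leave-one-out cross-validated classification on group means
#'
#' For each specimen the group means and pooled within-group covariance are
#' re-estimated without it, and the specimen is assigned to the group with the
#' smallest Mahalanobis distance in the refitted metric (uniform priors).
#' When \eqn{p > n - g - 1} the features are first reduced once by principal
#' components on the full data (the superimposition and basis are likewise not
#' refitted per fold).
#'
#' @inheritParams fit_cva
#' @return A \code{confusion_matrix}: \code{labels}, \code{counts} (true x
#'   assigned), \code{overall_correct_pct}, \code{per_group_misclassified_pct}.
#' @export
loo_crossvalidate_cva <- function(features, labels, pc_tol = 1e-10) {
  if (inherits(features, "partial_warp_matrix")) {
    if (missing(labels) || is.null(labels)) labels <- features$taxon
    features <- features$scores
  }
  X <- as.matrix(features)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  g <- length(groups)
  n <- nrow(X)
  if (any(table(labels) < 2L)) {
    stop("leave-one-out needs every group size >= 2")
  }
  if (ncol(X) > n - g - 1L) {
    pca <- eigen(stats::cov(X), symmetric = TRUE)
    keep <- which(pca$values > pc_tol)
    keep <- keep[seq_len(min(length(keep), n - g - 1L))]
    X <- sweep(X, 2, colMeans(X)) %*% pca$vectors[, keep, drop = FALSE]
  }
  assigned <- character(n)
  for (i in seq_len(n)) {
    st <- group_stats(X[-i, , drop = FALSE], labels[-i])
    R <- chol(st$W)
    d2 <- apply(st$means, 1, function(m) {
      z <- backsolve(R, X[i, ] - m, transpose = TRUE); sum(z^2)
    })
    assigned[i] <- st$groups[which.min(d2)]
  }
  confusion_matrix(labels, assigned, groups)
}

confusion_matrix <- function(true, assigned, groups = sort(unique(true))) {
  counts <- table(factor(true, levels = groups), factor(assigned, levels = groups))
  counts <- unclass(counts)
  overall <- 100 * sum(diag(counts)) / sum(counts)
  mis <- 100 * (1 - diag(counts) / rowSums(counts))
  structure(list(labels = groups, counts = counts,
                 overall_correct_pct = overall,
                 per_group_misclassified_pct = mis),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Cross-validated confusion matrix (true x assigned):\n")
  print(x$counts)
  cat(sprintf("Overall correct: %.1f%%\n", x$overall_correct_pct))
  invisible(x)
}

#' Pairwise permutation test on Mahalanobis separation
#'
#' For each pair of groups, labels are permuted within the pair and the
#' Mahalanobis distance between the two permuted group means (in the pair's
#' pooled within-group metric) is recomputed;
#' \eqn{p = (1 + \#\{d_{perm} \ge d_{obs}\}) / (n_{perm} + 1)}.
#'
#' @inheritParams fit_cva
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param pc_tol Eigenvalue threshold for rank reduction, as in [fit_cva()].
#' @return \code{g x g} symmetric matrix of p-values (diagonal \code{NA}).
#' @export
cva_permutation_test <- function(features, labels, n_perm = 1000L, seed = 1L,
                                 pc_tol = 1e-10) {
  if (inherits(features, "partial_warp_matrix")) {
    if (missing(labels) || is.null(labels)) labels <- features$taxon
    features <- features$scores
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- as.matrix(features)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  g <- length(groups)
  pmat <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  set.seed(seed)
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    sel <- labels %in% c(groups[i], groups[j])
    Xp <- X[sel, , drop = FALSE]
    lp <- labels[sel]
    np <- nrow(Xp)
    if (ncol(Xp) > np - 3L) {
      pca <- eigen(stats::cov(Xp), symmetric = TRUE)
      keep <- which(pca$values > pc_tol)
      keep <- keep[seq_len(min(length(keep), np - 3L))]
      Xp <- sweep(Xp, 2, colMeans(Xp)) %*% pca$vectors[, keep, drop = FALSE]
    }
    obs <- pair_mahal2(Xp, lp)
    count <- 0L
    for (b in seq_len(n_perm)) {
      if (pair_mahal2(Xp, sample(lp)) >= obs) count <- count + 1L
    }
    pmat[i, j] <- pmat[j, i] <- (1 + count) / (n_perm + 1)
  }
  pmat
}

pair_mahal2 <- function(X, labels) {
  st <- group_stats(X, labels)
  d <- backsolve(chol(st$W), st$means[1, ] - st$means[2, ], transpose = TRUE)
  sum(d^2)
}
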