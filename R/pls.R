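#' Two-block partial least squares
#'
#' Singular value decomposition of the between-block covariance matrix
#' (divisor \eqn{n - 1}) between a shape block (typically the W' partial-warp
#' scores) and a genetic block (typically two PCoA axes).  Latent pairs are
#' ordered by singular value; scores are projections of the centered blocks on
#' the unit-norm weight vectors, and each pair's R is the Pearson correlation
#' of its paired scores.  A correlation-mode flag standardizes columns to unit
#' variance before the SVD.
#'
#' @param block1 \code{n x p} numeric matrix (shape block).
#' @param block2 \code{n x q} numeric matrix (genetic block), same \code{n}.
#' @param mode \code{"covariance"} (default) or \code{"correlation"}.
#' @return A \code{pls_result}: \code{shape_weights} (\code{p x m}),
#'   \code{genetic_weights} (\code{q x m}), \code{singular_values}
#'   (descending), \code{pair_correlations}, \code{linear_r2} (squared
#'   Pearson correlation of the first pair), \code{spearman_rho} (rank
#'   correlation of the first pair), \code{scores1}, \code{scores2};
#'   \code{m = min(p, q)}.
#' @export
two_block_pls <- function(block1, block2, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  X <- as.matrix(block1); Y <- as.matrix(block2)
  if (nrow(X) != nrow(Y)) stop("blocks must share specimens")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 specimens")
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  if (mode == "correlation") {
    X <- scale_nonconstant(X); Y <- scale_nonconstant(Y)
  }
  C <- crossprod(X, Y) / (n - 1)
  sv <- svd(C)
  m <- min(ncol(X), ncol(Y))
  U <- sv$u[, seq_len(m), drop = FALSE]
  V <- sv$v[, seq_len(m), drop = FALSE]
  s1 <- X %*% U
  s2 <- Y %*% V
  # orient each pair so its score correlation is non-negative
  for (j in seq_len(m)) {
    if (stats::sd(s1[, j]) > 0 && stats::sd(s2[, j]) > 0 &&
        stats::cor(s1[, j], s2[, j]) < 0) {
      V[, j] <- -V[, j]; s2[, j] <- -s2[, j]
    }
  }
  r <- vapply(seq_len(m), function(j) {
    if (stats::sd(s1[, j]) == 0 || stats::sd(s2[, j]) == 0) return(0)
    stats::cor(s1[, j], s2[, j])
  }, numeric(1))
  rho <- if (stats::sd(s1[, 1]) > 0 && stats::sd(s2[, 1]) > 0)
    stats::cor(s1[, 1], s2[, 1], method = "spearman") else 0
  structure(list(shape_weights = U, genetic_weights = V,
                 singular_values = sv$d[seq_len(m)],
                 pair_correlations = r,
                 linear_r2 = r[1]^2,
                 spearman_rho = rho,
                 scores1 = s1, scores2 = s2,
                 mode = mode, n = n),
            class = "pls_result")
}

scale_nonconstant <- function(M) {
  s <- apply(M, 2, stats::sd)
  s[s == 0] <- 1
  sweep(M, 2, s, "/")
}

#' Permutation test for two-block PLS
#'
#' Rows of the second block are permuted (breaking the specimen pairing) and
#' the per-pair statistic recomputed;
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(n_{perm} + 1)}, one-sided
#' upper tail.  For \eqn{n \le 7} an exhaustive mode enumerates all \eqn{n!}
#' row permutations and \eqn{p = \#\{stat \ge stat_{obs}\}/n!} (the identity
#' permutation included).
#'
#' @inheritParams two_block_pls
#' @param statistic \code{"R"} (pair correlation) or \code{"covariance"}
#'   (singular value).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all permutations; default \code{TRUE} when
#'   \code{n <= 7}.
#' @return Numeric vector of p-values, one per latent pair.
#' @export
pls_permutation_test <- function(block1, block2,
                                 statistic = c("R", "covariance"),
                                 n_perm = 999L, seed = 1L,
                                 mode = c("covariance", "correlation"),
                                 exhaustive = nrow(as.matrix(block1)) <= 7L) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("parameter error: n_perm must be >= 1")
  X <- as.matrix(block1); Y <- as.matrix(block2)
  n <- nrow(X)
  stat_of <- function(fit) {
    if (statistic == "R") abs(fit$pair_correlations) else fit$singular_values
  }
  obs <- stat_of(two_block_pls(X, Y, mode = mode))
  m <- length(obs)
  if (exhaustive) {
    perms <- all_permutations(n)
    counts <- integer(m)
    for (pi in seq_len(nrow(perms))) {
      s <- stat_of(two_block_pls(X, Y[perms[pi, ], , drop = FALSE], mode = mode))
      counts <- counts + as.integer(s >= obs - 1e-12)
    }
    return(counts / nrow(perms))
  }
  set.seed(seed)
  counts <- integer(m)
  for (b in seq_len(n_perm)) {
    s <- stat_of(two_block_pls(X, Y[sample.int(n), , drop = FALSE], mode = mode))
    counts <- counts + as.integer(s >= obs)
  }
  (1 + counts) / (n_perm + 1)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Group-level summary of a fitted PLS integration
#'
#' Per-group centroids in latent space, between- versus within-group spread
#' ratios per latent axis, and flags for specimens whose position along the
#' first genetic latent axis falls on the opposite half-plane from their
#' labeled group's majority -- the signature of a specimen whose genotype
#' disagrees with its morphological assignment.
#'
#' @param pls A \code{pls_result}.
#' @param labels Group labels, one per specimen.
#' @return An \code{integration_report}: \code{centroids1}, \code{centroids2}
#'   (group centroids on each block's latent axes), \code{spread_ratio}
#'   (between/within, per latent axis of block 2), \code{flagged} (specimen
#'   indices), \code{labels}.
#' @export
integration_report <- function(pls, labels) {
  labels <- as.character(labels)
  if (length(labels) != pls$n) stop("label count mismatch")
  groups <- sort(unique(labels))
  cent <- function(S) {
    t(vapply(groups, function(g) colMeans(S[labels == g, , drop = FALSE]),
             numeric(ncol(S))))
  }
  c1 <- cent(pls$scores1); c2 <- cent(pls$scores2)
  rownames(c1) <- rownames(c2) <- groups
  spread <- vapply(seq_len(ncol(pls$scores2)), function(j) {
    s <- pls$scores2[, j]
    within <- mean(vapply(groups, function(g) stats::var(s[labels == g]), numeric(1)))
    between <- stats::var(c2[, j])
    if (within <= 0) return(Inf)
    between / within
  }, numeric(1))
  # half-plane disagreement on the first genetic latent axis; only coherent
  # groups (>= 90% of members on one side) can flag their minority, so a
  # homogeneous group straddling zero flags nobody
  g1 <- pls$scores2[, 1]
  flagged <- integer(0)
  for (g in groups) {
    idx <- which(labels == g)
    pos <- mean(g1[idx] > 0)
    if (max(pos, 1 - pos) < 0.9) next
    maj <- if (pos >= 0.5) 1 else -1
    flagged <- c(flagged, idx[sign(g1[idx]) == -maj])
  }
  structure(list(centroids1 = c1, centroids2 = c2,
                 spread_ratio = spread,
                 flagged = sort(flagged),
                 flagged_id = rownames(pls$scores2)[sort(flagged)],
                 labels = labels),
            class = "integration_report")
}
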