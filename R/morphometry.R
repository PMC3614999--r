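#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from their
#' centroid; the size measure removed by Procrustes scaling.
#'
#' @param coords A \code{k x 2} numeric matrix of landmark coordinates.
#' @return Positive scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  cen <- colMeans(coords)
  cs <- sqrt(sum(sweep(coords, 2, cen)^2))
  if (cs <= .Machine$double.eps * nrow(coords)) {
    stop("degenerate configuration: all landmarks coincident")
  }
  cs
}

center_scale <- function(coords) {
  coords <- sweep(coords, 2, colMeans(coords))
  coords / sqrt(sum(coords^2))
}

# Proper (det = +1) least-squares rotation of x onto target, both centered.
optimal_rotation <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes superimposition
#'
#' Partial Procrustes fit: every configuration is translated to the origin,
#' scaled to unit centroid size, and iteratively rotated (proper rotations
#' only, no reflection) onto the running consensus by the least-squares SVD
#' rotation; the consensus is the coordinate-wise mean, itself renormalized to
#' unit centroid size.  Iteration stops when the consensus root-mean-square
#' change drops below \code{tol}.
#'
#' @param configs A \code{landmark_configs} object or a \code{k x 2 x n} array.
#' @param tol Convergence tolerance on the consensus change (default 1e-10).
#' @param max_iter Maximum number of consensus updates (default 100).
#' @return An \code{aligned_shapes} object: \code{coords} (\code{k x 2 x n}
#'   aligned array), \code{consensus} (\code{k x 2}, unit centroid size),
#'   \code{centroid_sizes} (original sizes), \code{specimen_id}, \code{taxon}.
#' @export
gpa_align <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (inherits(configs, "landmark_configs")) {
    arr <- configs$coords; ids <- configs$specimen_id; taxon <- configs$taxon
  } else {
    arr <- configs
    ids <- dimnames(arr)[[3]]
    if (is.null(ids)) ids <- paste0("specimen", seq_len(dim(arr)[3]))
    taxon <- rep(NA_character_, dim(arr)[3])
  }
  if (length(dim(arr)) != 3L || dim(arr)[2] != 2L) {
    stop("shape mismatch: expected a k x 2 x n coordinate array")
  }
  n <- dim(arr)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  sizes <- apply(arr, 3, centroid_size)
  aligned <- array(NA_real_, dim = dim(arr))
  for (i in seq_len(n)) aligned[, , i] <- center_scale(arr[, , i])
  consensus <- center_scale(aligned[, , 1])
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
    }
    new_consensus <- center_scale(apply(aligned, c(1, 2), mean))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("GPA failed to converge after ", max_iter,
         " iterations (last consensus change ", format(delta), ")")
  }
  # deterministic orientation: rotate the consensus onto its principal axes
  # (proper rotation only) and fix the overall sign so the landmark with the
  # largest |x| lies at positive x; makes the result input-order invariant
  pc <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  if (det(pc) < 0) pc[, 2] <- -pc[, 2]
  consensus <- consensus %*% pc
  if (consensus[which.max(abs(consensus[, 1])), 1] < 0) consensus <- -consensus
  dimnames(consensus) <- list(NULL, c("x", "y"))
  # final rotation onto the oriented consensus
  for (i in seq_len(n)) {
    aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
  }
  dimnames(aligned) <- list(NULL, c("x", "y"), ids)
  structure(list(coords = aligned, consensus = consensus,
                 centroid_sizes = sizes, specimen_id = ids, taxon = taxon),
            class = "aligned_shapes")
}

#' Procrustes distance between two aligned configurations
#'
#' Square root of the summed squared coordinate differences after the optimal
#' proper rotation of \code{b} onto \code{a}.  Both inputs must be centered and
#' of unit centroid size.
#'
#' @param a,b \code{k x 2} matrices, centered, unit centroid size.
#' @return Non-negative scalar; symmetric in its arguments.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch: unequal landmark counts")
  b <- b %*% optimal_rotation(b, a)
  sqrt(sum((a - b)^2))
}

#' Thin-plate-spline bending-energy basis of a consensus configuration
#'
#' Builds the TPS kernel \eqn{U(r) = r^2 \log r^2} over the consensus
#' landmarks, forms the bending-energy matrix (the upper-left \eqn{k \times k}
#' block of the inverse of the bordered kernel system), and eigen-decomposes
#' it.  For 2-D data the matrix has exactly 3 zero eigenvalues (the affine null
#' space); the \eqn{k-3} eigenvectors with positive eigenvalue are the
#' principal warps.  The uniform (affine) shape basis is the orthonormal
#' complement of size and rotation within the span of the linear maps of the
#' consensus, following the complement construction of Rohlf and Bookstein.
#'
#' @param consensus \code{k x 2} matrix, no two landmarks coincident.
#' @return A \code{bending_energy_basis}: \code{principal_warps} (\code{k x
#'   (k-3)} orthonormal columns, ascending bending energy),
#'   \code{bending_eigenvalues} (all \code{k}, ascending),
#'   \code{uniform_basis} (\code{2k x 2} orthonormal), \code{consensus}.
#' @export
bending_energy_basis <- function(consensus) {
  consensus <- as.matrix(consensus)
  k <- nrow(consensus)
  if (k < 4L) stop("need at least 4 landmarks for a bending-energy basis")
  d2 <- as.matrix(stats::dist(consensus))^2
  if (any(d2[upper.tri(d2)] < 1e-24)) {
    stop("singular kernel: coincident landmarks in consensus")
  }
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, consensus)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Linv <- solve(L)
  Be <- Linv[seq_len(k), seq_len(k)]
  Be <- (Be + t(Be)) / 2
  eig <- eigen(Be, symmetric = TRUE)
  ord <- order(eig$values)            # ascending
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  values[abs(values) < 1e-12] <- 0
  nonzero <- values > 0
  if (sum(!nonzero) != 3L) {
    stop("unexpected affine null space: ", sum(!nonzero), " zero eigenvalues")
  }
  structure(list(principal_warps = vectors[, nonzero, drop = FALSE],
                 bending_eigenvalues = values,
                 uniform_basis = uniform_complement_basis(consensus),
                 consensus = consensus),
            class = "bending_energy_basis")
}

# 2k-vector layout used throughout: (x_1..x_k, y_1..y_k).
flatten_xy <- function(coords) c(coords[, 1], coords[, 2])

# Orthonormal basis (2k x 2) of the uniform shape subspace: the span of the
# four linear (affine, non-translational) deformations of the consensus, with
# the in-plane similarity directions (scaling = consensus itself, rotation =
# 90-degree-rotated consensus) projected out.
uniform_complement_basis <- function(consensus) {
  x <- consensus[, 1]; y <- consensus[, 2]; z <- numeric(length(x))
  affine <- cbind(c(x, z), c(y, z), c(z, x), c(z, y))
  scale_dir <- flatten_xy(consensus)
  rot_dir <- c(-y, x)
  basis <- cbind(scale_dir / sqrt(sum(scale_dir^2)), rot_dir / sqrt(sum(rot_dir^2)))
  for (j in seq_len(ncol(affine))) {
    v <- affine[, j]
    v <- v - basis %*% crossprod(basis, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-9) basis <- cbind(basis, v / nv)
  }
  uni <- basis[, -(1:2), drop = FALSE]
  if (ncol(uni) != 2L) stop("failed to construct a 2-D uniform basis")
  uni
}

#' Partial-warp scores (the W' shape-variable matrix)
#'
#' Projects each specimen's Procrustes residual from the consensus onto the
#' principal warps (x and y components separately) and onto the two uniform
#' directions.  With the orthonormal warp basis used here (alpha = 0
#' weighting), the score space is an isometric rotation of the Procrustes
#' tangent space: the row sum of squares equals the squared norm of the
#' specimen's tangent-projected residual.  Residuals are orthogonally
#' projected into the tangent space (the component along the consensus, left
#' over by unit-size scaling, is removed) before scoring.
#'
#' @param aligned An \code{aligned_shapes} object from [gpa_align()].
#' @param basis A \code{bending_energy_basis} built from \code{aligned$consensus}.
#' @param include_uniform Append the two uniform scores (default \code{TRUE}).
#' @return A \code{partial_warp_matrix}: \code{scores} (\code{n x (2k-4)}
#'   matrix when \code{include_uniform}), \code{column_labels}, plus the
#'   \code{basis} and specimen metadata needed to reconstruct residuals.
#' @export
partial_warp_scores <- function(aligned, basis, include_uniform = TRUE) {
  if (max(abs(basis$consensus - aligned$consensus)) > 1e-8) {
    stop("basis mismatch: basis was not built from this consensus")
  }
  k <- nrow(aligned$consensus)
  n <- dim(aligned$coords)[3]
  E <- basis$principal_warps                  # k x (k-3)
  cvec <- flatten_xy(aligned$consensus)
  cunit <- cvec / sqrt(sum(cvec^2))
  labels <- c(paste0("pw", rep(seq_len(ncol(E)), each = 2), c("x", "y")))
  if (include_uniform) labels <- c(labels, "uniform1", "uniform2")
  scores <- matrix(0, n, length(labels), dimnames = list(aligned$specimen_id, labels))
  for (i in seq_len(n)) {
    r <- flatten_xy(aligned$coords[, , i]) - cvec
    r <- r - cunit * sum(cunit * r)           # tangent projection
    rx <- r[seq_len(k)]; ry <- r[k + seq_len(k)]
    pw <- rbind(as.numeric(crossprod(E, rx)),
                as.numeric(crossprod(E, ry)))         # 2 x (k-3), x over y
    row <- as.numeric(pw)                             # interleaved x1,y1,x2,...
    if (include_uniform) row <- c(row, as.numeric(crossprod(basis$uniform_basis, r)))
    scores[i, ] <- row
  }
  structure(list(scores = scores, column_labels = labels, basis = basis,
                 include_uniform = include_uniform,
                 specimen_id = aligned$specimen_id, taxon = aligned$taxon),
            class = "partial_warp_matrix")
}

#' Reconstruct tangent-space residuals from partial-warp scores
#' @param pw A \code{partial_warp_matrix}.
#' @return \code{n x 2k} matrix of reconstructed residual vectors
#'   (x-block then y-block).
#' @export
residuals_from_scores <- function(pw) {
  E <- pw$basis$principal_warps
  k <- nrow(E); m <- ncol(E)
  n <- nrow(pw$scores)
  out <- matrix(0, n, 2 * k)
  for (i in seq_len(n)) {
    row <- pw$scores[i, ]
    pwblock <- matrix(row[seq_len(2 * m)], nrow = 2)   # x over y per warp
    r <- c(E %*% pwblock[1, ], E %*% pwblock[2, ])
    if (pw$include_uniform) {
      u <- row[2 * m + 1:2]
      r <- r + as.numeric(pw$basis$uniform_basis %*% u)
    }
    out[i, ] <- r
  }
  rownames(out) <- rownames(pw$scores)
  out
}

#' Thin-plate-spline grid warp
#'
#' Fits the TPS interpolant mapping the consensus landmarks onto the target
#' landmarks and applies it to a rectangular grid, the standard deformation-
#' grid visualisation of shape difference.
#'
#' @param consensus,target \code{k x 2} matrices with matching landmarks.
#' @param n_grid Grid lines per axis (default 24).
#' @param expand Fractional margin around the consensus bounding box (default 0.05).
#' @return List with \code{grid} (the input grid points, \code{m x 2}) and
#'   \code{warped} (their images, \code{m x 2}), plus \code{nx}, \code{ny}.
#' @export
tps_warp_grid <- function(consensus, target, n_grid = 24L, expand = 0.05) {
  consensus <- as.matrix(consensus); target <- as.matrix(target)
  if (!all(dim(consensus) == dim(target))) stop("shape mismatch: unequal landmark counts")
  k <- nrow(consensus)
  d2 <- as.matrix(stats::dist(consensus))^2
  if (any(d2[upper.tri(d2)] < 1e-24)) stop("singular kernel: coincident landmarks")
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, consensus)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- solve(L, rhs)                      # (k+3) x 2
  rng <- apply(consensus, 2, range)
  pad <- expand * (rng[2, ] - rng[1, ])
  xs <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = n_grid)
  ys <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = n_grid)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  warped <- tps_apply(consensus, coefs, grid)
  list(grid = grid, warped = warped, nx = length(xs), ny = length(ys))
}

tps_apply <- function(src, coefs, pts) {
  k <- nrow(src)
  d2 <- outer(rowSums(pts^2), rep(1, k)) +
    outer(rep(1, nrow(pts)), rowSums(src^2)) - 2 * pts %*% t(src)
  d2[d2 < 1e-300] <- 0
  U <- ifelse(d2 > 0, d2 * log(d2), 0)
  cbind(1, pts) %*% coefs[k + 1:3, , drop = FALSE] + U %*% coefs[seq_len(k), , drop = FALSE]
}
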