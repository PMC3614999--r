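# Independent oracles used across the suite.  Each deliberately takes the
# dumbest correct route (grid search, cofactor expansion, closed forms) so it
# shares no code path with the implementation it checks.

# Best rotation angle of b onto a by brute-force grid search.
grid_search_rotation <- function(a, b, resolution = 1e-5) {
  angles <- seq(0, 2 * pi, by = resolution)
  rss <- vapply(angles, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((a - b %*% R)^2)
  }, numeric(1))
  best <- angles[which.min(rss)]
  list(angle = best, rss = min(rss))
}

# Matrix inverse via the adjugate (cofactor expansion), base det() only.
cofactor_inverse <- function(M) {
  n <- nrow(M)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[j, i] <- (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
  }
  adj / det(M)
}

# Bending-energy matrix of a configuration assembled from scratch and
# inverted by cofactor expansion.
bending_energy_oracle <- function(conf) {
  k <- nrow(conf)
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) {
      r2 <- sum((conf[i, ] - conf[j, ])^2)
      K[i, j] <- r2 * log(r2)
    }
  }
  Q <- cbind(1, conf)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  cofactor_inverse(L)[seq_len(k), seq_len(k)]
}

# Generalized eigenproblem W^-1 B for 2x2 matrices: explicit inverse and
# quadratic characteristic polynomial.
cva_2x2_oracle <- function(B, W) {
  Winv <- matrix(c(W[2, 2], -W[2, 1], -W[1, 2], W[1, 1]), 2, 2) / det(W)
  M <- Winv %*% B
  tr <- M[1, 1] + M[2, 2]
  dt <- det(M)
  lam <- sort(c((tr + sqrt(tr^2 - 4 * dt)) / 2,
                (tr - sqrt(tr^2 - 4 * dt)) / 2), decreasing = TRUE)
  vecs <- sapply(lam, function(l) {
    A <- M - diag(2) * l
    v <- if (abs(A[1, 2]) > abs(A[2, 2])) c(-A[1, 2], A[1, 1]) else c(-A[2, 2], A[2, 1])
    v / sqrt(sum(v * (W %*% v)))   # a' W a = 1 normalization
  })
  list(values = lam, vectors = vecs)
}

# Eigenvalues of a symmetric 3x3 matrix as characteristic-polynomial roots
# found with polyroot().
eigen3_oracle <- function(M) {
  # det(M - x I) = -x^3 + c2 x^2 + c1 x + c0
  c2 <- sum(diag(M))
  c1 <- -(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1] +
            M[1, 1] * M[3, 3] - M[1, 3] * M[3, 1] +
            M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2])
  c0 <- det(M)
  sort(Re(polyroot(c(c0, c1, c2, -1))), decreasing = TRUE)
}

# Singular values of a p x 2 matrix via the quadratic formula on C'C.
singular_values_oracle <- function(C) {
  M <- t(C) %*% C
  tr <- M[1, 1] + M[2, 2]
  dt <- det(M)
  sqrt(pmax(0, c((tr + sqrt(max(0, tr^2 - 4 * dt))) / 2,
                 (tr - sqrt(max(0, tr^2 - 4 * dt))) / 2)))
}

# Exhaustive best Gini split over every predictor and every midpoint.
gini_split_oracle <- function(X, labels) {
  gini <- function(l) 1 - sum((table(l) / length(l))^2)
  n <- length(labels)
  best <- list(decrease = -Inf)
  for (pred in names(X)) {
    vals <- sort(unique(X[[pred]]))
    if (length(vals) < 2) next
    mids <- (vals[-length(vals)] + vals[-1]) / 2
    for (t in mids) {
      left <- X[[pred]] <= t
      dec <- gini(labels) - mean(left) * gini(labels[left]) -
        mean(!left) * gini(labels[!left])
      if (dec > best$decrease + 1e-12) {
        best <- list(predictor = pred, threshold = t, decrease = dec)
      }
    }
  }
  best
}

# Random unit-centroid-size configuration.
random_shape <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  leucidelim:::center_scale(matrix(stats::rnorm(2 * k), k, 2))
}

# Small templates/sizes for fast end-to-end runs.
small_sizes <- function(n = 8L) c(Sl = n, Ss = n, Tm = n, Rr = n)
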