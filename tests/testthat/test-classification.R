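toy_groups_2d <- function(seed = 5, n = 12) {
  set.seed(seed)
  means <- rbind(A = c(0, 0), B = c(3, 1), C = c(1, 4))
  X <- do.call(rbind, lapply(rownames(means), function(g)
    sweep(matrix(rnorm(2 * n, sd = 0.8), n, 2), 2, means[g, ], `+`)))
  list(X = X, labels = rep(rownames(means), each = n))
}

test_that("CVA solves the generalized eigenproblem (closed-form 2x2 oracle)", {
  toy <- toy_groups_2d()
  fit <- fit_cva(toy$X, toy$labels)
  st <- leucidelim:::group_stats(sweep(toy$X, 2, colMeans(toy$X)), toy$labels)
  n <- nrow(toy$X)
  B <- crossprod(st$means * sqrt(st$sizes)) / (n - 1)
  oracle <- cva_2x2_oracle(B, st$W)
  expect_equal(fit$eigenvalues, oracle$values, tolerance = 1e-8)
  for (j in 1:2) {
    a <- fit$canonical_axes[, j]; o <- oracle$vectors[, j]
    expect_lt(min(max(abs(a - o)), max(abs(a + o))), 1e-8)
  }
})

test_that("CVA axes have unit pooled within-group variance and find planted axes", {
  toy <- toy_groups_2d(9)
  fit <- fit_cva(toy$X, toy$labels)
  # pooled within-group variance of each canonical score = 1
  st <- leucidelim:::group_stats(fit$scores, fit$labels)
  expect_equal(diag(st$W), c(CV1 = 1, CV2 = 1), tolerance = 1e-6)
  # groups separated only along coordinate 1, with orthogonal within-group
  # residual patterns (diagonal within covariance, zero between-group spread
  # in coordinates 2-3), load only coordinate 1
  pat <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1), c(-1, 1, 1, -1))
  X <- do.call(rbind, lapply(c(0, 10, 20), function(m)
    cbind(m + pat[, 1], pat[, 2], pat[, 3])))
  fit1 <- fit_cva(X, rep(c("a", "b", "c"), each = 4))
  a1 <- fit1$canonical_axes[, 1] / max(abs(fit1$canonical_axes[, 1]))
  expect_lt(max(abs(a1[2:3])), 1e-9)
  # 4 groups in many dimensions give min(g-1, p) = 3 axes
  cfg <- simulate_landmarks(n_per_species = small_sizes(10), seed = 4)
  g <- gpa_align(cfg)
  pw <- partial_warp_scores(g, bending_energy_basis(g$consensus))
  fit4 <- fit_cva(pw)
  expect_identical(ncol(fit4$scores), 3L)
  expect_true(isSymmetric(fit4$mahalanobis))
  expect_true(all(diag(fit4$mahalanobis) == 0))
})

test_that("CVA agrees with lda on the discriminant subspace (cross-check)", {
  skip_if_not_installed("MASS")
  toy <- toy_groups_2d(13)
  fit <- fit_cva(toy$X, toy$labels)
  ld <- MASS::lda(toy$X, grouping = toy$labels)
  # scalings span the same subspace: correlation of scores ~ +/-1
  s1 <- fit$scores[, 1]
  s2 <- (toy$X %*% ld$scaling)[, 1]
  expect_gt(abs(cor(s1, s2)), 1 - 1e-6)
})

test_that("CVA scores are invariant to invertible linear feature transforms", {
  toy <- toy_groups_2d(17)
  fit <- fit_cva(toy$X, toy$labels)
  set.seed(3)
  A <- matrix(rnorm(4), 2, 2) + diag(2) * 2
  fit2 <- fit_cva(toy$X %*% A, toy$labels)
  for (j in 1:2) {
    expect_lt(min(max(abs(fit$scores[, j] - fit2$scores[, j])),
                  max(abs(fit$scores[, j] + fit2$scores[, j]))), 1e-7)
  }
})

test_that("leave-one-out classification matches a hand-enumerated 1-D oracle", {
  x <- matrix(c(1, 2, 3, 7.5, 9, 10), ncol = 1)
  labels <- c("a", "a", "a", "b", "b", "b")
  cm <- loo_crossvalidate_cva(x, labels)
  # oracle: per fold, recompute means and pooled variance without the holdout
  assigned <- character(6)
  for (i in 1:6) {
    xa <- x[-i][labels[-i] == "a"]; xb <- x[-i][labels[-i] == "b"]
    s2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (5 - 2)
    assigned[i] <- if ((x[i] - mean(xa))^2 / s2 <= (x[i] - mean(xb))^2 / s2)
      "a" else "b"
  }
  oracle_counts <- unclass(table(factor(labels, c("a", "b")),
                                 factor(assigned, c("a", "b"))))
  expect_equal(cm$counts, oracle_counts)
  expect_equal(sum(cm$counts), 6)

  # perfectly separated groups classify perfectly
  set.seed(8)
  X <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20) + 20, 10, 2))
  cm2 <- loo_crossvalidate_cva(X, rep(c("g1", "g2"), each = 10))
  expect_equal(cm2$overall_correct_pct, 100)
  expect_error(loo_crossvalidate_cva(X[c(1:10, 11), ], c(rep("g1", 10), "g2")),
               "size|>= 2")
})

test_that("leave-one-out accuracy sits at chance on structureless data", {
  set.seed(19)
  X <- matrix(rnorm(60 * 3), 60, 3)
  correct <- 0L
  shuffles <- 200L
  for (b in seq_len(shuffles)) {
    labels <- sample(rep(c("a", "b"), each = 30))
    cm <- loo_crossvalidate_cva(X, labels)
    correct <- correct + sum(diag(cm$counts))
  }
  acc <- correct / (shuffles * 60)
  # binomial 99% CI around 1/g (LOO is mildly pessimistic, hence the lower side)
  half <- 2.576 * sqrt(0.25 / (shuffles * 60))
  expect_lt(acc, 0.5 + half)
  expect_gt(acc, 0.40)
})

test_that("pairwise permutation test attains its minimum p on separated groups", {
  set.seed(23)
  X <- rbind(matrix(rnorm(24), 12, 2), matrix(rnorm(24) + 50, 12, 2))
  labels <- rep(c("a", "b"), each = 12)
  p <- cva_permutation_test(X, labels, n_perm = 99, seed = 2)
  expect_equal(p["a", "b"], 1 / 100)
  # invariance under orthogonal feature rotation
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p2 <- cva_permutation_test(X %*% Q, labels, n_perm = 99, seed = 2)
  expect_equal(p, p2)
  expect_error(cva_permutation_test(X, labels, n_perm = 0), "n_perm")
})

test_that("tree induction recovers a separable split and matches the Gini oracle", {
  mk <- function(nsll, cls) {
    data.frame(specimen_id = paste0("s", seq_along(nsll)), taxon = cls,
               NSLL = nsll, NSALL = 8L, NSULL = 4L, NRDF = 8L,
               NRPF = 14L, NRAF = 9L)
  }
  sep <- mk(c(38L, 39L, 40L, 40L, 45L, 46L, 47L, 48L),
            rep(c("A", "B"), each = 4))
  tree <- fit_crt(sep, min_parent = 2L, min_child = 1L, cv_folds = 4L)
  expect_false(tree$root$leaf)
  expect_equal(tree$root$predictor, "NSLL")
  expect_gt(tree$root$threshold, 40)
  expect_lt(tree$root$threshold, 45)
  expect_equal(predict_crt(tree, sep), sep$taxon)

  toy <- mk(c(40L, 41L, 42L, 43L, 60L, 61L, 62L, 63L),
            rep(c("A", "B"), each = 4))
  toy$NRPF <- c(13L, 14L, 13L, 14L, 13L, 14L, 13L, 14L)
  tree2 <- fit_crt(toy, min_parent = 2L, min_child = 1L, cv_folds = 4L)
  oracle <- gini_split_oracle(toy[leucidelim:::MERISTIC_CHARACTERS], toy$taxon)
  expect_equal(tree2$root$predictor, oracle$predictor)
  expect_equal(tree2$root$threshold, oracle$threshold)
  expect_equal(tree2$root$decrease, oracle$decrease, tolerance = 1e-12)
})

test_that("root splits match the exhaustive Gini oracle on noisy data", {
  for (seed in 1:5) {
    m <- simulate_meristics(n_per_species = small_sizes(10), seed = seed)
    tree <- fit_crt(m, seed = seed)
    oracle <- gini_split_oracle(m[leucidelim:::MERISTIC_CHARACTERS], m$taxon)
    expect_equal(tree$root$predictor, oracle$predictor)
    expect_equal(tree$root$threshold, oracle$threshold)
  }
})

test_that("the planted dominant predictor wins the root split across replicates", {
  hits <- 0L
  for (seed in 1:100) {
    m <- simulate_meristics(n_per_species = small_sizes(8), seed = seed)
    tree <- fit_crt(m, seed = seed)
    if (tree$root$predictor == "NSLL") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("tree prediction follows the tie rule and training consistency", {
  m <- simulate_meristics(n_per_species = small_sizes(12), seed = 31)
  tree <- fit_crt(m, seed = 31)
  # record exactly at the root threshold goes left
  at <- m[1, ]
  at[[tree$root$predictor]] <- tree$root$threshold
  left_label <- leucidelim:::descend(tree$root$left, at)
  expect_equal(leucidelim:::descend(tree$root, at), left_label)
  # training rows land on their leaf's majority class
  preds <- predict_crt(tree, m)
  expect_gte(mean(preds == m$taxon), 0.8)
  # missing predictor value errors (no surrogate splits)
  bad <- m[1, ]
  bad[[tree$root$predictor]] <- NA_integer_
  expect_error(predict_crt(tree, bad), "missing")
  expect_error(fit_crt(m, min_parent = 4L, min_child = 5L), "min_child")
})

test_that("growing the tree never increases training impurity", {
  m <- simulate_meristics(n_per_species = small_sizes(10), seed = 37)
  tree <- fit_crt(m, seed = 37)
  check <- function(node) {
    if (node$leaf) return(invisible())
    wl <- node$left$n / node$n; wr <- node$right$n / node$n
    expect_lte(wl * node$left$impurity + wr * node$right$impurity,
               node$impurity + 1e-12)
    check(node$left); check(node$right)
  }
  check(tree$root)
})

test_that("tree structure agrees with rpart on a clean two-class problem (cross-check)", {
  skip_if_not_installed("rpart")
  set.seed(41)
  m <- data.frame(specimen_id = paste0("s", 1:60),
                  taxon = rep(c("A", "B"), each = 30),
                  NSLL = c(sample(38:44, 30, TRUE), sample(47:54, 30, TRUE)),
                  NSALL = sample(7:9, 60, TRUE), NSULL = sample(3:5, 60, TRUE),
                  NRDF = sample(8:9, 60, TRUE), NRPF = sample(12:16, 60, TRUE),
                  NRAF = sample(8:11, 60, TRUE))
  tree <- fit_crt(m, seed = 1)
  rp <- rpart::rpart(taxon ~ NSLL + NSALL + NSULL + NRDF + NRPF + NRAF,
                     data = m, method = "class",
                     control = rpart::rpart.control(minsplit = 10, cp = 0.01))
  expect_equal(tree$root$predictor,
               as.character(rp$frame$var[1]))
  expect_equal(tree$root$threshold, rp$splits[1, "index"], tolerance = 0.51)
})
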