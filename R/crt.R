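gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

# Exhaustive best split at one node: every predictor, every midpoint between
# consecutive distinct observed values.  Ties in Gini decrease are broken by
# predictor order, then by the lower threshold, so trees are deterministic.
best_split <- function(X, labels, predictors, min_child) {
  n <- length(labels)
  node_imp <- gini_impurity(labels)
  best <- NULL
  for (pred in predictors) {
    x <- X[[pred]]
    vals <- sort(unique(x))
    if (length(vals) < 2L) next
    for (t in (vals[-length(vals)] + vals[-1]) / 2) {
      left <- x <= t
      nl <- sum(left); nr <- n - nl
      if (nl < min_child || nr < min_child) next
      dec <- node_imp - (nl / n) * gini_impurity(labels[left]) -
        (nr / n) * gini_impurity(labels[!left])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(predictor = pred, threshold = t, decrease = dec)
      }
    }
  }
  best
}

grow_node <- function(X, labels, predictors, params, depth, node_id) {
  counts <- table(factor(labels, levels = params$classes))
  majority <- params$classes[which.max(counts)]
  leaf <- list(id = node_id, leaf = TRUE, label = majority,
               counts = as.integer(counts), n = length(labels),
               impurity = gini_impurity(labels))
  if (length(unique(labels)) == 1L || length(labels) < params$min_parent ||
      depth >= params$max_depth) {
    return(leaf)
  }
  split <- best_split(X, labels, predictors, params$min_child)
  if (is.null(split) || split$decrease <= 1e-12) return(leaf)
  go_left <- X[[split$predictor]] <= split$threshold
  list(id = node_id, leaf = FALSE,
       predictor = split$predictor, threshold = split$threshold,
       decrease = split$decrease, n = length(labels),
       counts = as.integer(counts), impurity = gini_impurity(labels),
       left = grow_node(X[go_left, , drop = FALSE], labels[go_left],
                        predictors, params, depth + 1L, paste0(node_id, "L")),
       right = grow_node(X[!go_left, , drop = FALSE], labels[!go_left],
                         predictors, params, depth + 1L, paste0(node_id, "R")))
}

#' Fit a classification tree on meristic counts (species identification key)
#'
#' Greedy binary recursive partitioning with the Gini impurity criterion over
#' the six ordinal meristic characters.  At every node all predictors and all
#' midpoints between consecutive observed values are evaluated; the split with
#' the largest impurity decrease wins (ties broken by predictor order NSLL,
#' NSALL, NSULL, NRDF, NRPF, NRAF, then by the lower threshold).  Splitting
#' stops at pure nodes, below \code{min_parent} cases, or at \code{max_depth}.
#' A stratified k-fold cross-validated confusion matrix is attached.
#'
#' @param meristics Data frame from [read_meristic_csv()] (or with the six
#'   count columns).
#' @param labels Species labels; defaults to \code{meristics$taxon}.
#' @param min_parent Minimum node size to attempt a split (default 10).
#' @param min_child Minimum size of each daughter node (default 5).
#' @param max_depth Maximum tree depth (default 5).
#' @param cv_folds Folds for the stratified cross-validation (default 10);
#'   use \code{"loo"} for leave-one-out.
#' @param seed Seed for fold assignment.
#' @return A \code{crt_tree}: recursive \code{root} node list (internal nodes
#'   carry predictor, threshold and the rule "x <= t goes left"; leaves carry
#'   the majority species, class counts and impurity), \code{classes}, and
#'   \code{cv}, the cross-validated \code{confusion_matrix}.
#' @export
fit_crt <- function(meristics, labels = meristics$taxon,
                    min_parent = 10L, min_child = 5L, max_depth = 5L,
                    cv_folds = 10L, seed = 1L) {
  if (min_child >= min_parent) stop("parameter error: min_child must be < min_parent")
  labels <- as.character(labels)
  if (any(is.na(labels))) stop("species labels required for every row")
  predictors <- MERISTIC_CHARACTERS[MERISTIC_CHARACTERS %in% names(meristics)]
  if (length(predictors) < 6L) {
    stop("meristic table must carry all six predictors; missing: ",
         paste(setdiff(MERISTIC_CHARACTERS, predictors), collapse = ", "))
  }
  X <- meristics[predictors]
  if (all(vapply(X, function(x) length(unique(x)) == 1L, logical(1)))) {
    stop("degenerate input: all predictors constant")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  params <- list(min_parent = min_parent, min_child = min_child,
                 max_depth = max_depth, classes = classes)
  root <- grow_node(X, labels, predictors, params, 0L, "n")
  cv <- crt_crossvalidate(X, labels, predictors, params, cv_folds, seed)
  structure(list(root = root, classes = classes, predictors = predictors,
                 params = params, cv = cv, n = nrow(X)),
            class = "crt_tree")
}

crt_crossvalidate <- function(X, labels, predictors, params, cv_folds, seed) {
  n <- length(labels)
  if (identical(cv_folds, "loo")) {
    fold <- seq_len(n)
  } else {
    cv_folds <- min(as.integer(cv_folds), min(table(labels)))
    set.seed(seed)
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  }
  assigned <- character(n)
  for (f in unique(fold)) {
    test <- fold == f
    root <- grow_node(X[!test, , drop = FALSE], labels[!test],
                      predictors, params, 0L, "n")
    assigned[test] <- vapply(which(test), function(i)
      descend(root, X[i, , drop = FALSE]), character(1))
  }
  confusion_matrix(labels, assigned, params$classes)
}

descend <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$predictor]]
    if (is.na(v)) stop("missing-data error: predictor ", node$predictor,
                       " absent from record")
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$label
}

#' Predict species from a fitted classification tree
#'
#' Deterministic descent: at each internal node the record goes left when
#' \code{value <= threshold} (records exactly at the threshold go left).
#' No surrogate splits: a missing predictor raises an error.
#'
#' @param tree A \code{crt_tree} from [fit_crt()].
#' @param records Data frame of meristic records (one or more rows).
#' @return Character vector of species labels.
#' @export
predict_crt <- function(tree, records) {
  vapply(seq_len(nrow(records)), function(i)
    descend(tree$root, records[i, , drop = FALSE]), character(1))
}

#' Render a tree as a dichotomous identification key
#' @param tree A \code{crt_tree}.
#' @return Character vector, one line per key step.
#' @export
crt_key_text <- function(tree) {
  out <- character(0)
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      out <<- c(out, sprintf("%s-> %s (n = %d)", pad, node$label, node$n))
    } else {
      out <<- c(out, sprintf("%s%s <= %s:", pad, node$predictor,
                             format(node$threshold)))
      walk(node$left, indent + 1L)
      out <<- c(out, sprintf("%s%s > %s:", pad, node$predictor,
                             format(node$threshold)))
      walk(node$right, indent + 1L)
    }
  }
  walk(tree$root, 0L)
  out
}

#' @export
print.crt_tree <- function(x, ...) {
  cat("Species identification key (classification tree):\n")
  cat(crt_key_text(x), sep = "\n")
  cat(sprintf("Cross-validated correct: %.1f%%\n", x$cv$overall_correct_pct))
  invisible(x)
}
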