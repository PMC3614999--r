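BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Count variable sites in an alignment
#'
#' A column is variable when it contains at least two distinct bases among
#' \code{A,C,G,T}.  Columns whose only variation involves \code{N} are not
#' counted, and a column containing gaps but only one distinct base is not
#' variable (gaps do not create variation on their own).
#'
#' @param set An aligned \code{sequence_set}.
#' @return List with \code{variable} (count), \code{length} (alignment
#'   columns) and \code{pct} (percentage, rounded to 1 decimal).
#' @export
count_variable_sites <- function(set) {
  m <- alignment_matrix(set)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  variable <- sum(apply(m, 2, function(col) {
    length(unique(col[col %in% BASES])) >= 2L
  }))
  len <- ncol(m)
  list(variable = variable, length = len,
       pct = round(100 * variable / len, 1))
}

#' Collapse sequences to haplotypes
#'
#' Exact-match collapse after upper-casing; \code{N} is treated as a distinct
#' state (no ambiguity merging).
#'
#' @param set An aligned \code{sequence_set}.
#' @return A \code{haplotype_set}: list with \code{haplotypes} (data frame of
#'   sequence, multiplicity) and \code{members} (list of specimen ids).
#' @export
collapse_haplotypes <- function(set) {
  groups <- split(seq_along(set$seq), set$seq)
  ord <- order(vapply(groups, min, integer(1)))   # first-seen order
  groups <- groups[ord]
  structure(list(
    haplotypes = data.frame(sequence = names(groups),
                            multiplicity = lengths(groups),
                            row.names = NULL, stringsAsFactors = FALSE),
    members = lapply(groups, function(i) set$specimen_id[i])),
    class = "haplotype_set")
}

#' Percent identity between two sequences
#'
#' Identity = 100 x matches / compared positions; positions where either
#' sequence carries a gap are excluded from numerator and denominator.  With
#' \code{mode = "global_align"} the sequences are first aligned globally
#' (Needleman-Wunsch: match +1, mismatch -1, gap open -5, gap extend -1).
#'
#' @param a,b Character strings over \code{A,C,G,T,N,-}.
#' @param mode \code{"aligned"} (equal lengths required) or
#'   \code{"global_align"}.
#' @return Percent identity, rounded to 1 decimal.
#' @export
pairwise_identity <- function(a, b, mode = c("aligned", "global_align")) {
  mode <- match.arg(mode)
  a <- toupper(a); b <- toupper(b)
  if (mode == "global_align") {
    al <- global_align(a, b)
    a <- al[[1]]; b <- al[[2]]
  } else if (nchar(a) != nchar(b)) {
    stop("aligned mode requires equal lengths")
  }
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("undefined identity: no gap-free overlap")
  round(100 * sum(ca[keep] == cb[keep]) / sum(keep), 1)
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Affine-gap global alignment with the fixed scoring scheme match +1,
#' mismatch -1, gap open -5, gap extend -1, delegated to
#' \code{Biostrings::pairwiseAlignment}.
#'
#' @param a,b Character strings (gaps are stripped before alignment).
#' @return List of the two aligned strings (equal length, \code{-} for gaps).
#' @export
global_align <- function(a, b) {
  a <- gsub("-", "", toupper(a), fixed = TRUE)
  b <- gsub("-", "", toupper(b), fixed = TRUE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1)
  list(as.character(Biostrings::alignedPattern(al)),
       as.character(Biostrings::alignedSubject(al)))
}

#' Pairwise genetic distance matrix
#'
#' Uncorrected p-distance by default (proportion of differing sites, with gap
#' and \code{N} positions excluded pairwise), via \code{ape::dist.dna};
#' Jukes-Cantor and Kimura 2-parameter corrections are pluggable.  Two markers
#' over the same specimen roster combine by unweighted per-pair averaging.
#'
#' @param sets One aligned \code{sequence_set} or a list of them (same roster).
#' @param model \code{"p"}, \code{"JC69"} or \code{"K80"}.
#' @return A \code{distance_matrix}: \code{ids}, \code{values} (symmetric,
#'   zero diagonal), \code{metric_tag}.
#' @export
p_distance_matrix <- function(sets, model = c("p", "JC69", "K80")) {
  model <- match.arg(model)
  if (inherits(sets, "sequence_set")) sets <- list(sets)
  ids <- sets[[1]]$specimen_id
  mats <- lapply(sets, function(set) {
    if (!identical(sort(set$specimen_id), sort(ids))) {
      stop("specimen roster mismatch across markers")
    }
    m <- alignment_matrix(set)[ids, , drop = FALSE]
    bin <- ape::as.DNAbin(tolower(m))
    d <- ape::dist.dna(bin, model = if (model == "p") "raw" else model,
                       pairwise.deletion = TRUE)
    as.matrix(d)
  })
  values <- Reduce(`+`, mats) / length(mats)
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values,
                 metric_tag = paste0(model, "-distance",
                                     if (length(mats) > 1)
                                       paste0(", unweighted mean of ",
                                              length(mats), " markers"))),
            class = "distance_matrix")
}

#' Diagnostic differences between two taxa in an alignment
#'
#' Reports alignment columns fixed for one base in every member of group A and
#' a different base in every member of group B (classified as transition or
#' transversion), and maximal gap blocks present in every member of one group
#' and absent in all members of the other.
#'
#' @param set An aligned \code{sequence_set} with taxon labels.
#' @param group_a,group_b Taxon labels present in \code{set$taxon}.
#' @return A \code{diagnostic_differences}: \code{substitutions} (data frame:
#'   position, state_a, state_b, class) and \code{indels} (data frame: start,
#'   length, missing_in).
#' @export
diagnostic_differences <- function(set, group_a, group_b) {
  require_taxa(set)
  m <- alignment_matrix(set)
  ia <- which(set$taxon == group_a)
  ib <- which(set$taxon == group_b)
  if (!length(ia)) stop("group label absent: ", group_a)
  if (!length(ib)) stop("group label absent: ", group_b)
  subs <- data.frame(position = integer(0), state_a = character(0),
                     state_b = character(0), class = character(0),
                     stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    sa <- unique(m[ia, j]); sb <- unique(m[ib, j])
    if (length(sa) == 1L && length(sb) == 1L &&
        sa %in% BASES && sb %in% BASES && sa != sb) {
      cls <- if ((sa %in% PURINES) == (sb %in% PURINES)) "transition" else "transversion"
      subs <- rbind(subs, data.frame(position = j, state_a = sa, state_b = sb,
                                     class = cls, stringsAsFactors = FALSE))
    }
  }
  gap_fixed <- function(rows, other) {
    vapply(seq_len(ncol(m)), function(j)
      all(m[rows, j] == "-") && all(m[other, j] != "-"), logical(1))
  }
  indels <- data.frame(start = integer(0), length = integer(0),
                       missing_in = character(0), stringsAsFactors = FALSE)
  for (side in list(list(rows = ia, other = ib, lab = group_a),
                    list(rows = ib, other = ia, lab = group_b))) {
    runs <- rle(gap_fixed(side$rows, side$other))
    pos <- cumsum(c(1L, runs$lengths))
    for (r in which(runs$values)) {
      indels <- rbind(indels, data.frame(start = pos[r], length = runs$lengths[r],
                                         missing_in = side$lab,
                                         stringsAsFactors = FALSE))
    }
  }
  structure(list(substitutions = subs, indels = indels,
                 group_a = group_a, group_b = group_b),
            class = "diagnostic_differences")
}

#' Species attribution from Cyfun P band length
#'
#' The amplicon length of the Cyfun P region carries genus-level signal: the
#' default key assigns ~310 bp to \emph{T. muticellus}, ~440 bp to
#' \emph{R. rubilio} and ~410 bp to genus \emph{Squalius}
#' (species-ambiguous), each +/- 15 bp; lengths outside every interval return
#' \code{"unassigned"}.
#'
#' @param length_bp Positive integer band length.
#' @param key Data frame with columns \code{label}, \code{min}, \code{max};
#'   intervals must not overlap.
#' @return Label string.
#' @export
band_length_attribution <- function(length_bp,
                                    key = data.frame(
                                      label = c("T. muticellus", "Squalius", "R. rubilio"),
                                      min = c(295, 395, 426),
                                      max = c(325, 425, 455))) {
  if (length_bp <= 0) stop("band length must be positive")
  key <- key[order(key$min), ]
  if (any(key$max[-nrow(key)] >= key$min[-1])) {
    stop("configuration error: overlapping band-length intervals")
  }
  hit <- which(length_bp >= key$min & length_bp <= key$max)
  if (length(hit)) key$label[hit] else "unassigned"
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of \eqn{-D^2/2} and eigendecomposition, with
#' optional Lingoes or Cailliez correction for negative eigenvalues
#' (delegated to \code{ape::pcoa}).  Coordinates are eigenvectors scaled by
#' the square roots of the positive eigenvalues; each axis's sign is fixed so
#' its largest-magnitude loading is positive.
#'
#' @param dm A \code{distance_matrix} (or square symmetric matrix).
#' @param correction \code{"none"}, \code{"lingoes"} or \code{"cailliez"}.
#' @return A \code{pcoa_result}: \code{coordinates} (n x m, m = positive
#'   eigenvalues), \code{eigenvalues} (all n, descending),
#'   \code{negative_eigenvalue_sum}, \code{correction}, \code{ids}.
#' @export
pcoa <- function(dm, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  values <- if (inherits(dm, "distance_matrix")) dm$values else as.matrix(dm)
  ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  d <- stats::as.dist(values)
  raw_eig <- eigen(gower_center(as.matrix(d)), symmetric = TRUE,
                   only.values = TRUE)$values
  applied <- correction
  if (correction != "none" && min(raw_eig) > -1e-9) {
    message("no negative eigenvalues; ", correction, " correction not applied")
    applied <- "none"
  }
  res <- if (applied == "none") ape::pcoa(d) else ape::pcoa(d, correction = applied)
  eigv <- if (applied == "none") sort(raw_eig, decreasing = TRUE) else
    sort(c(res$values$Corr_eig,
           rep(0, max(0, nrow(values) - length(res$values$Corr_eig)))),
         decreasing = TRUE)
  coords <- as.matrix(res$vectors)
  # deterministic axis orientation
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ids
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = eigv,
                 negative_eigenvalue_sum = sum(raw_eig[raw_eig < 0]),
                 correction = applied, ids = ids),
            class = "pcoa_result")
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Within/between-group sequence similarity summaries
#'
#' Pairwise percent identities aggregated within and between taxa; the mean,
#' minimum and maximum over pairs are all reported since summaries in the
#' literature are ambiguous about which is meant.
#'
#' @param set An aligned \code{sequence_set} with taxon labels.
#' @return Data frame with \code{group_a}, \code{group_b} (equal for
#'   within-group rows), \code{mean}, \code{min}, \code{max}, \code{n_pairs}.
#' @export
similarity_summary <- function(set) {
  require_taxa(set)
  taxa <- sort(unique(set$taxon))
  out <- NULL
  for (i in seq_along(taxa)) for (j in i:length(taxa)) {
    ia <- which(set$taxon == taxa[i]); ib <- which(set$taxon == taxa[j])
    pairs <- if (i == j) {
      if (length(ia) < 2L) next
      t(utils::combn(ia, 2))
    } else as.matrix(expand.grid(ia, ib))
    sims <- apply(pairs, 1, function(p)
      pairwise_identity(set$seq[p[1]], set$seq[p[2]]))
    out <- rbind(out, data.frame(group_a = taxa[i], group_b = taxa[j],
                                 mean = round(mean(sims), 1),
                                 min = min(sims), max = max(sims),
                                 n_pairs = nrow(pairs),
                                 stringsAsFactors = FALSE))
  }
  out
}
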