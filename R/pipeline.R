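#' Run the full species-delimitation pipeline
#'
#' Chains every analysis stage on one dataset: Procrustes superimposition and
#' partial-warp extraction of the landmark data; CVA with leave-one-out
#' cross-validation (and optional pairwise permutation tests) on the W'
#' matrix; classification-tree induction on the meristic counts; alignment
#' summaries and combined p-distances for the phylogenetic markers; principal
#' coordinates of the distance matrix; and the two-block PLS of shape against
#' the first two PCoA axes, with permutation test and group-level integration
#' report.
#'
#' @param dataset A \code{synthetic_dataset}, or a list with \code{configs}
#'   (\code{landmark_configs}), \code{meristics} (data frame) and
#'   \code{alignments} (named list of aligned \code{sequence_set}s including
#'   \code{cytb} and \code{rag1}).
#' @param n_perm Permutations for the PLS test (default 999); set to 0 to
#'   skip permutation testing.
#' @param cva_n_perm Permutations for the pairwise CVA tests (default 0 =
#'   skip; the study design used 1000).
#' @param seed Integer seed for all resampling.
#' @return A \code{delim_report} list with elements \code{gpa}, \code{pw},
#'   \code{cva}, \code{cva_loo}, \code{cva_perm}, \code{crt}, \code{seqstats},
#'   \code{distances}, \code{pcoa}, \code{pls}, \code{pls_p},
#'   \code{integration}.
#' @export
run_pipeline <- function(dataset, n_perm = 999L, cva_n_perm = 0L, seed = 1L) {
  gpa <- gpa_align(dataset$configs)
  basis <- bending_energy_basis(gpa$consensus)
  pw <- partial_warp_scores(gpa, basis)
  cva <- fit_cva(pw)
  cva_loo <- loo_crossvalidate_cva(pw)
  cva_perm <- if (cva_n_perm > 0)
    cva_permutation_test(pw, labels = NULL, n_perm = cva_n_perm, seed = seed)
  crt <- fit_crt(dataset$meristics, seed = seed)
  seqstats <- lapply(dataset$alignments, function(set) {
    list(variable = count_variable_sites(set),
         haplotypes = collapse_haplotypes(set))
  })
  dm <- p_distance_matrix(dataset$alignments[c("cytb", "rag1")])
  pco <- pcoa(dm)
  G <- pco$coordinates[, 1:2, drop = FALSE]
  pls <- two_block_pls(pw$scores, G)
  pls_p <- if (n_perm > 0)
    pls_permutation_test(pw$scores, G, n_perm = n_perm, seed = seed,
                         exhaustive = FALSE)
  integration <- integration_report(pls, dataset$configs$taxon)
  structure(list(gpa = gpa, pw = pw, cva = cva, cva_loo = cva_loo,
                 cva_perm = cva_perm, crt = crt, seqstats = seqstats,
                 distances = dm, pcoa = pco, pls = pls, pls_p = pls_p,
                 integration = integration),
            class = "delim_report")
}

#' @export
print.delim_report <- function(x, ...) {
  cat("Integrative species-delimitation report\n")
  cat(sprintf("  specimens: %d, species: %s\n", length(x$gpa$specimen_id),
              paste(x$cva$groups, collapse = ", ")))
  cat(sprintf("  shape LOO cross-validation: %.1f%% correct\n",
              x$cva_loo$overall_correct_pct))
  cat(sprintf("  meristic key cross-validation: %.1f%% correct\n",
              x$crt$cv$overall_correct_pct))
  cat(sprintf("  PLS first-pair R = %.3f (R^2 = %.2f%s)\n",
              x$pls$pair_correlations[1], x$pls$linear_r2,
              if (!is.null(x$pls_p)) sprintf(", p = %.3g", x$pls_p[1]) else ""))
  if (length(x$integration$flagged_id)) {
    cat("  genotype/phenotype disagreement flagged:",
        paste(x$integration$flagged_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the scalar summaries of every stage (not the raw per-specimen
#' matrices) as one JSON record.
#'
#' @param report A \code{delim_report}.
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    n_specimens = length(report$gpa$specimen_id),
    cva = list(
      loo_correct_pct = report$cva_loo$overall_correct_pct,
      mahalanobis = report$cva$mahalanobis,
      eigenvalues = report$cva$eigenvalues),
    crt = list(
      cv_correct_pct = report$crt$cv$overall_correct_pct,
      key = crt_key_text(report$crt)),
    seqstats = lapply(report$seqstats, function(s)
      list(variable_sites = s$variable$variable,
           alignment_length = s$variable$length,
           variable_pct = s$variable$pct,
           n_haplotypes = nrow(s$haplotypes$haplotypes))),
    pcoa = list(eigenvalues = report$pcoa$eigenvalues,
                correction = report$pcoa$correction),
    pls = list(singular_values = report$pls$singular_values,
               pair_correlations = report$pls$pair_correlations,
               linear_r2 = report$pls$linear_r2,
               spearman_rho = report$pls$spearman_rho,
               permutation_p = report$pls_p),
    flagged_specimens = report$integration$flagged_id)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
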