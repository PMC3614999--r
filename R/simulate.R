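# Base 21-landmark left-lateral fish outline (snout at the origin, standard
# length ~0.92 units).  Landmark order follows the digitizing scheme used for
# the shape analysis: 1 snout tip, 2 nostril, 3 start of dorsal scale
# coverage, 4 eye centre, 5 premaxillar, 6 ventral operculum insertion,
# 7 start of lateral line, 8 posterior operculum, 9-10 pectoral-fin
# insertions, 11-12 dorsal-fin insertions, 13/17 caudal-fin insertions,
# 14/16 caudal-peduncle insertions, 15 posterior body extremity, 18-19
# anal-fin insertions, 20 anus, 21 pelvic-fin insertion.
base_fish_shape <- function() {
  matrix(c(
    0.00,  0.000,   # 1 snout tip
    0.06,  0.060,   # 2 nostril
    0.25,  0.140,   # 3 dorsal scale coverage
    0.10,  0.050,   # 4 eye centre
    0.07, -0.030,   # 5 premaxillar
    0.22, -0.110,   # 6 operculum, ventral profile
    0.26,  0.050,   # 7 lateral line start
    0.28,  0.000,   # 8 operculum, posterior
    0.30, -0.080,   # 9 pectoral fin, superior
    0.31, -0.120,   # 10 pectoral fin, inferior
    0.48,  0.160,   # 11 dorsal fin, anterior
    0.58,  0.140,   # 12 dorsal fin, posterior
    0.88,  0.080,   # 13 caudal fin, superior
    0.82,  0.070,   # 14 caudal peduncle, superior
    0.92,  0.000,   # 15 posterior extremity
    0.82, -0.070,   # 16 caudal peduncle, inferior
    0.88, -0.080,   # 17 caudal fin, inferior
    0.72, -0.100,   # 18 anal fin, posterior
    0.64, -0.120,   # 19 anal fin, anterior
    0.62, -0.110,   # 20 anus
    0.45, -0.130    # 21 pelvic fin, anterior
  ), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

# Deterministic deformation of the base outline: body depth (discoidal vs
# streamlined lateral profile), dorsal-fin shift along the body axis, eye
# raise, and caudal-peduncle height change -- the contrasts that separate the
# four study species on the canonical axes.
make_mean_shape <- function(depth = 1, dorsal_shift = 0, eye_raise = 0,
                            peduncle = 1) {
  m <- base_fish_shape()
  trunk <- c(3, 6, 9, 10, 11, 12, 18, 19, 20, 21)
  m[trunk, 2] <- m[trunk, 2] * depth
  m[c(11, 12), 1] <- m[c(11, 12), 1] + dorsal_shift
  m[4, 2] <- m[4, 2] + eye_raise
  m[c(13, 14, 16, 17), 2] <- m[c(13, 14, 16, 17), 2] * peduncle
  m
}

#' Default four-species templates
#'
#' Templates for the four sympatric taxa of the study system: two
#' \emph{Squalius}-like streamlined species (the \emph{S. lucumonis}-like one
#' with twice the within-group shape spread), plus a deeper-bodied
#' \emph{T. muticellus}-like and \emph{R. rubilio}-like pair.  Each template
#' carries a 21-landmark mean shape, within-group landmark noise, overlapping
#' meristic count ranges (lateral-line scales separating the
#' \emph{Squalius}-like pair from the others, anal/pectoral fin rays
#' refining), and per-marker divergence from a common ancestor with
#' species-specific Cyfun P indel blocks (including a 17 bp terminal deletion
#' in the \emph{S. lucumonis}-like species).
#'
#' @param shape_noise_sd Within-group isotropic landmark noise, in units of
#'   centroid size (default 0.004, which places the largest between-species
#'   Mahalanobis distance near 14-15 and leave-one-out accuracy in the 90s,
#'   the regime of the study system).
#' @return Named list of \code{species_template} objects (Sl, Ss, Tm, Rr).
#' @export
species_templates <- function(shape_noise_sd = 0.004) {
  tpl <- function(name, mean_shape, mult, meristics, divergence, indels,
                  clade = name) {
    structure(list(name = name, mean_shape = mean_shape,
                   shape_noise_sd = shape_noise_sd,
                   shape_spread_multiplier = mult,
                   meristic_ranges = meristics,
                   divergence = divergence,
                   clade = clade,
                   clade_fraction = c(cytb = 0.6, rag1 = 0.6, cyfunp = 0.25),
                   cyfunp_indels = indels),
              class = "species_template")
  }
  div <- c(cytb = 0.06, rag1 = 0.007, cyfunp = 0.015)
  list(
    Sl = tpl("Sl",
             make_mean_shape(depth = 0.88, dorsal_shift = 0.02,
                             eye_raise = 0.008, peduncle = 0.92),
             mult = 2,
             meristics = list(NSLL = c(43L, 48L), NSALL = c(7L, 9L),
                              NSULL = c(3L, 5L), NRDF = c(8L, 9L),
                              NRPF = c(13L, 16L), NRAF = c(8L, 10L)),
             divergence = div, clade = "Squalius",
             indels = list(c(start = 201L, length = 25L),
                           c(start = 424L, length = 17L))),
    Ss = tpl("Ss",
             make_mean_shape(depth = 0.84, dorsal_shift = -0.01,
                             eye_raise = 0, peduncle = 1.04),
             mult = 1,
             meristics = list(NSLL = c(45L, 50L), NSALL = c(7L, 10L),
                              NSULL = c(3L, 5L), NRDF = c(8L, 9L),
                              NRPF = c(15L, 18L), NRAF = c(10L, 12L)),
             divergence = div, clade = "Squalius",
             indels = list(c(start = 201L, length = 25L))),
    Tm = tpl("Tm",
             make_mean_shape(depth = 1.08, dorsal_shift = -0.025,
                             eye_raise = 0.012, peduncle = 0.94),
             mult = 1,
             meristics = list(NSLL = c(50L, 58L), NSALL = c(8L, 11L),
                              NSULL = c(4L, 6L), NRDF = c(8L, 10L),
                              NRPF = c(13L, 16L), NRAF = c(9L, 11L)),
             divergence = div,
             indels = list(c(start = 151L, length = 130L))),
    Rr = tpl("Rr",
             make_mean_shape(depth = 1.14, dorsal_shift = 0.015,
                             eye_raise = 0, peduncle = 1.06),
             mult = 1,
             meristics = list(NSLL = c(36L, 42L), NSALL = c(7L, 9L),
                              NSULL = c(3L, 5L), NRDF = c(9L, 10L),
                              NRPF = c(12L, 15L), NRAF = c(10L, 12L)),
             divergence = div,
             indels = list()))
}

#' Table-1 group sizes of the study design
#' @return Named integer vector (Sl, Ss, Tm, Rr) = (65, 26, 27, 27).
#' @export
default_group_sizes <- function() c(Sl = 65L, Ss = 26L, Tm = 27L, Rr = 27L)

specimen_roster <- function(templates, n_per_species) {
  unlist(lapply(names(templates), function(sp)
    sprintf("%s%02d", sp, seq_len(n_per_species[[sp]]))), use.names = FALSE)
}

#' Simulate labeled landmark configurations
#'
#' Each specimen is its species' mean shape (normalized to unit centroid
#' size) plus isotropic Gaussian landmark noise of sd
#' \code{shape_noise_sd * shape_spread_multiplier}, then pushed back into
#' "digitizing" space by a random rotation, translation and scale -- exactly
#' the nuisance variation that Procrustes superimposition removes.
#'
#' @param templates Named list from [species_templates()].
#' @param n_per_species Named integer vector of group sizes.
#' @param seed Integer seed.
#' @return A \code{landmark_configs} object with true taxon labels.
#' @export
simulate_landmarks <- function(templates = species_templates(),
                               n_per_species = default_group_sizes(),
                               seed = 1L) {
  stopifnot(all(names(templates) %in% names(n_per_species)))
  if (any(n_per_species[names(templates)] < 2L)) {
    stop("need n_per_species >= 2 for every species")
  }
  set.seed(seed)
  k <- nrow(templates[[1]]$mean_shape)
  ids <- specimen_roster(templates, n_per_species)
  n <- length(ids)
  arr <- array(NA_real_, dim = c(k, 2, n))
  taxon <- character(n)
  i <- 0L
  for (sp in names(templates)) {
    t <- templates[[sp]]
    mean_shape <- center_scale(t$mean_shape)   # also validates non-degeneracy
    sd_i <- t$shape_noise_sd * t$shape_spread_multiplier
    for (s in seq_len(n_per_species[[sp]])) {
      i <- i + 1L
      shape <- mean_shape + matrix(stats::rnorm(2 * k, sd = sd_i), k, 2)
      theta <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      scale <- exp(stats::runif(1, log(80), log(160)))
      shift <- stats::runif(2, 100, 900)
      arr[, , i] <- sweep(scale * shape %*% R, 2, shift, `+`)
      taxon[i] <- sp
    }
  }
  structure(list(coords = arr, specimen_id = ids, taxon = taxon),
            class = "landmark_configs")
}

#' Simulate meristic count records
#'
#' Each of the six counts is drawn uniformly from the species' configured
#' integer interval.  The default intervals overlap between species the way
#' the study system's do: lateral-line scale counts separate the
#' \emph{Squalius}-like pair from the other two species, and anal/pectoral
#' fin-ray counts refine the remaining contrasts.
#'
#' @inheritParams simulate_landmarks
#' @return Data frame with \code{specimen_id}, \code{taxon} and the six counts.
#' @export
simulate_meristics <- function(templates = species_templates(),
                               n_per_species = default_group_sizes(),
                               seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (sp in names(templates)) {
    t <- templates[[sp]]
    nsp <- n_per_species[[sp]]
    row <- data.frame(specimen_id = sprintf("%s%02d", sp, seq_len(nsp)),
                      taxon = sp, stringsAsFactors = FALSE)
    for (ch in MERISTIC_CHARACTERS) {
      rng <- t$meristic_ranges[[ch]]
      if (is.null(rng) || rng[2] < rng[1]) stop("empty interval for ", ch)
      row[[ch]] <- sample(seq.int(rng[1], rng[2]), nsp, replace = TRUE)
    }
    rows[[sp]] <- row
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

mutate_seq <- function(chars, prob) {
  hit <- which(stats::runif(length(chars)) < prob & chars %in% BASES)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  chars
}

#' Simulate an aligned sequence set for one marker
#'
#' A common ancestor sequence is mutated independently on each species branch
#' at per-site probability \code{divergence[marker]}; within species a small
#' number of haplotype variants (default 2) are derived at probability
#' \code{divergence/20} and assigned to specimens at random.  For the
#' non-coding Cyfun P marker, species-specific deletion blocks from the
#' template (including a 17 bp terminal deletion in the
#' \emph{S. lucumonis}-like species) are applied as gaps, so the set is
#' returned aligned; cyt b and RAG1 evolve without indels.
#'
#' @inheritParams simulate_landmarks
#' @param marker One of \code{"cytb"}, \code{"rag1"}, \code{"cyfunp"}.
#' @param n_haplotypes Haplotype variants per species (default 2).
#' @return An aligned \code{sequence_set} with taxon labels.
#' @export
simulate_sequences <- function(templates = species_templates(),
                               marker = c("cytb", "rag1", "cyfunp"),
                               n_per_species = default_group_sizes(),
                               seed = 1L, n_haplotypes = 2L) {
  marker <- match.arg(marker)
  len <- c(cytb = 1131L, rag1 = 840L, cyfunp = 440L)[[marker]]
  set.seed(seed)
  ancestor <- sample(BASES, len, replace = TRUE)
  # congeneric species share a clade ancestor: total root-to-tip divergence is
  # d, split (1 - f) on the clade stem and f on each species branch
  clade_anc <- list()
  seqs <- character(0)
  for (sp in names(templates)) {
    t <- templates[[sp]]
    d <- t$divergence[[marker]]
    if (is.null(d) || is.na(d)) stop("marker unknown to template: ", marker)
    shared <- vapply(templates, function(x) identical(x$clade, t$clade), logical(1))
    if (sum(shared) > 1L) {
      f <- t$clade_fraction[[marker]]
      if (is.null(clade_anc[[t$clade]])) {
        clade_anc[[t$clade]] <- mutate_seq(ancestor, d * (1 - f))
      }
      species_base <- mutate_seq(clade_anc[[t$clade]], d * f)
    } else {
      species_base <- mutate_seq(ancestor, d)
    }
    if (marker == "cyfunp") {
      for (block in t$cyfunp_indels) {
        idx <- seq.int(block[["start"]], length.out = block[["length"]])
        species_base[idx] <- "-"
      }
    }
    haps <- lapply(seq_len(n_haplotypes), function(h) {
      if (h == 1L) species_base else mutate_seq(species_base, d / 20)
    })
    nsp <- n_per_species[[sp]]
    assign <- sort(sample.int(n_haplotypes, nsp, replace = TRUE))
    for (s in seq_len(nsp)) {
      nm <- sprintf("%s%02d|%s", sp, s, sp)
      seqs[nm] <- paste(haps[[assign[s]]], collapse = "")
    }
  }
  sequence_set(seqs, marker)
}

#' Simulate a fully integrated four-species dataset
#'
#' Generates sequences for both phylogenetic markers, embeds their pairwise
#' p-distances by principal coordinates, and constructs each specimen's shape
#' as the base outline displaced along two orthonormal tangent directions in
#' proportion to its genetic coordinates -- so between-species shape offsets
#' are proportional to between-species genetic distances by construction.
#' Isotropic shape noise is then calibrated analytically so the expected
#' first-pair PLS correlation equals \code{target_R}: with planted offset
#' scale \eqn{\beta\sqrt{\lambda_1}} and per-coordinate noise sd \eqn{s},
#' \eqn{R = \beta\sqrt{\lambda_1} / \sqrt{\beta^2\lambda_1 + s^2}}.
#' Optionally one specimen's sequences (all markers) are swapped to another
#' species after the shapes are built, planting a genotype/phenotype
#' disagreement for the integration report to flag.
#'
#' @inheritParams simulate_landmarks
#' @param target_R Planted first-pair PLS correlation, in (0, 1].
#' @param offset_scale Standard deviation of the planted shape offsets along
#'   the leading genetic axis, in centroid-size units (default 0.02).
#' @param planted_outlier \code{NULL}, or a length-2 character vector
#'   \code{c(from, to)}: the first specimen of species \code{from} receives
#'   the base haplotype of species \code{to}.
#' @return A \code{synthetic_dataset}: \code{configs}, \code{meristics},
#'   \code{alignments} (cytb, rag1, cyfunp), and \code{truth} (generator
#'   parameters, analytic first-pair R, noise sd, outlier id, genetic scores).
#' @export
simulate_integrated <- function(templates = species_templates(),
                                n_per_species = default_group_sizes(),
                                target_R = 0.9, seed = 1L,
                                offset_scale = 0.02,
                                planted_outlier = NULL) {
  if (target_R > 1) stop("target_R must be <= 1")
  if (target_R <= 0.05) {
    stop("unattainable target_R: needs shape noise sd > ",
         format(offset_scale * sqrt(1 - 0.05^2) / 0.05, digits = 3),
         " centroid-size units; the attainable range is (0.05, 1]")
  }
  seed <- as.integer(seed) %% 2147480000L
  alignments <- list(
    cytb = simulate_sequences(templates, "cytb", n_per_species, seed = seed + 1L),
    rag1 = simulate_sequences(templates, "rag1", n_per_species, seed = seed + 2L),
    cyfunp = simulate_sequences(templates, "cyfunp", n_per_species, seed = seed + 3L))
  dm <- p_distance_matrix(alignments[c("cytb", "rag1")])
  G <- pcoa(dm)$coordinates[, 1:2, drop = FALSE]
  Gc <- sweep(G, 2, colMeans(G))
  eg <- eigen(stats::cov(Gc), symmetric = TRUE)
  lambda1 <- eg$values[1]
  beta <- offset_scale / sqrt(lambda1)
  ids <- specimen_roster(templates, n_per_species)
  taxon <- rep(names(templates), n_per_species[names(templates)])
  n <- length(ids)
  mults <- vapply(templates, `[[`, numeric(1), "shape_spread_multiplier")
  msq <- sum(n_per_species[names(templates)] * mults^2) / n
  s_target <- offset_scale * sqrt(1 - target_R^2) / target_R
  noise_sd <- s_target / sqrt(msq)
  base <- center_scale(templates[[1]]$mean_shape)
  basis <- bending_energy_basis(base)
  E1 <- basis$principal_warps[, 1]
  k <- nrow(base)
  set.seed(seed + 4L)
  arr <- array(NA_real_, dim = c(k, 2, n))
  Gv <- Gc %*% eg$vectors     # genetic coordinates on their principal axes
  for (i in seq_len(n)) {
    offset <- beta * cbind(Gv[i, 1] * E1, Gv[i, 2] * E1)
    sd_i <- noise_sd * mults[[taxon[i]]]
    shape <- base + offset + matrix(stats::rnorm(2 * k, sd = sd_i), k, 2)
    theta <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    scale <- exp(stats::runif(1, log(80), log(160)))
    shift <- stats::runif(2, 100, 900)
    arr[, , i] <- sweep(scale * shape %*% R, 2, shift, `+`)
  }
  configs <- structure(list(coords = arr, specimen_id = ids, taxon = taxon),
                       class = "landmark_configs")
  outlier_id <- NULL
  if (!is.null(planted_outlier)) {
    from <- planted_outlier[[1]]; to <- planted_outlier[[2]]
    if (!all(c(from, to) %in% names(templates))) stop("unknown species in planted_outlier")
    outlier_id <- sprintf("%s01", from)
    for (mk in names(alignments)) {
      al <- alignments[[mk]]
      donor <- which(al$taxon == to)[1]
      al$seq[al$specimen_id == outlier_id] <- al$seq[donor]
      alignments[[mk]] <- al
    }
  }
  meristics <- simulate_meristics(templates, n_per_species, seed = seed + 5L)
  structure(list(configs = configs,
                 meristics = meristics,
                 alignments = alignments,
                 truth = list(target_R = target_R,
                              analytic_R = target_R,
                              beta = beta, lambda1 = lambda1,
                              offset_scale = offset_scale,
                              noise_sd = noise_sd,
                              outlier_id = outlier_id,
                              genetic_scores = Gv,
                              seed = seed)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes \code{landmarks.tps}, \code{meristics.csv}, one FASTA per marker and
#' \code{truth.json} under \code{out_dir}.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, \code{out_dir}.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$configs
  recs <- lapply(seq_along(cfg$specimen_id), function(i) {
    structure(list(specimen_id = cfg$specimen_id[i],
                   landmark_count = dim(cfg$coords)[1],
                   coords = cfg$coords[, , i], scale = NULL),
              class = "tps_record")
  })
  write_tps(recs, file.path(out_dir, "landmarks.tps"))
  write_meristic_csv(dataset$meristics, file.path(out_dir, "meristics.csv"))
  for (mk in names(dataset$alignments)) {
    write_fasta(dataset$alignments[[mk]], file.path(out_dir, paste0(mk, ".fasta")))
  }
  truth <- dataset$truth
  truth$genetic_scores <- NULL
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
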