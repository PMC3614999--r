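toy_set <- function(seqs, marker = "cytb") sequence_set(seqs, marker)

test_that("variable-site counting follows the gap and N conventions", {
  s <- toy_set(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"))
  v <- count_variable_sites(s)
  expect_equal(v$variable, 0)
  expect_equal(v$pct, 0)
  # planted differences at columns 2 and 7 only
  s2 <- toy_set(c(a = "ACGTACGTAC", b = "AGGTACATAC", c = "ACGTACGTAC"))
  expect_equal(count_variable_sites(s2)$variable, 2)
  # N-only variation and gap-with-one-base columns do not count
  s3 <- toy_set(c(a = "ANG-A", b = "AAGCA", c = "AAG-T"))
  expect_equal(count_variable_sites(s3)$variable, 1)   # only column 5
  # order invariance
  s4 <- toy_set(c(c = "ACGTACGTAC", a = "AGGTACATAC", b = "ACGTACGTAC"))
  expect_equal(count_variable_sites(s4)$variable,
               count_variable_sites(s2)$variable)
  expect_error(count_variable_sites(toy_set(c(a = "ACG", b = "AC"))),
               "not aligned")
})

test_that("variable sites agree with seg.sites on gap-free data (cross-check)", {
  set <- simulate_sequences(marker = "cytb", n_per_species = small_sizes(4),
                            seed = 12)
  m <- tolower(do.call(rbind, strsplit(set$seq, "")))
  expect_equal(count_variable_sites(set)$variable,
               length(ape::seg.sites(ape::as.DNAbin(m))))
})

test_that("haplotype collapse is exact with N kept distinct", {
  s <- toy_set(c(x1 = "ACGT", x2 = "ACGT", x3 = "ACGT", x4 = "ACGT"))
  h <- collapse_haplotypes(s)
  expect_equal(nrow(h$haplotypes), 1)
  expect_equal(h$haplotypes$multiplicity, 4)
  s2 <- toy_set(c(x1 = "ACGT", x2 = "ACGA", x3 = "ACGN"))
  expect_equal(nrow(collapse_haplotypes(s2)$haplotypes), 3)
  expect_equal(sum(collapse_haplotypes(s2)$haplotypes$multiplicity), 3)
  # generator-known truth: one species, one haplotype under zero divergence
  tpl <- species_templates()
  for (sp in names(tpl)) tpl[[sp]]$divergence[] <- 0
  s3 <- simulate_sequences(tpl, "rag1", small_sizes(5), seed = 3,
                           n_haplotypes = 1L)
  expect_equal(nrow(collapse_haplotypes(s3)$haplotypes), 1)
  expect_equal(count_variable_sites(s3)$variable, 0)
})

test_that("pairwise identity excludes gapped positions and can align first", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAT"), 90)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 100)   # gap column dropped
  expect_error(pairwise_identity("----", "AC-T"), "overlap|undefined")
  # global alignment recovers identity across an indel
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGTACGTCGTACGTACGT"   # one base deleted
  expect_gte(pairwise_identity(a, b, mode = "global_align"), 95)
})

test_that("p-distances match a naive site-loop oracle and average across markers", {
  set <- toy_set(c("s1|A" = "ACGTACGTAC", "s2|A" = "ACCTACGAAC",
                   "s3|B" = "ANGTAC-TAC"))
  dm <- p_distance_matrix(set)
  naive <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    ok <- cx %in% c("A", "C", "G", "T") & cy %in% c("A", "C", "G", "T")
    sum(cx[ok] != cy[ok]) / sum(ok)
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(dm$values[i, j], naive(set$seq[i], set$seq[j]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(dm$values))
  expect_true(all(diag(dm$values) == 0))
  # two markers: unweighted per-pair average
  set2 <- toy_set(c("s1|A" = "AAAA", "s2|A" = "AAAT", "s3|B" = "AATT"), "rag1")
  set3 <- toy_set(c("s1|A" = "GGGG", "s2|A" = "GGGG", "s3|B" = "CCCC"), "cytb")
  dm2 <- p_distance_matrix(list(set2, set3))
  expect_equal(dm2$values["s1", "s2"], (0.25 + 0) / 2)
  expect_equal(dm2$values["s1", "s3"], (0.5 + 1) / 2)
  expect_error(p_distance_matrix(list(set2, toy_set(c("x1|A" = "AAAA",
                                                      "x2|B" = "AAAT",
                                                      "x3|B" = "AATT")))),
               "roster")
})

test_that("diagnostic differences report fixed substitutions and maximal indels", {
  s <- toy_set(c("a1|A" = "ACGTAAA--A", "a2|A" = "ACGTAAA--A",
                 "b1|B" = "ACATATACGA", "b2|B" = "ACATATACGA"))
  dd <- diagnostic_differences(s, "A", "B")
  # column 3 G->A fixed (transition), column 6 A->T fixed (transversion),
  # columns 8-9 one maximal deletion block in A
  expect_equal(dd$substitutions$position, c(3, 6))
  expect_equal(dd$substitutions$class, c("transition", "transversion"))
  expect_equal(nrow(dd$indels), 1)
  expect_equal(dd$indels$start, 8)
  expect_equal(dd$indels$length, 2)
  expect_equal(dd$indels$missing_in, "A")
  # shared polymorphism is not diagnostic
  s2 <- toy_set(c("a1|A" = "AC", "a2|A" = "GC", "b1|B" = "AT", "b2|B" = "GT"))
  dd2 <- diagnostic_differences(s2, "A", "B")
  expect_equal(dd2$substitutions$position, 2)
  # symmetry under swapping group labels
  dd_swap <- diagnostic_differences(s, "B", "A")
  expect_equal(dd_swap$substitutions$state_a, dd$substitutions$state_b)
  expect_equal(dd_swap$substitutions$state_b, dd$substitutions$state_a)
  expect_equal(dd_swap$indels$missing_in, dd$indels$missing_in)
  # a group against itself is clean
  dd_self <- diagnostic_differences(s, "A", "A")
  expect_equal(nrow(dd_self$substitutions), 0)
  expect_equal(nrow(dd_self$indels), 0)
  expect_error(diagnostic_differences(s, "A", "Z"), "absent")
})

test_that("band-length attribution uses the genus-informative intervals", {
  expect_equal(band_length_attribution(310), "T. muticellus")
  expect_equal(band_length_attribution(440), "R. rubilio")
  expect_equal(band_length_attribution(410), "Squalius")
  expect_equal(band_length_attribution(370), "unassigned")
  bad_key <- data.frame(label = c("x", "y"), min = c(300, 310), max = c(320, 330))
  expect_error(band_length_attribution(315, bad_key), "overlap")
})

test_that("PCoA recovers planar configurations and the trace identity", {
  pts <- cbind(c(0, 3, 3, 0), c(0, 0, 2, 2))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  res <- pcoa(D)
  expect_equal(sum(res$eigenvalues > 1e-9), 2)
  rec <- as.matrix(dist(res$coordinates[, 1:2]))
  expect_lt(max(abs(rec - D)), 1e-9)
  expect_equal(sum(res$eigenvalues),
               sum(diag(leucidelim:::gower_center(D))), tolerance = 1e-9)
  expect_equal(res$negative_eigenvalue_sum, 0, tolerance = 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    expect_gt(res$coordinates[which.max(abs(res$coordinates[, j])), j], 0)
  }
})

test_that("PCoA eigenvalues match the characteristic-polynomial oracle", {
  D <- matrix(c(0, 2, 5, 2, 0, 4, 5, 4, 0), 3, 3)
  res <- pcoa(D)
  oracle <- eigen3_oracle(leucidelim:::gower_center(D))
  expect_equal(res$eigenvalues, oracle, tolerance = 1e-8)
  # cross-check against classical MDS
  cmd <- cmdscale(as.dist(D), k = 2, eig = TRUE)
  expect_equal(res$eigenvalues[1:2], cmd$eig[1:2], tolerance = 1e-9)
})

test_that("similarity summaries expose within- and between-species structure", {
  set <- simulate_sequences(marker = "cytb", n_per_species = small_sizes(4),
                            seed = 21)
  ss <- similarity_summary(set)
  within <- ss$mean[ss$group_a == ss$group_b]
  between <- ss$mean[ss$group_a != ss$group_b]
  expect_true(all(within > max(between)))
  sl_ss <- ss$mean[ss$group_a == "Sl" & ss$group_b == "Ss"]
  expect_true(all(sl_ss > ss$mean[ss$group_a != ss$group_b &
                                    !(ss$group_a == "Sl" & ss$group_b == "Ss")]))
})
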