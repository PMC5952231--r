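test_that("haplotype collapsing respects the column-exclusion policy", {
  aln <- marker_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                          "m")
  expect_equal(length(unique(collapse_haplotypes(aln))), 1L)
  # rows differ only at a gap-containing column: same haplotype
  aln2 <- marker_alignment(c(a = "ACGT", b = "ACAT", c = "AC-T"), "m")
  h <- collapse_haplotypes(aln2)
  expect_equal(h[["a"]], h[["b"]])
  expect_equal(attr(h, "n_sites"), 3L)
  # everything excluded: degenerate
  aln3 <- marker_alignment(c(a = "-N", b = "N-"), "m")
  expect_warning(h3 <- collapse_haplotypes(aln3), "degenerate")
  expect_equal(length(unique(h3)), 1L)

  set.seed(202)
  for (rep in 1:25) {
    aln <- rand_aln(sample(3:10, 1), sample(5:30, 1), p_gap = 0.1, p_n = 0.1)
    got <- as.integer(collapse_haplotypes(aln))
    want <- oracle_haplotypes(aln$seqs)
    expect_equal(got, want)
  }
})

test_that("haplotype diversity follows the corrected frequency formula", {
  expect_equal(haplotype_diversity(1:5), 1)
  expect_equal(haplotype_diversity(rep(1, 6)), 0)
  expect_equal(haplotype_diversity(c(1, 1, 2, 2)), (4 / 3) * (1 - 0.5))
  expect_true(is.na(haplotype_diversity(1)))
})

test_that("nucleotide diversity matches the exhaustive pair loop", {
  two <- marker_alignment(c(a = "ACGT", b = "ACGA"), "m")
  expect_equal(nucleotide_diversity(two), 0.25)
  same <- marker_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"), "m")
  expect_equal(nucleotide_diversity(same), 0)
  set.seed(212)
  for (rep in 1:25) {
    aln <- rand_aln(sample(3:8, 1), sample(6:30, 1), p_gap = 0.1)
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln$seqs))
  }
})

test_that("segregating sites count distinct states on retained columns", {
  same <- marker_alignment(c(a = "ACGT", b = "ACGT"), "m")
  expect_equal(segregating_sites(same)$S, 0L)
  one <- marker_alignment(c(a = "AACT", b = "AACT", c = "AGCT"), "m")
  ss <- segregating_sites(one)
  expect_equal(ss$S, 1L)
  expect_equal(ss$S_pct, 25)
  set.seed(222)
  for (rep in 1:20) {
    aln <- rand_aln(sample(3:8, 1), sample(6:30, 1), p_gap = 0.1, p_n = 0.1)
    expect_equal(segregating_sites(aln)$S, oracle_segsites(aln$seqs))
  }
})

test_that("indel events are maximal runs deduplicated across rows", {
  one <- marker_alignment(c(a = "AC---GT", b = "ACAAAGT"), "m")
  expect_equal(count_indel_events(one), 1L)
  shared <- marker_alignment(c(a = "AC---GT", b = "AC---GT"), "m")
  expect_equal(count_indel_events(shared), 1L)
  overlap <- marker_alignment(c(a = "AC---GT", b = "ACC--GT"), "m")
  expect_equal(count_indel_events(overlap), 2L)
  none <- marker_alignment(c(a = "ACGT", b = "ACGT"), "m")
  expect_equal(count_indel_events(none), 0L)
})

test_that("grouped statistics flag singletons and pool consistently", {
  seqs <- c(a1 = "ACGTACGT", a2 = "ACGTACGA", b1 = "TTGTACGT", c1 = "ACGAACGT")
  aln <- marker_alignment(seqs, "m")
  tab <- data.frame(individual_id = names(seqs),
                    species = c("A", "A", "B", "C"),
                    section = c("S1", "S1", "S2", "S3"),
                    region = "r")
  gs <- group_stats(aln, tab, group_by = "section")
  expect_true(gs$singleton[gs$group == "S2"])
  expect_true(is.na(gs$Pi[gs$group == "S2"]))
  s1 <- gs[gs$group == "S1", ]
  expect_equal(s1$N, 2L)
  expect_equal(s1$Hn, 2L)
  expect_equal(s1$Pi, 1 / 8)

  ident <- marker_alignment(c(x = "AAAA", y = "AAAA", z = "AAAA"), "m")
  tabi <- data.frame(individual_id = c("x", "y", "z"), species = "A",
                     section = "S", region = "r")
  gi <- group_stats(ident, tabi, group_by = "dataset")
  expect_equal(gi$Pi, 0)
  expect_equal(gi$Hd, 0)
  expect_equal(gi$S, 0L)

  # pooling never reduces the haplotype count below either group's
  set.seed(232)
  for (rep in 1:10) {
    aln <- rand_aln(8, 20, p_gap = 0.05)
    grp <- sample(c("G1", "G2"), 8, replace = TRUE)
    if (length(unique(grp)) < 2) next
    tabr <- data.frame(individual_id = aln$ids, species = "sp",
                       section = grp, region = "r")
    per <- group_stats(aln, tabr, group_by = "section")
    all_h <- length(unique(collapse_haplotypes(aln)))
    expect_true(all(na.omit(per$Hn) <= all_h + 0L))
    expect_true(all_h >= max(per$Hn, na.rm = TRUE))
  }
})

test_that("Pi, Hd and haplotypes are order-invariant and analytically linked", {
  set.seed(242)
  aln <- rand_aln(7, 25, p_gap = 0.05)
  perm <- sample(aln$ids)
  aln2 <- marker_alignment(aln$seqs[perm, ], "m")
  expect_equal(nucleotide_diversity(aln), nucleotide_diversity(aln2))
  expect_equal(haplotype_diversity(collapse_haplotypes(aln)),
               haplotype_diversity(collapse_haplotypes(aln2)))

  # two-haplotype data: Pi equals Hd times the haplotype distance
  seqs <- rbind(matrix(rep(c("A", "A", "C", "G"), 3), 3, byrow = TRUE),
                matrix(rep(c("A", "T", "C", "T"), 2), 2, byrow = TRUE))
  rownames(seqs) <- paste0("i", 1:5)
  aln3 <- marker_alignment(seqs, "m")
  d <- p_distance(seqs[1, ], seqs[5, ])$distance
  hd <- haplotype_diversity(collapse_haplotypes(aln3))
  expect_equal(nucleotide_diversity(aln3), hd * d)
})

test_that("principal coordinates reproduce Euclidean configurations", {
  # collinear points: axis 1 recovers spacings up to sign
  pos <- c(0, 1, 2.5, 4, 7)
  V <- abs(outer(pos, pos, "-")); diag(V) <- 0
  dimnames(V) <- list(paste0("p", 1:5), paste0("p", 1:5))
  ord <- pcoa_ordination(as_pdist_matrix(V), k = 4)
  ax1 <- ord$coordinates[, 1]
  expect_equal(unname(sort(diff(sort(ax1)))), sort(diff(pos)),
               tolerance = 1e-8)

  # three equidistant points: two equal positive eigenvalues
  V3 <- matrix(1, 3, 3); diag(V3) <- 0
  dimnames(V3) <- list(letters[1:3], letters[1:3])
  ord3 <- pcoa_ordination(as_pdist_matrix(V3), k = 2)
  eig <- sort(ord3$eigenvalues[ord3$eigenvalues > 1e-9], decreasing = TRUE)
  expect_equal(eig[1], eig[2], tolerance = 1e-9)

  # full-rank Euclidean input: distances reconstructed within 1e-8
  set.seed(252)
  X <- matrix(rnorm(6 * 3), 6, 3)
  D <- as.matrix(dist(X)); dimnames(D) <- list(paste0("q", 1:6),
                                               paste0("q", 1:6))
  ordE <- pcoa_ordination(as_pdist_matrix(D), k = 5)
  recon <- as.matrix(dist(ordE$coordinates))
  expect_lt(max(abs(recon - D)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(sum(ordE$explained), 1 + 1e-12)

  Dm <- D; Dm[1, 2] <- Dm[2, 1] <- NA
  expect_error(pcoa_ordination(as_pdist_matrix(Dm)), "missing")
})
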