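small_markers <- data.frame(name = c("m1", "m2"), length = c(300L, 200L),
                            rate = c(1, 2), stringsAsFactors = FALSE)

test_that("configuration validates and the seed is mandatory", {
  expect_error(sim_config(n_species = 5, seed = NULL), "seed")
  expect_error(sim_config(n_species = 0, seed = 1), "at least one species")
  expect_error(sim_config(introgression_prob = 1.5, seed = 1))
  cfg <- sim_config(n_species = 3, individuals_per_species = 2,
                    markers = small_markers, seed = 9)
  expect_s3_class(cfg, "sim_config")
})

test_that("simulation is byte-deterministic given the seed", {
  cfg <- sim_config(n_species = 5, individuals_per_species = c(1, 4),
                    markers = small_markers, height = 8, seed = 33)
  t1 <- simulate_barcode_data(cfg)
  t2 <- simulate_barcode_data(cfg)
  expect_identical(t1$samples, t2$samples)
  for (m in names(t1$alignments))
    expect_identical(t1$alignments[[m]]$seqs, t2$alignments[[m]]$seqs)
  expect_identical(write_newick(t1$species_tree),
                   write_newick(t2$species_tree))
  t3 <- simulate_barcode_data(sim_config(n_species = 5,
                                         individuals_per_species = c(1, 4),
                                         markers = small_markers, height = 8,
                                         seed = 34))
  expect_false(identical(t1$alignments$m1$seqs, t3$alignments$m1$seqs))
})

test_that("the truth set is structurally consistent", {
  cfg <- sim_config(n_species = 6, individuals_per_species = 3,
                    markers = small_markers, height = 10,
                    introgression_prob = 0.3, indel_rate = 1e-3, seed = 44)
  ts <- simulate_barcode_data(cfg)
  expect_equal(length(ts$samples$individual_id), 18L)
  for (m in names(ts$alignments)) {
    aln <- ts$alignments[[m]]
    expect_identical(aln$ids, ts$samples$individual_id)
    expect_equal(aln$length,
                 small_markers$length[small_markers$name == m])
  }
  expect_true(all(ts$introgressed %in% ts$samples$individual_id))
  expect_equal(sort(ts$species_tree$tip.label),
               sort(unique(ts$samples$species)))
})

test_that("expected diversity scales with theta and marker rate", {
  cfg <- sim_config(n_species = 2, individuals_per_species = 2,
                    theta_w = 0.005, markers = small_markers, seed = 5)
  ep <- expected_pi(cfg)
  expect_equal(unname(ep["m1"]), 0.005)
  expect_equal(unname(ep["m2"]), 0.01)
  cfg_m <- sim_config(n_species = 2, individuals_per_species = 2,
                      introgression_prob = 0.2, markers = small_markers,
                      seed = 5)
  expect_error(expected_pi(cfg_m), "unsupported")
})

test_that("one individual per species gives trivially sorted gene trees", {
  cfg <- sim_config(n_species = 8, individuals_per_species = 1,
                    markers = small_markers, height = 10, seed = 55)
  ts <- simulate_barcode_data(cfg)
  for (gt in ts$gene_trees) {
    expect_equal(sort(gt$tip.label), sort(ts$samples$individual_id))
    for (s in unique(ts$samples$species)) {
      tips <- ts$samples$individual_id[ts$samples$species == s]
      expect_true(as.logical(is_monophyletic_tips(
        root_with_outgroup(gt, gt$tip.label[1]), tips)))
    }
  }
})

test_that("deep divergence without introgression leaves species sorted", {
  cfg <- sim_config(n_species = 6, individuals_per_species = 4,
                    markers = small_markers, height = 120,
                    topology = "balanced", theta_w = 5e-4, seed = 66)
  ts <- simulate_barcode_data(cfg)
  dm <- suppressMessages(distance_matrix(
    concatenate_markers(ts$alignments, combo_spec(c("m1", "m2")))))
  sets <- split_intra_inter(dm, ts$samples)
  expect_gt(min(sets$inter), max(sets$intra))
})

test_that("shallow species trees generate incomplete lineage sorting", {
  # within-species coalescence (about 1 unit) far exceeds the internodes
  n_non_mono <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_species = 6, individuals_per_species = 4,
                      markers = small_markers[1, ], height = 0.5,
                      topology = "balanced", seed = 700 + s)
    ts <- simulate_barcode_data(cfg)
    gt <- root_with_outgroup(ts$gene_trees[[1]],
                             ts$gene_trees[[1]]$tip.label[1])
    mono <- vapply(unique(ts$samples$species), function(sp) {
      as.logical(is_monophyletic_tips(
        gt, ts$samples$individual_id[ts$samples$species == sp]))
    }, logical(1))
    if (!all(mono)) n_non_mono <- n_non_mono + 1L
  }
  expect_gte(n_non_mono, 4L)
})

test_that("truth sets round-trip through disk", {
  cfg <- sim_config(n_species = 4, individuals_per_species = 2,
                    markers = small_markers, height = 10,
                    indel_rate = 1e-3, seed = 77)
  ts <- simulate_barcode_data(cfg)
  dir <- withr::local_tempdir()
  files <- write_truth_set(ts, dir)
  aln <- read_alignment(file.path(dir, "m1.fasta"), "m1")
  expect_identical(aln$seqs, ts$alignments$m1$seqs)
  meta <- read_metadata(file.path(dir, "samples.tsv"))
  expect_equal(meta$individual_id, ts$samples$individual_id)
  tr <- parse_newick(path = file.path(dir, "species_tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(ts$species_tree$tip.label))
})
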