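# Multispecies-coalescent simulator with introgression (chloroplast
# capture) and indels, producing multi-marker alignments with known
# truth.
#
# Time is measured in coalescent units: two lineages in the same
# population coalesce at rate 1, so their expected coalescence time is
# one unit. theta_w is the expected pairwise intraspecific diversity
# per site at relative rate 1, which fixes the substitution rate at
# mu = theta_w * rate / 2 per site per unit time. Introgression is
# modelled as lineage re-homing: with probability m a sampled
# individual's (maternally inherited, non-recombining) chloroplast
# lineage starts in a random other species' population — the flag is
# therefore shared by all markers of that individual, while each
# marker's genealogy is still drawn independently.

#' Default marker panel
#'
#' Four plastid-like markers with aligned lengths matching a typical
#' universal-marker panel (1187, 691, 554, 796 bp) and relative
#' substitution rates proportional to their observed per-site
#' diversities (an intergenic spacer being the fastest).
#'
#' @return `data.frame` with columns `name`, `length`, `rate`.
#' @export
default_markers <- function() {
  data.frame(
    name = c("atpI-atpH", "matK", "psbA-trnH", "ycf1"),
    length = c(1187L, 691L, 554L, 796L),
    rate = c(0.46, 0.48, 2.07, 0.98),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_species Number of species (>= 1).
#' @param individuals_per_species Fixed count, or a length-2 range from
#'   which each species' sample size is drawn uniformly. Default `c(1, 15)`.
#' @param height Species-tree height in coalescent units.
#' @param topology `"random"` (pure-birth, rescaled to `height`) or
#'   `"balanced"` (evenly spaced split levels).
#' @param theta_w Expected pairwise intraspecific diversity per site at
#'   relative rate 1.
#' @param introgression_prob Probability `m` that an individual's
#'   chloroplast lineage is re-homed to a random other species before
#'   coalescing.
#' @param markers Marker panel, see [default_markers()].
#' @param indel_rate Per-site rate of indel events per tip sequence.
#' @param indel_length_p Geometric parameter for indel lengths
#'   (mean `1/p`).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_species = 40L, individuals_per_species = c(1L, 15L),
                       height = 5, topology = c("random", "balanced"),
                       theta_w = 0.005, introgression_prob = 0,
                       markers = default_markers(), indel_rate = 2e-4,
                       indel_length_p = 0.5, seed) {
  topology <- match.arg(topology)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("input error: seed is mandatory")
  if (n_species < 1L) stop("input error: need at least one species")
  if (any(individuals_per_species < 1L))
    stop("input error: individuals_per_species must be >= 1")
  stopifnot(height > 0, theta_w > 0,
            introgression_prob >= 0, introgression_prob <= 1,
            indel_rate >= 0, indel_length_p > 0, indel_length_p <= 1,
            all(markers$length >= 1L), all(markers$rate > 0))
  structure(list(n_species = as.integer(n_species),
                 individuals_per_species = as.integer(individuals_per_species),
                 height = height, topology = topology, theta_w = theta_w,
                 introgression_prob = introgression_prob, markers = markers,
                 indel_rate = indel_rate, indel_length_p = indel_length_p,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ultrametric balanced species tree with evenly spaced split levels
.balanced_species_tree <- function(labels, height) {
  build <- function(x) {
    if (length(x) == 1L) return(list(leaf = x, lev = 0L))
    h <- ceiling(length(x) / 2)
    a <- build(x[seq_len(h)])
    b <- build(x[-seq_len(h)])
    list(a = a, b = b, lev = max(a$lev, b$lev) + 1L)
  }
  root <- build(labels)
  unit <- height / root$lev
  emit <- function(node) {
    if (!is.null(node$leaf)) return(list(txt = node$leaf, h = 0))
    ca <- emit(node$a); cb <- emit(node$b)
    h <- node$lev * unit
    list(txt = sprintf("(%s:%.10g,%s:%.10g)", ca$txt, h - ca$h,
                       cb$txt, h - cb$h), h = h)
  }
  ape::read.tree(text = paste0(emit(root)$txt, ";"))
}

.random_species_tree <- function(labels, height) {
  n <- length(labels)
  if (n == 1L) return(ape::read.tree(text = paste0(labels, ";")))
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- labels
  dep <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * height / max(dep)
  tr
}

# simulate one gene genealogy under the multispecies coalescent;
# `home` maps each individual id to the species population its lineage
# starts in (after any introgressive re-homing)
.msc_gene_tree <- function(sptree, ids, home) {
  if (length(ids) == 1L) return(NULL)
  nt <- length(sptree$tip.label)
  if (nt == 1L) {
    hgt <- 0
    names(hgt) <- "1"
    children <- list()
    ord <- integer(0)
    pop <- rep(1L, length(ids))
  } else {
    dep <- ape::node.depth.edgelength(sptree)
    hgt <- max(dep[seq_len(nt)]) - dep
    hgt[hgt < 0] <- 0
    children <- split(sptree$edge[, 2], sptree$edge[, 1])
    ints <- nt + seq_len(sptree$Nnode)
    ord <- ints[order(hgt[ints])]
    pop <- match(home, sptree$tip.label)
  }
  frag <- as.list(ids)
  fh <- numeric(length(ids))
  alive <- rep(TRUE, length(ids))

  run_pop <- function(t0, t1) {
    for (p in sort(unique(pop[alive]))) {
      members <- which(alive & pop == p)
      k <- length(members)
      t <- t0
      while (k >= 2L) {
        t <- t + rexp(1, k * (k - 1) / 2)
        if (t >= t1) break
        pick <- sample(members, 2L)
        i <- pick[1L]; j <- pick[2L]
        frag[[i]] <<- sprintf("(%s:%.12g,%s:%.12g)", frag[[i]], t - fh[i],
                              frag[[j]], t - fh[j])
        fh[i] <<- t
        alive[j] <<- FALSE
        members <- setdiff(members, j)
        k <- k - 1L
      }
    }
  }

  t0 <- 0
  for (v in ord) {
    t1 <- hgt[v]
    if (t1 > t0) run_pop(t0, t1)
    ch <- children[[as.character(v)]]
    pop[alive & pop %in% ch] <- v
    t0 <- t1
  }
  run_pop(t0, Inf)
  ape::read.tree(text = paste0(frag[[which(alive)]], ";"))
}

# Jukes-Cantor sequence evolution along a genealogy; returns a character
# matrix of tip sequences
.evolve_jc <- function(gtree, L, mu) {
  gtree <- stats::reorder(gtree, "cladewise")
  nt <- length(gtree$tip.label)
  nn <- nt + gtree$Nnode
  S <- matrix(0L, nn, L)
  root <- nt + 1L
  S[root, ] <- sample.int(4L, L, replace = TRUE)
  for (e in seq_len(nrow(gtree$edge))) {
    par <- gtree$edge[e, 1L]
    ch <- gtree$edge[e, 2L]
    p <- 0.75 * (1 - exp(-4 / 3 * mu * gtree$edge.length[e]))
    x <- S[par, ]
    mask <- runif(L) < p
    nm <- sum(mask)
    if (nm)
      x[mask] <- ((x[mask] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    S[ch, ] <- x
  }
  out <- matrix(c("A", "C", "G", "T")[S[seq_len(nt), , drop = FALSE]],
                nrow = nt, dimnames = list(gtree$tip.label, NULL))
  out
}

#' Simulate a multi-marker barcoding dataset
#'
#' Draws an ultrametric species tree, samples individuals per species,
#' optionally re-homes lineages to model chloroplast capture, simulates
#' one coalescent genealogy per marker within the species tree
#' (incomplete lineage sorting arises whenever within-species
#' coalescence outlasts an internode), evolves sequences root-to-tip
#' under Jukes-Cantor at the marker's relative rate, and overlays indels
#' as maximal gap runs. Byte-deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return A `truth_set`: list with `alignments` (named list of
#'   [marker_alignment()]), `samples` (metadata `data.frame`),
#'   `species_tree` (`phylo`), `introgressed` (ids whose lineage was
#'   re-homed), `gene_trees` (per marker, `phylo`) and `config`.
#' @export
simulate_barcode_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_species
  species <- sprintf("sp%03d", seq_len(ns))
  ipp <- cfg$individuals_per_species
  n_ind <- if (length(ipp) == 1L) rep(ipp, ns)
           else sample(seq(ipp[1L], ipp[2L]), ns, replace = TRUE)
  origin <- rep(species, n_ind)
  ids <- unlist(lapply(seq_len(ns), function(i)
    sprintf("%s_i%02d", species[i], seq_len(n_ind[i]))))

  sptree <- if (cfg$topology == "balanced")
    .balanced_species_tree(species, cfg$height)
  else .random_species_tree(species, cfg$height)

  home <- origin
  flag <- rep(FALSE, length(ids))
  if (cfg$introgression_prob > 0 && ns > 1L) {
    flag <- runif(length(ids)) < cfg$introgression_prob
    for (i in which(flag))
      home[i] <- sample(setdiff(species, origin[i]), 1L)
  }

  sections <- c("Cyclobalanopsis", "Ilex", "Cerris", "Quercus")
  regions <- c("EastChina", "SWChina", "Japan", "Vietnam")
  sec_of_sp <- setNames(rep(sections, length.out = ns), species)
  samples <- data.frame(
    individual_id = ids,
    species = origin,
    section = sec_of_sp[origin],
    region = sample(regions, length(ids), replace = TRUE),
    introgressed = flag,
    stringsAsFactors = FALSE
  )

  alignments <- list()
  gene_trees <- list()
  for (r in seq_len(nrow(cfg$markers))) {
    mk <- cfg$markers[r, ]
    mu <- cfg$theta_w * mk$rate / 2
    gt <- .msc_gene_tree(sptree, ids, home)
    if (is.null(gt)) {   # single individual: no genealogy to draw
      seqs <- matrix(c("A", "C", "G", "T")[sample.int(4L, mk$length,
                                                      replace = TRUE)],
                     nrow = 1, dimnames = list(ids, NULL))
    } else {
      seqs <- .evolve_jc(gt, mk$length, mu)[ids, , drop = FALSE]
    }
    if (cfg$indel_rate > 0) {
      for (i in seq_len(nrow(seqs))) {
        nev <- rpois(1, cfg$indel_rate * mk$length)
        for (ev in seq_len(nev)) {
          len <- min(rgeom(1, cfg$indel_length_p) + 1L, mk$length)
          start <- sample.int(mk$length - len + 1L, 1L)
          seqs[i, start:(start + len - 1L)] <- "-"
        }
      }
    }
    alignments[[mk$name]] <- marker_alignment(seqs, mk$name)
    gene_trees[[mk$name]] <- gt
  }

  structure(list(alignments = alignments, samples = samples,
                 species_tree = sptree,
                 introgressed = ids[flag],
                 gene_trees = gene_trees, config = cfg),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set: ", length(x$samples$individual_id), " individuals, ",
      length(unique(x$samples$species)), " species, ",
      length(x$alignments), " marker(s); ",
      length(x$introgressed), " introgressed lineage(s)\n", sep = "")
  invisible(x)
}

#' Expected within-species nucleotide diversity
#'
#' Under the neutral coalescent without introgression the expected
#' pairwise intraspecific diversity per site is `theta_w` scaled by the
#' marker's relative rate. Used for parameter-recovery checks.
#'
#' @param cfg A [sim_config()] with `introgression_prob = 0`.
#' @return Named numeric vector, one expectation per marker.
#' @export
expected_pi <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$introgression_prob > 0)
    stop("unsupported: expected_pi is defined for introgression_prob = 0")
  setNames(cfg$theta_w * cfg$markers$rate, cfg$markers$name)
}

#' Write a truth set to disk
#'
#' Writes one FASTA per marker, the metadata TSV, the true species tree
#' (Newick) and a JSON echo of the realized parameters.
#'
#' @param truth A `truth_set`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_truth_set <- function(truth, outdir) {
  stopifnot(inherits(truth, "truth_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(truth$alignments)) {
    f <- file.path(outdir, paste0(nm, ".fasta"))
    write_alignment(truth$alignments[[nm]], f)
    files <- c(files, f)
  }
  meta <- file.path(outdir, "samples.tsv")
  write.table(truth$samples, meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tre <- file.path(outdir, "species_tree.nwk")
  write_newick(truth$species_tree, tre)
  cfgf <- file.path(outdir, "config.json")
  cfg <- truth$config
  jsonlite::write_json(
    list(n_species = cfg$n_species,
         individuals_per_species = cfg$individuals_per_species,
         height = cfg$height, topology = cfg$topology,
         theta_w = cfg$theta_w,
         introgression_prob = cfg$introgression_prob,
         markers = cfg$markers, indel_rate = cfg$indel_rate,
         indel_length_p = cfg$indel_length_p, seed = cfg$seed,
         introgressed = truth$introgressed),
    cfgf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta, tre, cfgf))
}
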