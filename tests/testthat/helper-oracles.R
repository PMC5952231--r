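# Fixture generators and independent brute-force oracles. The oracles
# deliberately use naive per-site / per-pair loops, independent of the
# package's vectorised implementations.

rand_aln <- function(n, L, p_gap = 0.1, p_n = 0.05, ids = NULL) {
  m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L, replace = TRUE,
                     prob = c(rep((1 - p_gap - p_n) / 4, 4), p_gap, p_n)),
              nrow = n)
  rownames(m) <- if (is.null(ids)) sprintf("i%02d", seq_len(n)) else ids
  marker_alignment(m, "rnd")
}

rand_tab <- function(ids, n_species) {
  data.frame(
    individual_id = ids,
    species = sample(sprintf("sp%d", seq_len(n_species)), length(ids),
                     replace = TRUE),
    section = "A", region = "r1",
    stringsAsFactors = FALSE
  )
}

# per-site loop oracle for the p-distance (pairwise deletion)
oracle_p <- function(a, b) {
  mism <- 0L; comp <- 0L
  for (k in seq_along(a)) {
    if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
      comp <- comp + 1L
      if (a[k] != b[k]) mism <- mism + 1L
    }
  }
  if (comp == 0L) NA_real_ else mism / comp
}

oracle_dmat <- function(aln) {
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    D[i, j] <- oracle_p(aln$seqs[i, ], aln$seqs[j, ])
  }
  D
}

# exhaustive pair classification oracle
oracle_split <- function(D, ids, species) {
  intra <- c(); inter <- c()
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- D[i, j]
    if (is.na(d)) next
    if (species[i] == species[j]) intra <- c(intra, d) else inter <- c(inter, d)
  }
  list(intra = intra, inter = inter)
}

# brute-force nearest-neighbour species success
oracle_tophit_species <- function(D, ids, species) {
  n <- length(ids)
  hit <- character(n)
  for (i in seq_len(n)) {
    row <- D[i, -i]
    others <- species[-i]
    if (all(is.na(row))) { hit[i] <- "ne"; next }
    b <- min(row, na.rm = TRUE)
    cons <- others[!is.na(row) & row == b] == species[i]
    hit[i] <- if (all(cons)) "yes" else if (any(cons)) "amb" else "no"
  }
  sapply(sort(unique(species)), function(s) {
    idx <- species == s
    sum(idx) >= 2 && all(hit[idx] == "yes")
  })
}

# string-comparison haplotype oracle on retained columns
oracle_haplotypes <- function(seqs) {
  keep <- apply(seqs, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) return(rep(1L, nrow(seqs)))
  strs <- apply(seqs[, keep, drop = FALSE], 1, paste, collapse = "")
  match(strs, unique(strs))
}

# column-scan oracle for segregating sites on retained columns
oracle_segsites <- function(seqs) {
  keep <- apply(seqs, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  sum(apply(seqs[, keep, drop = FALSE], 2,
            function(col) length(unique(col)) >= 2))
}

# exhaustive pair-loop nucleotide diversity on retained columns
oracle_pi <- function(seqs) {
  keep <- apply(seqs, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  sub <- seqs[, keep, drop = FALSE]
  if (ncol(sub) == 0) return(NA_real_)
  n <- nrow(sub)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(sub[i, ] != sub[j, ]) / ncol(sub)
    np <- np + 1
  }
  tot / np
}

# clade sweep over every node: is `tips` exactly some node's descendants?
oracle_monophyletic <- function(tree, tips) {
  if (length(tips) == 1) return(TRUE)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (p in parts) {
    if (setequal(labs[p], tips)) return(TRUE)
  }
  FALSE
}

# exact rank-sum distribution by enumerating value assignments; U counted
# directly over pairs
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  U_of <- function(xx, yy) {
    u <- 0
    for (xi in xx) for (yj in yy) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  obs <- U_of(x, y)
  mu <- n1 * length(y) / 2
  idx <- utils::combn(n, n1)
  Us <- apply(idx, 2, function(ii) U_of(pooled[ii], pooled[-ii]))
  list(W = obs,
       p_two = mean(abs(Us - mu) >= abs(obs - mu) - 1e-9))
}

# planted partition: one-dimensional embedding, species centres far
# apart, individuals jittered around them
planted_matrix <- function(n_species = 20, n_ind = 5, spacing = 0.1,
                           jitter = 0.001) {
  pos <- c(); sp <- c(); ids <- c()
  for (s in seq_len(n_species)) {
    pos <- c(pos, s * spacing + runif(n_ind, -jitter, jitter))
    sp <- c(sp, rep(sprintf("sp%02d", s), n_ind))
    ids <- c(ids, sprintf("sp%02d_i%d", s, seq_len(n_ind)))
  }
  V <- abs(outer(pos, pos, "-"))
  diag(V) <- 0
  dimnames(V) <- list(ids, ids)
  list(dmat = as_pdist_matrix(V),
       tab = data.frame(individual_id = ids, species = sp, section = "A",
                        region = "r", stringsAsFactors = FALSE))
}

# gap-free matrix: evenly spaced points on a line, so successive sorted
# distances never exceed 1.5x the local mean spacing
gapfree_matrix <- function(n = 20, step = 0.003) {
  pos <- step * seq_len(n)
  V <- abs(outer(pos, pos, "-"))
  diag(V) <- 0
  dimnames(V) <- list(paste0("i", seq_len(n)), paste0("i", seq_len(n)))
  as_pdist_matrix(V)
}

# deep, introgression-free benchmark regime: the textbook barcode ideal
# (internodes of 1e5 coalescent units, species effectively fixed), so
# every method should resolve every species
easy_regime_config <- function(seed) {
  sim_config(n_species = 40, individuals_per_species = 5, height = 6e5,
             topology = "balanced", theta_w = 1e-6, introgression_prob = 0,
             indel_rate = 0, seed = seed)
}
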