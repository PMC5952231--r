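# Genetic diversity summaries: haplotypes, haplotype diversity (Hd),
# nucleotide diversity (Pi), segregating sites, indel events, grouped
# statistics and principal coordinates ordination.
#
# Site-exclusion policy: by default every column containing '-' or 'N'
# anywhere in the (group's) alignment is excluded before haplotype
# collapsing, Pi and segregating-site counting (complete deletion, the
# common default of population-genetics software); a pairwise-deletion
# mode is available for Pi. The policy in force is stamped into the
# grouped output.

.retained_columns <- function(seqs) {
  which(colSums(seqs == "-" | seqs == "N") == 0L)
}

#' Collapse sequences into haplotypes
#'
#' Two sequences share a haplotype iff they are identical at every
#' retained site (columns free of `-` and `N` across the alignment).
#' When every column is excluded the result is flagged degenerate and
#' all sequences form one haplotype.
#'
#' @param aln A [marker_alignment()].
#' @return Integer vector of haplotype indices named by id, with
#'   attributes `n_sites` (retained sites) and `degenerate`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  keep <- .retained_columns(aln$seqs)
  if (length(keep) == 0L) {
    warning("degenerate: all columns excluded; one haplotype assigned")
    out <- rep(1L, length(aln$ids))
    names(out) <- aln$ids
    return(structure(out, n_sites = 0L, degenerate = TRUE))
  }
  key <- apply(aln$seqs[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- as.integer(factor(key, levels = unique(key)))
  names(out) <- aln$ids
  structure(out, n_sites = length(keep), degenerate = FALSE)
}

#' Haplotype diversity
#'
#' `Hd = N/(N-1) * (1 - sum(f_i^2))` with `f_i` the haplotype
#' frequencies: the small-sample-corrected probability that two randomly
#' drawn sequences carry different haplotypes.
#'
#' @param assignment Haplotype assignment from [collapse_haplotypes()]
#'   (any integer/character grouping vector works).
#' @return `Hd` in `[0, 1]`; `NA` when fewer than two sequences.
#' @export
haplotype_diversity <- function(assignment) {
  n <- length(assignment)
  if (n < 2L) return(NA_real_)
  f <- as.numeric(table(assignment)) / n
  n / (n - 1) * (1 - sum(f^2))
}

#' Nucleotide diversity (Pi)
#'
#' Mean over all unordered sequence pairs of the per-site difference
#' proportion. Under the default complete-deletion policy all pairs are
#' compared over the same retained columns; under pairwise deletion each
#' pair uses its own comparable sites.
#'
#' @param aln A [marker_alignment()] with >= 2 sequences.
#' @param policy `"complete"` (default) or `"pairwise"`.
#' @return Pi per site; `NA` when no site is comparable.
#' @export
nucleotide_diversity <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  stopifnot(inherits(aln, "marker_alignment"))
  if (length(aln$ids) < 2L) return(NA_real_)
  dmat <- suppressMessages(distance_matrix(
    aln, deletion = if (policy == "complete") "complete" else "pairwise"))
  d <- dmat$values[upper.tri(dmat$values)]
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

#' Segregating (variable) sites
#'
#' `S` is the number of retained columns (complete deletion) holding at
#' least two distinct nucleotides; `S_pct` expresses it as a percentage
#' of the full aligned length.
#'
#' @param aln A [marker_alignment()].
#' @return List with `S` and `S_pct`.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  keep <- .retained_columns(aln$seqs)
  if (length(keep) == 0L) return(list(S = 0L, S_pct = 0))
  sub <- aln$seqs[, keep, drop = FALSE]
  S <- sum(apply(sub, 2, function(col) length(unique(col)) >= 2L))
  list(S = as.integer(S), S_pct = 100 * S / aln$length)
}

#' Count indel events
#'
#' An indel event is a maximal run of `-` within one row, identified by
#' its (start, end) interval; identical runs shared by several rows are
#' counted once.
#'
#' @param aln A [marker_alignment()].
#' @return Integer count of distinct gap runs.
#' @export
count_indel_events <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  runs <- character(0)
  for (i in seq_along(aln$ids)) {
    r <- rle(aln$seqs[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap <- which(r$values)
    if (length(gap))
      runs <- c(runs, paste(starts[gap], ends[gap], sep = "-"))
  }
  length(unique(runs))
}

#' Grouped diversity statistics
#'
#' Applies the diversity summaries per group (the whole dataset, per
#' species, or per taxonomic section), including the p-distance range
#' and mean from the group's own pairwise-deletion sub-matrix. Groups
#' with a single member have undefined diversity fields (reported `NA`)
#' and are flagged.
#'
#' @param aln A [marker_alignment()].
#' @param tab Sample table labelling every id.
#' @param group_by `"dataset"`, `"species"` or `"section"`.
#' @return `data.frame` with one row per group: `group`, `N`, `Ns`,
#'   `S`, `S_pct`, `Pi`, `Hn`, `Hd`, `indel_events`, `p_min`, `p_max`,
#'   `p_mean`, `singleton`, `site_policy`.
#' @export
group_stats <- function(aln, tab,
                        group_by = c("dataset", "species", "section")) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(aln, "marker_alignment"))
  lab <- switch(group_by,
                dataset = rep(aln$marker_name, length(aln$ids)),
                species = tab$species[match(aln$ids, tab$individual_id)],
                section = tab$section[match(aln$ids, tab$individual_id)])
  if (anyNA(lab))
    stop("validation error: unlabeled individual(s)")
  sp_all <- tab$species[match(aln$ids, tab$individual_id)]
  rows <- lapply(sort(unique(lab)), function(g) {
    idx <- which(lab == g)
    sub <- marker_alignment(aln$seqs[idx, , drop = FALSE], aln$marker_name)
    N <- length(idx)
    Ns <- length(unique(sp_all[idx]))
    if (N < 2L) {
      return(data.frame(group = g, N = N, Ns = Ns, S = NA_integer_,
                        S_pct = NA_real_, Pi = NA_real_, Hn = NA_integer_,
                        Hd = NA_real_, indel_events = NA_integer_,
                        p_min = NA_real_, p_max = NA_real_,
                        p_mean = NA_real_, singleton = TRUE,
                        site_policy = "complete",
                        stringsAsFactors = FALSE))
    }
    hap <- collapse_haplotypes(sub)
    ss <- segregating_sites(sub)
    dm <- suppressMessages(distance_matrix(sub, deletion = "pairwise"))
    d <- dm$values[upper.tri(dm$values)]
    d <- d[!is.na(d)]
    data.frame(group = g, N = N, Ns = Ns, S = ss$S, S_pct = ss$S_pct,
               Pi = nucleotide_diversity(sub),
               Hn = length(unique(hap)),
               Hd = haplotype_diversity(hap),
               indel_events = count_indel_events(sub),
               p_min = if (length(d)) min(d) else NA_real_,
               p_max = if (length(d)) max(d) else NA_real_,
               p_mean = if (length(d)) mean(d) else NA_real_,
               singleton = FALSE, site_policy = "complete",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a complete distance matrix: Gower
#' double-centering of the squared distances and eigendecomposition,
#' with coordinates scaled by the square root of each positive
#' eigenvalue. Explained fractions are computed over the positive
#' eigenvalues; the mass of negative eigenvalues (the non-Euclidean
#' part) is reported separately.
#'
#' @param dmat A `pdist_matrix` with no missing entries.
#' @param k Number of axes requested (default 2; capped at the number of
#'   positive eigenvalues).
#' @return List with `coordinates` (ids x axes), `eigenvalues` (all, in
#'   decreasing order), `explained` (fraction per returned axis) and
#'   `negative_fraction`.
#' @export
pcoa_ordination <- function(dmat, k = 2L) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  if (anyNA(dmat$values))
    stop("input error: missing entries; ordination needs a complete matrix")
  n <- length(dmat$ids)
  k <- min(k, n - 1L)
  fit <- suppressWarnings(stats::cmdscale(dmat$values, k = k, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-9
  pts <- fit$points
  keep <- seq_len(min(ncol(pts), sum(pos)))
  pts <- pts[, keep, drop = FALSE]
  colnames(pts) <- paste0("axis", keep)
  rownames(pts) <- dmat$ids
  list(coordinates = pts,
       eigenvalues = eig,
       explained = eig[keep] / sum(eig[pos]),
       negative_fraction = sum(abs(eig[eig < 0])) / sum(abs(eig)))
}
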