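# Intra/interspecific divergence summaries and the barcoding-gap test.
#
# Two intraspecific depth summaries are kept apart deliberately: theta,
# the mean intraspecific p-distance of one species (its average over
# species removes unequal-sampling bias), and the coalescent depth, the
# maximum intraspecific p-distance of one species. A barcoding gap is
# present only when the smallest interspecific distance strictly exceeds
# the largest intraspecific distance.

#' Per-species divergence summary
#'
#' For every species: number of individuals, theta (mean intraspecific
#' p-distance), coalescent depth (maximum intraspecific p-distance) and
#' the smallest interspecific distance involving the species. Species
#' with a single individual get missing intraspecific fields and are
#' flagged as singletons.
#'
#' @param dmat A `pdist_matrix`.
#' @param tab Sample table labelling every id.
#' @return `data.frame` with columns `species`, `n_individuals`,
#'   `n_intra_pairs`, `theta`, `coalescent_depth`,
#'   `nearest_nonconspecific`, `singleton`.
#' @export
species_summary <- function(dmat, tab) {
  sp <- tab$species[match(dmat$ids, tab$individual_id)]
  if (anyNA(sp))
    stop("validation error: unlabeled individual(s): ",
         paste(dmat$ids[is.na(sp)], collapse = ", "))
  species <- sort(unique(sp))
  V <- dmat$values
  rows <- lapply(species, function(s) {
    idx <- which(sp == s)
    n <- length(idx)
    if (n >= 2L) {
      sub <- V[idx, idx, drop = FALSE]
      d <- sub[upper.tri(sub)]
      d <- d[!is.na(d)]
      theta <- if (length(d)) mean(d) else NA_real_
      depth <- if (length(d)) max(d) else NA_real_
      npairs <- length(d)
    } else {
      theta <- depth <- NA_real_
      npairs <- 0L
    }
    if (length(idx) < length(sp)) {
      het <- V[idx, -idx, drop = FALSE]
      nn <- suppressWarnings(min(het, na.rm = TRUE))
      if (!is.finite(nn)) nn <- NA_real_
    } else nn <- NA_real_
    data.frame(species = s, n_individuals = n, n_intra_pairs = npairs,
               theta = theta, coalescent_depth = depth,
               nearest_nonconspecific = nn, singleton = n < 2L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Barcoding-gap assessment
#'
#' Dataset-level comparison of the intraspecific and interspecific
#' p-distance multisets: means, extremes, a gap flag (smallest
#' interspecific strictly greater than largest intraspecific), the
#' rank-sum test, and paired histograms over shared bin edges spanning
#' `[0, max observed]`.
#'
#' @param intra,inter Nonempty numeric vectors of intraspecific and
#'   interspecific p-distances.
#' @param bins Number of shared histogram bins (default 20).
#' @return List with `mean_intra`, `max_intra`, `mean_inter`,
#'   `min_inter`, `gap_present`, `rank_sum` (see [rank_sum_test()]) and
#'   `histogram` (`data.frame` of bin edges and the two counts).
#' @export
gap_assessment <- function(intra, inter, bins = 20L) {
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (!length(intra) || !length(inter))
    stop("insufficient-data error: both multisets must be nonempty")
  top <- max(intra, inter)
  if (top <= 0) top <- 1e-6
  edges <- seq(0, top, length.out = bins + 1L)
  h_intra <- graphics::hist(intra, breaks = edges, plot = FALSE,
                            include.lowest = TRUE, right = TRUE)$counts
  h_inter <- graphics::hist(inter, breaks = edges, plot = FALSE,
                            include.lowest = TRUE, right = TRUE)$counts
  list(
    mean_intra = mean(intra), max_intra = max(intra),
    mean_inter = mean(inter), min_inter = min(inter),
    gap_present = min(inter) > max(intra),
    rank_sum = rank_sum_test(intra, inter),
    histogram = data.frame(lower = edges[-length(edges)], upper = edges[-1],
                           intra = h_intra, inter = h_inter)
  )
}

#' Two-sample rank-sum test
#'
#' Mann-Whitney form in first-sample orientation: `W` is the number of
#' pairs `(x_i, y_j)` with `x_i > y_j` plus half the ties. For small
#' samples (total size at most `exact_limit`) the p-values are computed
#' by exact enumeration of the conditional rank assignments, which is
#' also correct under ties; larger samples use the normal approximation
#' with tie correction and continuity correction. When every value in
#' both samples is identical the test is degenerate: `W = |x||y|/2`,
#' `p = 1`.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact_limit Largest total sample size for which exact
#'   enumeration is used (default 16).
#' @return List with `W`, `p_value` (two-sided), `p_greater` (one-sided,
#'   x tending larger), `method` (`"exact"`, `"normal"` or
#'   `"degenerate"`) and `degenerate` flag.
#' @export
rank_sum_test <- function(x, y, exact_limit = 16L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("input error: both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1L)
    return(list(W = mu, p_value = 1, p_greater = 1,
                method = "degenerate", degenerate = TRUE))
  n <- n1 + n2
  if (n <= exact_limit) {
    subsets <- combn(n, n1)
    Ws <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_two <- mean(abs(Ws - mu) >= abs(W - mu) - eps)
    p_gr <- mean(Ws >= W - eps)
    return(list(W = W, p_value = p_two, p_greater = p_gr,
                method = "exact", degenerate = FALSE))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z_two <- (W - mu - sign(W - mu) * 0.5) / sigma
  p_two <- min(1, 2 * stats::pnorm(-abs(z_two)))
  p_gr <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  list(W = W, p_value = p_two, p_greater = p_gr,
       method = "normal", degenerate = FALSE)
}

#' Full gap report for one dataset
#'
#' Combines the per-species summaries and the dataset-level gap
#' assessment. The pooled mean intraspecific distance (over all
#' intraspecific pairs) and the unweighted mean of per-species thetas
#' are both reported; they differ under unequal sampling. Singleton
#' species are excluded from the mean-theta and mean-coalescent-depth
#' denominators.
#'
#' @param dmat A `pdist_matrix`.
#' @param tab Sample table.
#' @param bins Histogram bin count, see [gap_assessment()].
#' @return List with `species` (per-species `data.frame`), `dataset`
#'   (dataset-level list incl. `mean_theta`, `mean_coalescent_depth`)
#'   and `histogram`.
#' @export
gap_report <- function(dmat, tab, bins = 20L) {
  per_sp <- species_summary(dmat, tab)
  sets <- split_intra_inter(dmat, tab)
  ga <- gap_assessment(sets$intra, sets$inter, bins = bins)
  eval_sp <- per_sp[!per_sp$singleton & per_sp$n_intra_pairs > 0L, ]
  dataset <- list(
    n_individuals = length(dmat$ids),
    n_species = nrow(per_sp),
    mean_intra = ga$mean_intra,
    mean_theta = if (nrow(eval_sp)) mean(eval_sp$theta) else NA_real_,
    mean_coalescent_depth =
      if (nrow(eval_sp)) mean(eval_sp$coalescent_depth) else NA_real_,
    max_intra = ga$max_intra,
    mean_inter = ga$mean_inter,
    min_inter = ga$min_inter,
    gap_present = ga$gap_present,
    W = ga$rank_sum$W,
    p_value = ga$rank_sum$p_value
  )
  list(species = per_sp, dataset = dataset, histogram = ga$histogram)
}
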