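# Distance-based species delimitation by automatic barcode-gap
# detection with recursive single-linkage partitioning, scanned over a
# geometric series of prior maximum intraspecific divergences.
#
# The gap detector is a documented simplification of the automatic
# barcode-gap discovery heuristic: the sorted distinct distances are
# scanned for the first spacing that is more than `x` times the mean
# spacing over a preceding rank window; the prior P demands that the
# partition threshold (the gap's upper side) exceeds P.

#' Configuration for barcode-gap delimitation
#'
#' Defaults mirror the web defaults of the automatic barcode-gap
#' discovery tool: priors from 0.001 to 0.1 in a 10-step geometric
#' series and relative gap width 1.5.
#'
#' @param p_min,p_max Smallest and largest prior maximum intraspecific
#'   divergence (proportions, `0 < p_min < p_max < 1`).
#' @param steps Number of priors in the geometric series (>= 2).
#' @param x Relative gap width: a spacing counts as a barcode gap when it
#'   exceeds `x` times the local mean spacing.
#' @param window Rank window for the local mean-spacing scale; default
#'   `max(10, ceiling(n_pairs / 20))` where `n_pairs` is the length of
#'   the (tied) distance list.
#' @return An `abgd_config` object.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 10L, x = 1.5,
                        window = NULL) {
  if (!(p_min > 0 && p_min < p_max && p_max < 1))
    stop("input error: need 0 < p_min < p_max < 1")
  if (steps < 2L) stop("input error: steps must be >= 2")
  if (x <= 0) stop("input error: x must be positive")
  structure(list(p_min = p_min, p_max = p_max, steps = as.integer(steps),
                 x = x, window = window),
            class = "abgd_config")
}

#' Detect a barcode gap in a sorted distance list
#'
#' Ties are collapsed to distinct values before scanning. Spacings whose
#' upper endpoint does not exceed the prior `P` are skipped. The first
#' spacing larger than `x` times the local mean spacing is returned as a
#' threshold at its midpoint; the local scale is the mean of the
#' preceding (up to `window`) spacings, except for the very first
#' spacing, which is judged against the following window instead (the
#' case where every comparison below the gap is identical, e.g. fully
#' monomorphic species).
#'
#' @param sorted_distances Ascending numeric vector (length >= 2).
#' @param P Prior maximum intraspecific divergence.
#' @param cfg An [abgd_config()].
#' @return Threshold (midpoint of the first significant gap) or `NULL`
#'   when no significant gap exists.
#' @export
detect_gap <- function(sorted_distances, P, cfg = abgd_config()) {
  d <- sorted_distances[!is.na(sorted_distances)]
  if (length(d) < 2L) return(NULL)
  if (is.unsorted(d)) stop("input error: distances must be ascending")
  v <- unique(d)
  if (length(v) < 2L) return(NULL)
  g <- diff(v)
  w <- cfg$window
  if (is.null(w)) w <- max(10L, ceiling(length(d) / 20))
  for (j in seq_along(g)) {
    if (v[j + 1L] <= P) next
    if (j == 1L) {
      if (length(g) < 2L) next
      hi <- min(length(g), 1L + w)
      m <- mean(g[2L:hi])
    } else {
      lo <- max(1L, j - w)
      m <- mean(g[lo:(j - 1L)])
    }
    if (g[j] > cfg$x * m) return((v[j] + v[j + 1L]) / 2)
  }
  NULL
}

# connected components of a logical adjacency matrix (single linkage)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

.abgd_recurse <- function(V, ids, P, cfg) {
  n <- length(ids)
  if (n < 2L) return(list(ids))
  ut <- upper.tri(V)
  d <- V[ut]
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    warning("sub-matrix with no defined distances; ids kept as singletons")
    return(as.list(ids))
  }
  th <- detect_gap(sort(d), P, cfg)
  if (is.null(th)) return(list(ids))
  adj <- !is.na(V) & V < th
  diag(adj) <- TRUE
  comp <- .components(adj)
  if (max(comp) == 1L) return(list(ids))
  out <- list()
  for (k in sort(unique(comp))) {
    idx <- which(comp == k)
    if (length(idx) == 1L) {
      out <- c(out, list(ids[idx]))
    } else {
      out <- c(out, .abgd_recurse(V[idx, idx, drop = FALSE], ids[idx], P, cfg))
    }
  }
  out
}

#' Partition individuals at one prior
#'
#' If a significant gap is found, individuals are grouped by
#' single-linkage connectivity at distances strictly below the
#' threshold; the search is then repeated inside each group on its
#' sub-matrix until no further significant gap is found. When no gap is
#' detected at the top level all individuals form one group. Missing
#' distances are treated as non-edges.
#'
#' @param dmat A `pdist_matrix`.
#' @param P Prior maximum intraspecific divergence.
#' @param cfg An [abgd_config()].
#' @return A `partition` object: list with `groups` (list of id
#'   vectors), `prior` and `threshold` (top-level threshold or `NA`).
#' @export
abgd_partition <- function(dmat, P, cfg = abgd_config()) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  V <- dmat$values
  d <- V[upper.tri(V)]
  d <- d[!is.na(d)]
  th <- if (length(d)) detect_gap(sort(d), P, cfg) else NULL
  groups <- .abgd_recurse(V, dmat$ids, P, cfg)
  structure(list(groups = groups, prior = P,
                 threshold = if (is.null(th)) NA_real_ else th),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition: ", length(x$groups), " group(s) at prior P = ",
      format(x$prior), "\n", sep = "")
  invisible(x)
}

# order-free canonical encoding of a partition's groups
.partition_key <- function(part) {
  paste(sort(vapply(part$groups,
                    function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}

#' Scan the prior series and select the modal partition
#'
#' Runs [abgd_partition()] at each prior of the geometric series and
#' selects the grouping that recurs most often across priors; ties are
#' broken toward the grouping observed at the larger prior.
#'
#' @param dmat A `pdist_matrix`.
#' @param cfg An [abgd_config()].
#' @return List with `priors`, `partitions` (one per prior) and
#'   `selected` (the modal `partition`).
#' @export
abgd_scan <- function(dmat, cfg = abgd_config()) {
  priors <- exp(seq(log(cfg$p_min), log(cfg$p_max), length.out = cfg$steps))
  partitions <- lapply(priors, function(P) abgd_partition(dmat, P, cfg))
  keys <- vapply(partitions, .partition_key, character(1))
  counts <- table(keys)
  top <- names(counts)[counts == max(counts)]
  # among tied modal groupings take the one whose largest prior is largest
  best_key <- top[which.max(vapply(top, function(k) max(which(keys == k)), 0))]
  selected <- partitions[[max(which(keys == best_key))]]
  structure(list(priors = priors, partitions = partitions,
                 selected = selected),
            class = "abgd_scan")
}

#' Score a partition against the species labels
#'
#' A species is successfully delimited only when all its individuals lie
#' in a single group and that group contains no individuals of any other
#' species.
#'
#' @param part A `partition`.
#' @param tab Sample table labelling every partitioned id.
#' @return List with `species` (`data.frame` of per-species success) and
#'   `rate` (percent of species delimited).
#' @export
score_delimitation <- function(part, tab) {
  stopifnot(inherits(part, "partition"))
  ids <- unlist(part$groups)
  grp <- rep(seq_along(part$groups), lengths(part$groups))
  sp <- tab$species[match(ids, tab$individual_id)]
  if (anyNA(sp))
    stop("validation error: unlabeled individual(s): ",
         paste(ids[is.na(sp)], collapse = ", "))
  species <- sort(unique(sp))
  grp_size <- lengths(part$groups)
  success <- vapply(species, function(s) {
    gs <- unique(grp[sp == s])
    length(gs) == 1L && grp_size[gs] == sum(sp == s)
  }, logical(1))
  list(species = data.frame(species = species, success = success,
                            stringsAsFactors = FALSE),
       rate = 100 * mean(success))
}

#' Write a partition as TSV
#'
#' Columns: `individual_id`, `group_id`, `prior_P`.
#'
#' @param part A `partition`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_partition_tsv <- function(part, path) {
  df <- data.frame(
    individual_id = unlist(part$groups),
    group_id = rep(seq_along(part$groups), lengths(part$groups)),
    prior_P = part$prior
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
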