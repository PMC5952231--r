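# Pairwise p-distances over aligned sequences.
#
# A p-distance is the proportion of differing sites among the sites
# comparable between two rows; sites with '-' or 'N' in either row are
# not comparable under pairwise deletion. p-distances are not metric:
# nothing downstream may rely on the triangle inequality.

#' p-distance between two aligned rows
#'
#' @param a,b Character vectors of equal length over `A,C,G,T,N,-`, or
#'   single sequence strings.
#' @param deletion `"pairwise"` (default) excludes, per pair, sites where
#'   either row carries `-` or `N`; `"complete"` first drops every column
#'   containing `-` or `N` in either row (for a single pair the two modes
#'   coincide).
#' @return List with `distance` (proportion in `[0,1]`, `NA` when no
#'   comparable site remains) and `sites` (number of comparable sites).
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b))
    stop("input error: rows must have equal aligned length")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) return(list(distance = NA_real_, sites = 0L))
  list(distance = sum(a[ok] != b[ok]) / n, sites = n)
}

#' Pairwise p-distance matrix
#'
#' Computes all pairwise p-distances of an alignment. Pairs with no
#' comparable sites are recorded as missing (`NA`), never as zero, and a
#' message reports their count.
#'
#' @param aln A [marker_alignment()] with at least two individuals.
#' @param deletion `"pairwise"` (default) or `"complete"` (drop every
#'   column containing `-` or `N` anywhere in the alignment before
#'   computing distances).
#' @return An object of class `pdist_matrix`: list with `ids`, `values`
#'   (symmetric matrix of proportions, zero diagonal), `sites` (symmetric
#'   matrix of comparable-site counts) and `deletion`.
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "marker_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("input error: need >= 2 individuals")
  seqs <- aln$seqs
  if (deletion == "complete") {
    keep <- colSums(seqs == "-" | seqs == "N") == 0L
    seqs <- seqs[, keep, drop = FALSE]
  }
  enc <- match(seqs, c("A", "C", "G", "T"))
  enc <- matrix(enc, nrow = n)
  B <- matrix(as.numeric(!is.na(enc)), nrow = n)
  V <- tcrossprod(B)                      # comparable sites per pair
  M <- matrix(0, n, n)
  for (s in 1:4) {
    X <- matrix(as.numeric(!is.na(enc) & enc == s), nrow = n)
    M <- M + tcrossprod(X)                # matching sites per pair
  }
  D <- (V - M) / V
  D[V == 0] <- NA_real_
  diag(D) <- 0
  storage.mode(V) <- "integer"
  dimnames(D) <- dimnames(V) <- list(aln$ids, aln$ids)
  n_missing <- sum(is.na(D[upper.tri(D)]))
  if (n_missing > 0L)
    message(n_missing, " pair(s) with no comparable sites recorded as missing")
  structure(list(ids = aln$ids, values = D, sites = V, deletion = deletion),
            class = "pdist_matrix")
}

#' @export
print.pdist_matrix <- function(x, ...) {
  cat("pdist_matrix: ", length(x$ids), " individuals (",
      x$deletion, " deletion), ",
      sum(is.na(x$values[upper.tri(x$values)])), " undefined pair(s)\n",
      sep = "")
  invisible(x)
}

#' Subset a distance matrix by individual ids
#'
#' @param dmat A `pdist_matrix`.
#' @param ids Ids to keep, in the order given.
#' @return A `pdist_matrix` over `ids`.
#' @export
subset_distance_matrix <- function(dmat, ids) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  miss <- setdiff(ids, dmat$ids)
  if (length(miss)) stop("input error: unknown id(s): ",
                         paste(miss, collapse = ", "))
  structure(list(ids = ids,
                 values = dmat$values[ids, ids, drop = FALSE],
                 sites = dmat$sites[ids, ids, drop = FALSE],
                 deletion = dmat$deletion),
            class = "pdist_matrix")
}

#' Split pairwise distances into intra- and interspecific multisets
#'
#' Each unordered pair of distinct individuals contributes to exactly one
#' multiset according to whether the two individuals are conspecific.
#' Missing distances are excluded.
#'
#' @param dmat A `pdist_matrix`.
#' @param tab Sample table labelling every id in `dmat`.
#' @return List with numeric vectors `intra` and `inter`.
#' @export
split_intra_inter <- function(dmat, tab) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  sp <- tab$species[match(dmat$ids, tab$individual_id)]
  if (anyNA(sp))
    stop("validation error: unlabeled individual(s): ",
         paste(dmat$ids[is.na(sp)], collapse = ", "))
  ut <- upper.tri(dmat$values)
  same <- outer(sp, sp, "==")
  vals <- dmat$values[ut]
  same <- same[ut]
  keep <- !is.na(vals)
  list(intra = vals[keep & same], inter = vals[keep & !same])
}

#' Write / read a distance matrix as square TSV
#'
#' The first row and column carry the individual ids.
#'
#' @param dmat A `pdist_matrix`.
#' @param path Output (input) file path.
#' @return `write_distance_tsv` invisibly returns `path`;
#'   `read_distance_tsv` returns a `pdist_matrix` (site counts unknown,
#'   recorded as `NA`).
#' @export
write_distance_tsv <- function(dmat, path) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  df <- data.frame(individual_id = dmat$ids, dmat$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  sites <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  structure(list(ids = ids, values = m, sites = sites,
                 deletion = "unknown"),
            class = "pdist_matrix")
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dmat A `pdist_matrix`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(dmat, path) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(length(dmat$ids)), con)
  for (i in seq_along(dmat$ids)) {
    writeLines(paste(formatC(dmat$ids[i], width = -10),
                     paste(sprintf("%.6f", dmat$values[i, ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Build a pdist_matrix from a plain numeric matrix
#'
#' Convenience constructor used for planted-partition experiments and
#' external matrices: values must be symmetric with zero diagonal.
#'
#' @param values Symmetric numeric matrix with row/col names.
#' @param sites Optional matrix of comparable-site counts.
#' @return A `pdist_matrix`.
#' @export
as_pdist_matrix <- function(values, sites = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("i", seq_len(nrow(values)))
  ids <- rownames(values)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12)))
    stop("input error: matrix must be symmetric")
  if (any(diag(values) != 0)) stop("input error: diagonal must be zero")
  if (is.null(sites))
    sites <- matrix(NA_integer_, nrow(values), ncol(values),
                    dimnames = dimnames(values))
  structure(list(ids = ids, values = values, sites = sites,
                 deletion = "external"),
            class = "pdist_matrix")
}
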