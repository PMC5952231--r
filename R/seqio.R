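#' @importFrom stats rexp rpois rgeom runif rbinom setNames na.omit
#' @importFrom utils combn read.delim write.table
NULL

# Alphabet for aligned marker sequences. '-' is the only gap symbol;
# IUPAC ambiguity codes are collapsed to N on input.
ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a marker alignment
#'
#' A `marker_alignment` holds equal-length aligned sequences for one
#' barcoding marker (or a concatenation of markers), keyed by individual
#' identifier. Sequences are rows of a character matrix over the alphabet
#' `A, C, G, T, N, -`.
#'
#' @param seqs Character matrix (individuals x sites) of single upper-case
#'   characters, with unique row names giving the individual identifiers,
#'   or a named list/character vector of equal-length sequence strings.
#' @param marker_name Name of the marker.
#' @return An object of class `marker_alignment` with fields
#'   `marker_name`, `ids`, `seqs` (character matrix) and `length`.
#' @export
marker_alignment <- function(seqs, marker_name) {
  if (is.list(seqs) || (is.character(seqs) && !is.matrix(seqs))) {
    seqs <- as.list(seqs)
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("input error: sequences must be named by individual id")
    chars <- lapply(seqs, function(s) {
      if (length(s) == 1L) strsplit(s, "")[[1]] else as.character(s)
    })
    lens <- lengths(chars)
    if (length(unique(lens)) != 1L)
      stop("alignment error: records have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    seqs <- matrix(toupper(unlist(chars)), nrow = length(chars), byrow = TRUE,
                   dimnames = list(names(chars), NULL))
  }
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("input error: 'seqs' must be a character matrix")
  if (ncol(seqs) < 1L) stop("alignment error: aligned length must be >= 1")
  ids <- rownames(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("input error: individual ids must be present and unique")
  seqs[] <- toupper(seqs)
  amb <- seqs %in% IUPAC_AMBIGUITY
  if (any(amb)) {
    warning(sum(amb), " IUPAC ambiguity character(s) mapped to N")
    seqs[amb] <- "N"
  }
  bad <- !(seqs %in% ALN_ALPHABET)
  if (any(bad))
    stop("alphabet error: illegal character(s) ",
         paste(unique(seqs[bad]), collapse = " "),
         " (allowed: A C G T N -)")
  structure(
    list(marker_name = marker_name, ids = ids, seqs = seqs,
         length = ncol(seqs)),
    class = "marker_alignment"
  )
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("marker_alignment '", x$marker_name, "': ", length(x$ids),
      " sequences, ", x$length, " aligned sites\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a sequential or wrapped FASTA file holding one marker's multiple
#' sequence alignment. Lower-case input is normalised to upper case, IUPAC
#' ambiguity codes are mapped to `N` with a warning, and any character
#' outside `A, C, G, T, N, -` (including `.` and `~`) is rejected.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param marker_name Marker name to attach to the alignment.
#' @return A [marker_alignment()].
#' @export
read_alignment <- function(path, marker_name) {
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                       set.attributes = FALSE),
    error = function(e) stop("input error: cannot read FASTA '", path,
                             "': ", conditionMessage(e))
  )
  if (length(recs) == 0L) stop("input error: empty FASTA file '", path, "'")
  marker_alignment(lapply(recs, as.character), marker_name)
}

#' Write a marker alignment as FASTA
#'
#' @param aln A [marker_alignment()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "marker_alignment"))
  seqinr::write.fasta(
    sequences = lapply(seq_along(aln$ids), function(i) aln$seqs[i, ]),
    names = aln$ids, file.out = path, nbchar = 70
  )
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated table with header columns `individual_id`,
#' `species`, `section` and `region`. Extra columns are preserved but
#' ignored downstream.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per individual.
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  validate_sample_table(tab)
}

#' Validate a sample table
#'
#' @param tab Data frame with columns `individual_id`, `species`,
#'   `section`, `region`.
#' @return The validated data frame.
#' @export
validate_sample_table <- function(tab) {
  req <- c("individual_id", "species", "section", "region")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$individual_id))
    stop("input error: duplicated individual_id: ",
         paste(unique(tab$individual_id[duplicated(tab$individual_id)]),
               collapse = ", "))
  if (any(is.na(tab$species) | tab$species == ""))
    stop("input error: species must be nonempty for every individual")
  tab
}

#' Cross-check an alignment against the sample table
#'
#' Every aligned individual must have a metadata row.
#'
#' @param aln A [marker_alignment()].
#' @param tab A sample table (see [read_metadata()]).
#' @return Invisibly `TRUE`; errors if an id is unlabelled.
#' @export
check_alignment_metadata <- function(aln, tab) {
  miss <- setdiff(aln$ids, tab$individual_id)
  if (length(miss))
    stop("validation error: aligned individual(s) absent from sample table: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Enumerate all marker combinations
#'
#' Returns every nonempty subset of the marker names, ordered by subset
#' size and then lexicographically, each as a combination specification.
#' Four markers give the 15 single and combined datasets evaluated by the
#' pipeline.
#'
#' @param markers Character vector of marker names (at least one).
#' @param missing_policy How concatenation handles individuals missing a
#'   marker: `"drop"` (default) or `"pad"` with N.
#' @return List of `combo_spec` objects.
#' @export
enumerate_combinations <- function(markers, missing_policy = c("drop", "pad")) {
  missing_policy <- match.arg(missing_policy)
  if (length(markers) < 1L) stop("input error: need at least one marker")
  if (anyDuplicated(markers)) stop("input error: marker names must be unique")
  srt <- sort(markers)
  out <- list()
  for (k in seq_along(srt)) {
    subs <- combn(srt, k, simplify = FALSE)
    out <- c(out, lapply(subs, combo_spec, missing_policy = missing_policy))
  }
  out
}

#' Combination specification
#'
#' @param markers Character vector of marker names forming the combination.
#' @param missing_policy `"drop"` or `"pad"`.
#' @return A `combo_spec` object.
#' @export
combo_spec <- function(markers, missing_policy = c("drop", "pad")) {
  missing_policy <- match.arg(missing_policy)
  if (length(markers) < 1L || anyDuplicated(markers))
    stop("input error: combination markers must be a nonempty unique set")
  structure(list(markers = markers, missing_policy = missing_policy),
            class = "combo_spec")
}

#' Concatenate marker alignments
#'
#' Builds the per-individual concatenation of the markers named in the
#' combination, in combination order. Under the `drop` policy individuals
#' missing any member marker are excluded (their count is reported via a
#' message); under `pad`, missing blocks are filled with runs of `N` of
#' that marker's aligned length.
#'
#' @param alignments Named list of [marker_alignment()] objects.
#' @param combo A [combo_spec()] whose markers are all present in
#'   `alignments`.
#' @return A [marker_alignment()] named by joining the member markers
#'   with `+`.
#' @export
concatenate_markers <- function(alignments, combo) {
  stopifnot(inherits(combo, "combo_spec"))
  miss <- setdiff(combo$markers, names(alignments))
  if (length(miss))
    stop("input error: marker(s) not loaded: ", paste(miss, collapse = ", "))
  alns <- alignments[combo$markers]
  all_ids <- unique(unlist(lapply(alns, `[[`, "ids")))
  present <- vapply(alns, function(a) all_ids %in% a$ids,
                    logical(length(all_ids)))
  present <- matrix(present, nrow = length(all_ids))
  if (combo$missing_policy == "drop") {
    keep <- all_ids[rowSums(present) == length(alns)]
    n_drop <- length(all_ids) - length(keep)
    if (n_drop > 0L)
      message(n_drop, " individual(s) dropped (missing >=1 marker)")
    if (length(keep) == 0L)
      stop("empty-result error: no individual has all markers in the combination")
    ids <- keep
  } else {
    ids <- all_ids
  }
  blocks <- lapply(alns, function(a) {
    block <- matrix("N", nrow = length(ids), ncol = a$length,
                    dimnames = list(ids, NULL))
    have <- intersect(ids, a$ids)
    block[have, ] <- a$seqs[have, , drop = FALSE]
    block
  })
  marker_alignment(do.call(cbind, blocks),
                  marker_name = paste(combo$markers, collapse = "+"))
}
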