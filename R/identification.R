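# Similarity-based (leave-one-out top-hit) and diagnostic-nucleotide
# (greedy logic-mining) species identification.
#
# The top-hit criterion emulates local-alignment database searches by
# leave-one-out nearest neighbour under the p-distance: sequences are
# pre-aligned, so alignment-score machinery adds nothing. A species is
# discriminated only when every one of its individuals has all tied
# best matches conspecific.

#' Leave-one-out top-hit identification
#'
#' For each query individual the reference set is every other
#' individual; the best-match set is the argmin of the p-distance. The
#' hit is `"yes"` when all tied best matches are conspecific,
#' `"ambiguous"` when the tie mixes conspecific and heterospecific
#' references, `"no"` otherwise. A species succeeds only when every one
#' of its individuals scores `"yes"`. Singleton species cannot have a
#' conspecific hit and are excluded from the denominator by default.
#'
#' @param dmat A `pdist_matrix` over at least two individuals.
#' @param tab Sample table labelling every id.
#' @param include_singletons Count singleton species as failures instead
#'   of excluding them (default `FALSE`).
#' @return List with `individuals` (per-query `data.frame`), `species`
#'   (per-species `data.frame` with `evaluable` and `success`), `rate`
#'   (percent of evaluable species discriminated) and
#'   `n_evaluated`/`n_excluded`.
#' @export
tophit_identify <- function(dmat, tab, include_singletons = FALSE) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  n <- length(dmat$ids)
  if (n < 2L) stop("input error: need >= 2 individuals")
  sp <- tab$species[match(dmat$ids, tab$individual_id)]
  if (anyNA(sp))
    stop("validation error: unlabeled individual(s): ",
         paste(dmat$ids[is.na(sp)], collapse = ", "))
  V <- dmat$values
  diag(V) <- NA_real_
  hit <- character(n)
  best <- numeric(n)
  best_ids <- character(n)
  for (i in seq_len(n)) {
    row <- V[i, ]
    if (all(is.na(row))) {
      hit[i] <- "not-evaluable"; best[i] <- NA_real_; best_ids[i] <- ""
      next
    }
    b <- min(row, na.rm = TRUE)
    ties <- which(!is.na(row) & row == b)
    consp <- sp[ties] == sp[i]
    hit[i] <- if (all(consp)) "yes" else if (any(consp)) "ambiguous" else "no"
    best[i] <- b
    best_ids[i] <- paste(dmat$ids[ties], collapse = ",")
  }
  individuals <- data.frame(individual_id = dmat$ids, species = sp,
                            best_distance = best, best_matches = best_ids,
                            conspecific_hit = hit, stringsAsFactors = FALSE)
  species <- sort(unique(sp))
  n_ind <- vapply(species, function(s) sum(sp == s), 0L)
  evaluable <- n_ind >= 2L &
    vapply(species, function(s) !any(hit[sp == s] == "not-evaluable"),
           logical(1))
  success <- vapply(species, function(s) all(hit[sp == s] == "yes"),
                    logical(1)) & evaluable
  sp_df <- data.frame(species = species, n_individuals = n_ind,
                      evaluable = evaluable, success = success,
                      stringsAsFactors = FALSE)
  denom <- if (include_singletons) rep(TRUE, length(species)) else evaluable
  rate <- if (any(denom)) 100 * sum(success[denom]) / sum(denom) else NA_real_
  list(individuals = individuals, species = sp_df, rate = rate,
       n_evaluated = sum(denom), n_excluded = sum(!denom))
}

#' Stratified train/test split
#'
#' Splits individuals by species: species with at least two individuals
#' contribute at least one individual to each side; singleton species go
#' entirely to the training side and are flagged not evaluable. The
#' split is deterministic given the seed.
#'
#' @param tab Sample table.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed controlling the split.
#' @return List with `train` and `test` id vectors and `not_evaluable`
#'   (species placed wholly in training).
#' @export
split_train_test <- function(tab, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("input error: train_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  train <- character(0); test <- character(0); flagged <- character(0)
  for (s in sort(unique(tab$species))) {
    ids <- sort(tab$individual_id[tab$species == s])
    n <- length(ids)
    if (n < 2L) {
      train <- c(train, ids)
      flagged <- c(flagged, s)
      next
    }
    n_tr <- min(n - 1L, max(1L, round(train_fraction * n)))
    tr <- sample(ids, n_tr)
    train <- c(train, tr)
    test <- c(test, setdiff(ids, tr))
  }
  list(train = train, test = test, not_evaluable = flagged)
}

#' Mine diagnostic-nucleotide rules
#'
#' For each species a conjunction of (position, nucleotide) literals is
#' grown greedily: starting from the positions where all conspecific
#' training sequences share one of A, C, G or T (gap and N states are
#' never used), the literal excluding the most remaining heterospecific
#' training sequences is added (ties broken toward the leftmost
#' position) until no heterospecific sequence matches (a perfect rule),
#' `L_max` literals are reached, or no literal improves. A
#' heterospecific sequence is excluded by a literal whenever its state
#' at that position differs from the required nucleotide.
#'
#' @param train_aln [marker_alignment()] holding the training sequences.
#' @param tab Sample table labelling the training ids.
#' @param L_max Maximum literals per rule (default 5).
#' @return A `rule_set`: list of per-species rules, each with
#'   `species`, `literals` (`data.frame` of `position`, `state`),
#'   `perfect`, `n_train` and `n_excluded`.
#' @export
mine_rules <- function(train_aln, tab, L_max = 5L) {
  stopifnot(inherits(train_aln, "marker_alignment"))
  M <- train_aln$seqs
  sp <- tab$species[match(train_aln$ids, tab$individual_id)]
  if (anyNA(sp))
    stop("validation error: unlabeled individual(s): ",
         paste(train_aln$ids[is.na(sp)], collapse = ", "))
  L <- ncol(M)
  rules <- lapply(sort(unique(sp)), function(s) {
    own <- M[sp == s, , drop = FALSE]
    het <- M[sp != s, , drop = FALSE]
    ref <- own[1L, ]
    fixed <- ref %in% c("A", "C", "G", "T")
    if (nrow(own) > 1L)
      fixed <- fixed & colSums(own != matrix(ref, nrow(own), L,
                                             byrow = TRUE)) == 0L
    cand <- which(fixed)
    lits <- integer(0)
    remaining <- rep(TRUE, nrow(het))
    while (length(lits) < L_max && any(remaining) && length(cand)) {
      sub <- het[remaining, cand, drop = FALSE]
      gains <- colSums(sub != matrix(ref[cand], nrow(sub), length(cand),
                                     byrow = TRUE))
      if (max(gains) == 0L) break
      pick <- cand[which.max(gains)]     # cand ascending -> leftmost tie-break
      lits <- c(lits, pick)
      remaining <- remaining & (het[, pick] == ref[pick])
      cand <- setdiff(cand, pick)
    }
    list(species = s,
         literals = data.frame(position = lits, state = ref[lits],
                               stringsAsFactors = FALSE),
         perfect = !any(remaining) && length(lits) > 0L || nrow(het) == 0L,
         n_train = nrow(own),
         n_excluded = sum(!remaining))
  })
  structure(list(rules = rules, alignment_length = L), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  for (r in x$rules) {
    lit <- if (nrow(r$literals))
      paste(sprintf("pos%d=%s", r$literals$position, r$literals$state),
            collapse = " AND ")
    else "<empty>"
    cat(r$species, " := ", lit,
        if (r$perfect) "  [perfect]" else "  [imperfect]", "\n", sep = "")
  }
  invisible(x)
}

#' Classify aligned sequences with a rule set
#'
#' A sequence is assigned to the unique species whose perfect rule it
#' matches (equal to the required nucleotide at every literal position);
#' zero or multiple matches yield `"unknown"`.
#'
#' @param rules A `rule_set` from [mine_rules()].
#' @param seqs A [marker_alignment()], character matrix, or single
#'   aligned row whose length equals the training alignment length.
#' @return Character vector of species assignments (named by id when
#'   available).
#' @export
classify_sequences <- function(rules, seqs) {
  stopifnot(inherits(rules, "rule_set"))
  if (inherits(seqs, "marker_alignment")) seqs <- seqs$seqs
  if (!is.matrix(seqs)) seqs <- matrix(seqs, nrow = 1)
  if (ncol(seqs) != rules$alignment_length)
    stop("input error: sequence length ", ncol(seqs),
         " does not match training alignment length ",
         rules$alignment_length)
  perfect <- Filter(function(r) r$perfect && nrow(r$literals) > 0L,
                    rules$rules)
  match_mat <- vapply(perfect, function(r) {
    pos <- r$literals$position
    st <- r$literals$state
    rowSums(seqs[, pos, drop = FALSE] !=
              matrix(st, nrow(seqs), length(pos), byrow = TRUE)) == 0L
  }, logical(nrow(seqs)))
  match_mat <- matrix(match_mat, nrow = nrow(seqs))
  out <- apply(match_mat, 1, function(m) {
    hits <- which(m)
    if (length(hits) == 1L) perfect[[hits]]$species else "unknown"
  })
  names(out) <- rownames(seqs)
  out
}

#' Diagnostic-method species success
#'
#' A species is successfully identified only when all its training and
#' test individuals classify to it. Species without a test individual
#' (singletons) are not evaluable and are excluded from the species
#' denominator by default. The individual-level identification rate
#' (fraction of all individuals classified to their true species) is
#' reported independently: neither rate bounds the other.
#'
#' @param aln [marker_alignment()] holding all individuals.
#' @param tab Sample table.
#' @param split A split from [split_train_test()].
#' @param rules A `rule_set` mined on the training individuals.
#' @param include_singletons Count non-evaluable species as failures.
#' @return List with `species` (`data.frame`), `rate` (percent of
#'   evaluable species), `individual_rate` (percent of all individuals
#'   correctly classified) and `assignments`.
#' @export
blog_success <- function(aln, tab, split, rules,
                         include_singletons = FALSE) {
  stopifnot(inherits(aln, "marker_alignment"))
  ids <- c(split$train, split$test)
  miss <- setdiff(ids, aln$ids)
  if (length(miss)) stop("input error: split ids absent from alignment: ",
                         paste(miss, collapse = ", "))
  assigned <- classify_sequences(rules, aln$seqs[ids, , drop = FALSE])
  truth <- tab$species[match(ids, tab$individual_id)]
  correct <- assigned == truth
  species <- sort(unique(truth))
  in_test <- species %in% tab$species[match(split$test, tab$individual_id)]
  success <- vapply(species, function(s) all(correct[truth == s]),
                    logical(1)) & in_test
  denom <- if (include_singletons) rep(TRUE, length(species)) else in_test
  rate <- if (any(denom)) 100 * sum(success[denom]) / sum(denom) else NA_real_
  list(
    species = data.frame(species = species, evaluable = in_test,
                         success = success, stringsAsFactors = FALSE),
    rate = rate,
    individual_rate = 100 * mean(correct),
    assignments = data.frame(individual_id = ids, species = truth,
                             assigned = assigned,
                             set = rep(c("train", "test"),
                                       c(length(split$train),
                                         length(split$test))),
                             stringsAsFactors = FALSE),
    n_evaluated = sum(denom), n_excluded = sum(!denom)
  )
}
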