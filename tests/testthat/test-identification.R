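test_that("top-hit identification follows the strict conspecific criterion", {
  aln <- marker_alignment(c(a1 = "AAAA", a2 = "AAAA",
                            b1 = "TTTT", b2 = "TTTT"), "m")
  tab <- data.frame(individual_id = aln$ids,
                    species = c("A", "A", "B", "B"),
                    section = "s", region = "r")
  th <- tophit_identify(suppressMessages(distance_matrix(aln)), tab)
  expect_equal(th$rate, 100)
  expect_true(all(th$individuals$conspecific_hit == "yes"))

  # a1 equidistant to conspecific a2 and heterospecific b1: ambiguous tie
  V <- matrix(0.5, 4, 4); diag(V) <- 0
  V[1, 2] <- V[2, 1] <- 0.1
  V[1, 3] <- V[3, 1] <- 0.1
  dimnames(V) <- list(tab$individual_id, tab$individual_id)
  th2 <- tophit_identify(as_pdist_matrix(V), tab)
  expect_equal(th2$individuals$conspecific_hit[1], "ambiguous")
  expect_false(th2$species$success[th2$species$species == "A"])
})

test_that("top-hit matches the brute-force argmin oracle", {
  set.seed(132)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    aln <- rand_aln(n, 30, p_gap = 0.05)
    tab <- rand_tab(aln$ids, 3)
    dm <- suppressMessages(distance_matrix(aln))
    got <- tophit_identify(dm, tab)
    sp <- tab$species[match(aln$ids, tab$individual_id)]
    want <- oracle_tophit_species(dm$values, aln$ids, sp)
    expect_equal(got$species$success, unname(want[got$species$species]))
  }
})

test_that("top-hit success is invariant to positive scaling", {
  set.seed(142)
  aln <- rand_aln(8, 40, p_gap = 0)
  tab <- rand_tab(aln$ids, 3)
  dm <- suppressMessages(distance_matrix(aln))
  dm2 <- dm
  dm2$values <- dm$values * 0.37
  expect_equal(tophit_identify(dm, tab)$species$success,
               tophit_identify(dm2, tab)$species$success)
})

test_that("the stratified split is feasible, flagged and deterministic", {
  tab <- data.frame(
    individual_id = c(sprintf("a%02d", 1:10), "b1", "b2", "c1"),
    species = c(rep("A", 10), "B", "B", "C"),
    section = "s", region = "r")
  sp <- split_train_test(tab, 0.8, seed = 3)
  expect_equal(sum(grepl("^a", sp$train)), 8L)
  expect_equal(sum(grepl("^a", sp$test)), 2L)
  expect_equal(sum(grepl("^b", sp$train)), 1L)
  expect_equal(sum(grepl("^b", sp$test)), 1L)
  expect_true("c1" %in% sp$train)
  expect_equal(sp$not_evaluable, "C")
  expect_identical(sp, split_train_test(tab, 0.8, seed = 3))
  expect_error(split_train_test(tab, 1.2), "input error")
})

test_that("rule mining finds single diagnostic positions", {
  base <- strsplit("ACGTACGTAC", "")[[1]]
  mkrow <- function(mut = NULL) {
    r <- base
    if (!is.null(mut)) r[mut[[1]]] <- mut[[2]]
    r
  }
  seqs <- rbind(a1 = mkrow(list(5, "G")), a2 = mkrow(list(5, "G")),
                b1 = mkrow(), b2 = mkrow(list(9, "T")))
  aln <- marker_alignment(seqs, "m")
  tab <- data.frame(individual_id = rownames(seqs),
                    species = c("A", "A", "B", "B"),
                    section = "s", region = "r")
  rules <- mine_rules(aln, tab)
  ra <- rules$rules[[1]]
  expect_true(ra$perfect)
  expect_equal(nrow(ra$literals), 1L)
  # exhaustive single-literal oracle: position 5 state G is the only
  # literal kept by all A and matched by no B
  found <- c()
  for (p in 1:10) {
    st <- unique(seqs[1:2, p])
    if (length(st) == 1 && st %in% c("A", "C", "G", "T") &&
        all(seqs[3:4, p] != st))
      found <- c(found, p)
  }
  expect_equal(ra$literals$position, found)
  expect_equal(ra$literals$state, "G")
})

test_that("identical training species yield imperfect rules", {
  seqs <- rbind(a1 = c("A", "C", "G"), a2 = c("A", "C", "G"),
                b1 = c("A", "C", "G"))
  aln <- marker_alignment(seqs, "m")
  tab <- data.frame(individual_id = rownames(seqs),
                    species = c("A", "A", "B"),
                    section = "s", region = "r")
  rules <- mine_rules(aln, tab)
  expect_false(rules$rules[[1]]$perfect)
  expect_false(rules$rules[[2]]$perfect)
})

test_that("a two-literal conjunction is found when no single literal works", {
  # A is T at 3 and C at 7; each heterospecific shares exactly one of them
  base <- strsplit("AAAAAAAAAA", "")[[1]]
  mk <- function(p3, p7) { r <- base; r[3] <- p3; r[7] <- p7; r }
  seqs <- rbind(a1 = mk("T", "C"), a2 = mk("T", "C"),
                h1 = mk("T", "A"), h2 = mk("G", "C"))
  aln <- marker_alignment(seqs, "m")
  tab <- data.frame(individual_id = rownames(seqs),
                    species = c("A", "A", "H1", "H2"),
                    section = "s", region = "r")
  rules <- mine_rules(aln, tab, L_max = 2)
  ra <- rules$rules[[1]]
  expect_true(ra$perfect)
  expect_setequal(ra$literals$position, c(3, 7))
  # exhaustive 2-literal oracle over all position pairs
  ok_pairs <- list()
  for (p in 1:9) for (q in (p + 1):10) {
    stp <- unique(seqs[1:2, p]); stq <- unique(seqs[1:2, q])
    if (length(stp) == 1 && length(stq) == 1 &&
        all(c(stp, stq) %in% c("A", "C", "G", "T")) &&
        !any(seqs[3:4, p] == stp & seqs[3:4, q] == stq))
      ok_pairs[[length(ok_pairs) + 1]] <- c(p, q)
  }
  expect_true(any(vapply(ok_pairs, setequal, logical(1),
                         y = ra$literals$position)))
})

test_that("rule literals never sit on polymorphic or ambiguous columns", {
  set.seed(152)
  for (rep in 1:10) {
    aln <- rand_aln(8, 20, p_gap = 0.1, p_n = 0.1)
    tab <- rand_tab(aln$ids, 3)
    rules <- mine_rules(aln, tab)
    sp <- tab$species[match(aln$ids, tab$individual_id)]
    for (r in rules$rules) {
      own <- aln$seqs[sp == r$species, , drop = FALSE]
      for (i in seq_len(nrow(r$literals))) {
        col <- own[, r$literals$position[i]]
        expect_true(all(col == r$literals$state[i]))
        expect_true(r$literals$state[i] %in% c("A", "C", "G", "T"))
      }
    }
  }
})

test_that("classification demands a unique perfect-rule match", {
  seqs <- rbind(a1 = c("G", "A", "A"), a2 = c("G", "A", "A"),
                b1 = c("T", "A", "A"), b2 = c("T", "A", "A"))
  aln <- marker_alignment(seqs, "m")
  tab <- data.frame(individual_id = rownames(seqs),
                    species = c("A", "A", "B", "B"),
                    section = "s", region = "r")
  rules <- mine_rules(aln, tab)
  expect_equal(unname(classify_sequences(rules, c("G", "A", "A"))), "A")
  expect_equal(unname(classify_sequences(rules, c("C", "A", "A"))), "unknown")
  expect_error(classify_sequences(rules, c("G", "A")), "input error")
})

test_that("diagnostic-method scoring needs all train and test hits", {
  set.seed(162)
  # two well-separated species, 5 individuals each
  seqs <- rbind(
    matrix(rep(strsplit("AAAACCCCGGGG", "")[[1]], 5), 5, byrow = TRUE),
    matrix(rep(strsplit("TTTTCCCCGGGG", "")[[1]], 5), 5, byrow = TRUE))
  rownames(seqs) <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  aln <- marker_alignment(seqs, "m")
  tab <- data.frame(individual_id = rownames(seqs),
                    species = rep(c("A", "B"), each = 5),
                    section = "s", region = "r")
  split <- split_train_test(tab, 0.8, seed = 1)
  train_aln <- marker_alignment(aln$seqs[split$train, , drop = FALSE], "m")
  rules <- mine_rules(train_aln, tab)
  bs <- blog_success(aln, tab, split, rules)
  expect_equal(bs$rate, 100)
  expect_equal(bs$individual_rate, 100)

  # corrupt one test individual of A at every diagnostic position
  test_a <- intersect(split$test, sprintf("a%d", 1:5))[1]
  seqs2 <- seqs
  seqs2[test_a, 1:4] <- "C"
  bs2 <- blog_success(marker_alignment(seqs2, "m"), tab, split, rules)
  expect_equal(bs2$rate, 50)
  expect_true(bs2$species$success[bs2$species$species == "B"])
})
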