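# Combined-graph edge enumeration, weights, penalty, and A* search.

test_that("edge weights follow ln P_transition + ln P_emission (+ ln alpha)", {
  # hand-built model: M1 -0.9-> M2, emission P(G at 2) = 0.3
  trans <- matrix(-Inf, 3, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  trans[, "MM"] <- log(c(1, 0.9, 1))
  trans[2, "MI"] <- log(0.1)
  trans[, "IM"] <- 0
  trans[2:3, "DM"] <- 0
  em <- log(rbind(c(.25, .25, .25, .25), c(.4, .2, .3, .1)))
  colnames(em) <- NT
  h <- gtasm:::new_profile_hmm(2, "nt", trans, em)

  g4 <- build_graph(c("ACG", "ACG", "ACG", "ACG"), 2, add_reverse_complement = FALSE)
  # AC (count 4) -> CG (count 4) ends in 'G'
  s <- cag_successors(g4, h, "AC", 1, "M", penalty_config(0.5))
  mm <- s[s$state == "M", ]
  expect_equal(mm$kmer, "CG")
  expect_equal(mm$weight, log(0.9) + log(0.3), tolerance = 1e-12)
  expect_equal(log(0.9) + log(0.3), -1.3093, tolerance = 1e-4)

  g1 <- build_graph("ACG", 2, add_reverse_complement = FALSE)   # all counts 1
  s1 <- cag_successors(g1, h, "AC", 1, "M", penalty_config(0.5))
  mm1 <- s1[s1$state == "M", ]
  expect_equal(mm1$weight, log(0.9) + log(0.3) + log(0.5), tolerance = 1e-12)
  expect_equal(mm1$weight, -2.0025, tolerance = 1e-4)

  # a k-mer with no graph successors offers only delete moves
  trans2 <- trans; trans2[2, "MD"] <- log(0.05)
  trans2[2, "MM"] <- log(0.85)
  trans2[2:3, "DD"] <- c(log(0.5), -Inf)
  trans2[2:3, "DM"] <- c(log(0.5), 0)
  h2 <- gtasm:::new_profile_hmm(2, "nt", trans2, em, tol = 1e-6)
  sdead <- cag_successors(g1, h2, "CG", 1, "M", penalty_config(0.5))
  expect_true(all(sdead$state %in% c("D", "E")))
})

test_that("the low-coverage penalty applies exactly at multiplicity one", {
  cfg5 <- penalty_config(0.5)
  expect_equal(penalized_weight(-1, 2L, cfg5), -1)
  expect_equal(penalized_weight(-1, 1L, penalty_config(1.0)), -1)
  expect_equal(penalized_weight(-1, 1L, cfg5), -1 + log(0.5))
  expect_equal(penalized_weight(-1, 1L, cfg5), -1.6931, tolerance = 1e-4)
  expect_equal(penalized_weight(-1, 1L, cfg5, exempt = TRUE), -1)
  expect_error(penalized_weight(-1, 0L, cfg5), "multiplicity")
  expect_error(penalty_config(0), "alpha")
  expect_error(penalty_config(1.5), "alpha")
})

test_that("start vertices are read k-mers matching reference windows", {
  refs <- c(r1 = "ACGTACG", r2 = "ACGTACG")
  h <- hmm_from_alignment(refs, pseudocount = 1)
  g <- build_graph("ACGTAC", 4, add_reverse_complement = FALSE)
  seeds <- find_start_vertices(g, refs, h)
  # windows of the reference present in the graph: ACGT(j=4), CGTA(5), GTAC(6)
  expect_setequal(seeds$kmer, c("ACGT", "CGTA", "GTAC"))
  expect_equal(seeds$j[seeds$kmer == "ACGT"], 4L)
  expect_equal(seeds$j_first[seeds$kmer == "ACGT"], 1L)

  # a reference window absent from the reads is never a seed
  g2 <- build_graph("TTTTTT", 4, add_reverse_complement = FALSE)
  expect_equal(nrow(find_start_vertices(g2, refs, h)), 0L)
})

test_that("windows ending in an insert column anchor to the previous match column", {
  # column 3 is gapped in half the rows -> insert; model columns 1,2,4,5
  refs <- c(r1 = "ACGTA", r2 = "AC-TA", r3 = "ACGTA", r4 = "AC-TA")
  h <- hmm_from_alignment(refs, pseudocount = 1)
  expect_equal(h$L, 4L)
  g <- build_graph("ACG", 3, add_reverse_complement = FALSE)
  seeds <- find_start_vertices(g, refs, h)
  # window ACG of r1 ends in alignment column 3 (insert) -> anchors to match
  # position 2 (column 2)
  expect_equal(seeds$kmer, "ACG")
  expect_equal(seeds$j, 2L)
})

test_that("search on a branch-free graph equals the Viterbi oracle", {
  set.seed(101)
  for (rep in 1:10) {
    s <- rand_nt_seq(10)
    k <- 4
    g <- build_graph(s, k, add_reverse_complement = FALSE)
    if (n_kmers(g) < nchar(s) - k + 1L) next   # repeated k-mer: not branch-free
    emp <- t(vapply(seq_len(nchar(s)), function(j) { x <- runif(4) + .05; x / sum(x) },
                    numeric(4)))
    h <- all_match_hmm(emp)
    # anchored at the first k-mer, position k (its last character's column)
    res <- astar_best_path(g, h, substr(s, 1, k), k, penalty_config(1.0))
    expect_false(res$partial)
    expect_equal(res$sequence, s)
    # oracle: full-sequence Viterbi minus the prefix the anchor fixes
    anchor_score <- sum(vapply(seq_len(k), function(j) h$em[j, substr(s, j, j)],
                               numeric(1)))   # MM transitions are ln 1
    expect_equal(res$score, oracle_viterbi(h, s) - anchor_score, tolerance = 1e-9)
  }
})

test_that("search equals exhaustive product-graph relaxation on random instances", {
  set.seed(111)
  done <- 0
  while (done < 40) {
    inst <- random_cag_instance()
    if (is.null(inst)) next
    alpha <- sample(c(0.5, 1.0), 1)
    orc <- oracle_cag_best(inst$kmers, inst$counts, 4L, inst$h, alpha,
                           inst$start_kmer, inst$start_j)
    res <- astar_best_path(inst$g, inst$h, inst$start_kmer, inst$start_j,
                           penalty_config(alpha))
    if (is.finite(orc$best)) {
      expect_false(res$partial)
      expect_equal(res$score, orc$best, tolerance = 1e-9)
      validate_search_result(res, inst$g, inst$h, penalty_config(alpha))
    } else {
      expect_true(res$partial)
    }
    done <- done + 1
  }
})

test_that("the heuristic never under-estimates the true remaining score", {
  set.seed(121)
  done <- 0
  while (done < 10) {
    inst <- random_cag_instance()
    if (is.null(inst)) next
    heur <- hmm_heuristic(inst$h)
    # oracle best-from-vertex: relax from each vertex by running the oracle
    # with that vertex as start (penalty-free so heuristic and truth share
    # assumptions about alpha = 1)
    for (probe in 1:3) {
      u <- sample(inst$kmers, 1)
      j <- sample(0:inst$h$L, 1)
      orc <- oracle_cag_best(inst$kmers, inst$counts, 4L, inst$h, 1.0, u, max(j, 1))
      if (is.finite(orc$best))
        expect_gte(heur[max(j, 1) + 1L, "M"] + 1e-9, orc$best)
    }
    done <- done + 1
  }
})

test_that("alpha = 1 reproduces penalty-free scores bit-exactly and alpha = 0.5 never scores higher", {
  set.seed(131)
  done <- 0
  while (done < 10) {
    inst <- random_cag_instance()
    if (is.null(inst)) next
    r1 <- astar_best_path(inst$g, inst$h, inst$start_kmer, inst$start_j,
                          penalty_config(1.0))
    r5 <- astar_best_path(inst$g, inst$h, inst$start_kmer, inst$start_j,
                          penalty_config(0.5))
    # alpha = 1: identical to a configuration with no penalty term at all
    r1b <- astar_best_path(inst$g, inst$h, inst$start_kmer, inst$start_j,
                           penalty_config(1 - 1e-300))
    expect_identical(r1$score, r1b$score)
    expect_identical(r1$sequence, r1b$sequence)
    if (!r1$partial && !r5$partial) expect_lte(r5$score, r1$score + 1e-12)
    done <- done + 1
  }
})

test_that("the penalty flips branch choice exactly when the margin is below |ln alpha|", {
  # fork after seed k-mer ACA: true branch (count 2) spells ACATGTGC,
  # erroneous branch (count 1) spells ACACACAT; per-position emission
  # advantage delta for the erroneous characters, 5 penalized k-mers
  k <- 3
  true_s <- "ACATGTGC"
  err_s  <- "ACACTCAC"
  build_inst <- function(delta) {
    g <- build_graph(c(true_s, true_s, err_s), k, add_reverse_complement = FALSE)
    L <- nchar(true_s)
    emp <- matrix(0.05, nrow = L, ncol = 4, dimnames = list(NULL, NT))
    for (j in 1:k) emp[j, substr(true_s, j, j)] <- 0.8
    for (j in (k + 1):L) {
      tc <- substr(true_s, j, j); ec <- substr(err_s, j, j)
      emp[j, tc] <- 0.3
      emp[j, ec] <- 0.3 * exp(delta)
    }
    emp <- emp / rowSums(emp)
    # renormalisation shrinks both branch characters equally per row, so the
    # per-step advantage of the erroneous branch stays exactly delta
    all_match_hmm(emp)
  }
  delta <- 0.3           # < ln 2 = 0.693 per penalized k-mer
  h <- build_inst(delta)
  g <- build_graph(c(true_s, true_s, err_s), k, add_reverse_complement = FALSE)
  no_pen <- astar_best_path(g, h, "ACA", k, penalty_config(1.0))
  with_pen <- astar_best_path(g, h, "ACA", k, penalty_config(0.5))
  expect_equal(no_pen$sequence, err_s)
  expect_equal(with_pen$sequence, true_s)

  # margin above |ln alpha|: the penalty no longer flips the choice
  h_big <- build_inst(0.8)  # > ln 2
  no_pen2 <- astar_best_path(g, h_big, "ACA", k, penalty_config(1.0))
  with_pen2 <- astar_best_path(g, h_big, "ACA", k, penalty_config(0.5))
  expect_equal(no_pen2$sequence, err_s)
  expect_equal(with_pen2$sequence, err_s)
})

test_that("unreachable ends yield flagged partial results, never silence", {
  # model demanding an emission the graph cannot provide at position 3
  emp <- rbind(c(.7, .1, .1, .1), c(.1, .7, .1, .1), c(1e-12, 1e-12, 1 - 3e-12, 1e-12))
  emp[3, ] <- c(0, 0, 1, 0)      # only G possible at position 3
  h <- all_match_hmm(emp)
  g <- build_graph("ACT", 2, add_reverse_complement = FALSE)  # no G anywhere
  res <- astar_best_path(g, h, "AC", 2, penalty_config(1.0))
  expect_true(res$partial)
})

test_that("bidirectional assembly merges forward and reverse extensions", {
  set.seed(141)
  s <- rand_nt_seq(30)
  k <- 6
  g <- build_graph(s, k, add_reverse_complement = FALSE)
  refs <- stats::setNames(c(s, s), c("a", "b"))
  h <- hmm_from_alignment(refs, pseudocount = 0.01)
  h_rev <- reverse_hmm(h)
  seeds <- find_start_vertices(g, refs, h)

  # anchored at position k (first window): reverse extension is empty
  sd1 <- seeds[seeds$j_first == 1L, ][1, ]
  ctg1 <- bidirectional_assemble(g, h, h_rev, sd1, penalty_config(1.0))
  expect_equal(ctg1$sequence, s)
  fwd_only <- astar_best_path(g, h, sd1$kmer, sd1$j, penalty_config(1.0))
  expect_equal(ctg1$sequence, fwd_only$sequence)

  # mid-gene anchor on a branch-free graph: contig equals the unitig spelling
  sdm <- seeds[seeds$j == 15, ][1, ]
  ctgm <- bidirectional_assemble(g, h, h_rev, sdm, penalty_config(1.0))
  expect_equal(ctgm$sequence, spell_unitigs(g)$sequence)
  expect_equal(ctgm$score, ctgm$fwd_score + ctgm$rev_score)

  # two seeds on the same path dereplicate to one contig
  ctgs <- search_seeds(g, h, seeds[c(1, 8), ], penalty_config(1.0))
  expect_length(ctgs, 1)
  expect_true(all(vapply(windows_of(ctgs[[1]]$sequence, k), has_kmer, logical(1), g = g)))
})
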