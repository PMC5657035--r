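# De Bruijn graph construction, queries, cleaning and unitig spelling.

test_that("graph construction counts windows exactly", {
  g <- build_graph("ACGT", 3, add_reverse_complement = FALSE)
  expect_setequal(graph_kmers(g), c("ACG", "CGT"))
  expect_equal(kmer_count(g, "ACG"), 1L)
  expect_equal(kmer_count(g, "CGT"), 1L)

  # ACGT is its own reverse complement: every k-mer doubles
  g2 <- build_graph("ACGT", 3, add_reverse_complement = TRUE)
  expect_setequal(graph_kmers(g2), c("ACG", "CGT"))
  expect_equal(kmer_count(g2, "ACG"), 2L)
  expect_equal(kmer_count(g2, "CGT"), 2L)

  # windows touching an N contribute nothing
  g3 <- build_graph("ACNGT", 3, add_reverse_complement = FALSE)
  expect_equal(n_kmers(g3), 0L)

  expect_error(build_graph(character(0), 3), "no input")
  expect_error(build_graph("ACDEFG", 3, alphabet = "aa",
                           add_reverse_complement = TRUE), "reverse complement")
  expect_warning(build_graph(c("ACG", "CGT"), 5, add_reverse_complement = FALSE),
                 "exceeds every sequence")
})

test_that("multiplicity sums equal the number of valid windows", {
  set.seed(11)
  for (rep in 1:5) {
    seqs <- vapply(1:4, function(i) rand_nt_seq(sample(20:60, 1)), character(1))
    k <- sample(3:7, 1)
    g <- build_graph(seqs, k, add_reverse_complement = FALSE)
    expect_equal(total_multiplicity(g), sum(pmax(nchar(seqs) - k + 1L, 0L)))
  }
})

test_that("successors match a brute-force all-pairs overlap oracle", {
  g <- build_graph(c("ACGT", "ACGA"), 3, add_reverse_complement = FALSE)
  expect_setequal(successors(g, "ACG"), c("CGT", "CGA"))
  g1 <- build_graph("ACG", 3, add_reverse_complement = FALSE)
  expect_length(successors(g1, "ACG"), 0)
  expect_error(successors(g1, "TTT"), class = "gtasm_missing_kmer")
  expect_error(kmer_count(g1, "TTT"), class = "gtasm_missing_kmer")

  set.seed(21)
  seqs <- vapply(1:6, function(i) rand_nt_seq(15), character(1))
  g <- build_graph(seqs, 4, add_reverse_complement = FALSE)
  km <- graph_kmers(g)
  expect_gte(length(km), 40)
  for (u in km)
    expect_identical(sort(successors(g, u)), brute_successors(km, u))
  for (u in km)
    expect_identical(sort(predecessors(g, u)),
                     sort(km[substr(km, 2, 4) == substr(u, 1, 3)]))
})

test_that("membership is exact: random absent k-mers are never members", {
  set.seed(31)
  g <- build_graph(vapply(1:5, function(i) rand_nt_seq(40), character(1)), 9,
                   add_reverse_complement = FALSE)
  present <- new.env(); for (x in graph_kmers(g)) assign(x, TRUE, present)
  for (i in 1:2000) {
    cand <- rand_nt_seq(9)
    if (!exists(cand, envir = present, inherits = FALSE))
      expect_false(has_kmer(g, cand))
  }
})

test_that("tip removal deletes weak spurs and leaves linear paths alone", {
  # linear path: no tips
  lin <- build_graph(strrep("ACGTGCTTAG", 2), 4, add_reverse_complement = FALSE)
  expect_identical(graph_kmers(remove_tips(lin)), graph_kmers(lin))

  # main path x5, one-k-mer spur x1 hanging off the branch at CGT
  main <- "ACGTACG"   # ACGT CGTA GTAC TACG
  spur <- "ACGTT"     # ACGT CGTT
  g <- build_graph(c(rep(main, 5), spur), 4, add_reverse_complement = FALSE)
  gc <- remove_tips(g, max_tip_len = 3)
  expect_false(has_kmer(gc, "CGTT"))
  expect_true(all(c("ACGT", "CGTA", "GTAC", "TACG") %in% graph_kmers(gc)))

  # idempotent
  gc2 <- remove_tips(gc, max_tip_len = 3)
  expect_identical(graph_kmers(gc2), graph_kmers(gc))
})

test_that("equal dead ends from one branch resolve by the lexicographic rule", {
  # two equal-length equal-count dead ends: CGTA... vs CGTT...; the
  # lexicographically larger spelled path (ending T) loses
  a <- "ACGTA"  # ACGT CGTA
  b <- "ACGTT"  # ACGT CGTT
  g <- build_graph(c("GACGT", a, b), 4, add_reverse_complement = FALSE)
  gc <- remove_tips(g, max_tip_len = 2)
  expect_true(has_kmer(gc, "CGTA"))
  expect_false(has_kmer(gc, "CGTT"))
})

test_that("bubble merging pops the weaker arm and reaches a fixpoint", {
  # two parallel arms between shared source and sink, differing mid-char
  strong <- "TAACGATTG"
  weak <- "TAACTATTG"   # one substitution
  g <- build_graph(c(rep(strong, 5), weak), 4, add_reverse_complement = FALSE)
  gc <- merge_bubbles(g, max_bubble_len = 12)
  for (w in setdiff(windows_of(weak, 4), windows_of(strong, 4)))
    expect_false(has_kmer(gc, w))
  for (s in windows_of(strong, 4))
    expect_true(has_kmer(gc, s))

  # no parallel paths: unchanged
  lin <- build_graph("TAACGATTG", 4, add_reverse_complement = FALSE)
  expect_identical(graph_kmers(merge_bubbles(lin)), graph_kmers(lin))
})

test_that("unitig spelling covers each k-mer once and round-trips", {
  g <- build_graph("ACGTT", 3, add_reverse_complement = FALSE)
  u <- spell_unitigs(g)
  expect_equal(u$sequence, "ACGTT")

  # branch at CG. splits everything into singletons
  g2 <- build_graph(c("ACGT", "ACGA"), 3, add_reverse_complement = FALSE)
  u2 <- spell_unitigs(g2)
  expect_setequal(u2$sequence, c("ACG", "CGT", "CGA"))

  # random branch-free chain: unitig length n + k - 1; build/spell round trip
  set.seed(41)
  for (rep in 1:5) {
    s <- rand_nt_seq(30)
    k <- 6
    g3 <- build_graph(s, k, add_reverse_complement = FALSE)
    u3 <- spell_unitigs(g3)
    if (nrow(u3) == 1L)
      expect_equal(nchar(u3$sequence), n_kmers(g3) + k - 1L)
    g4 <- build_graph(u3$sequence, k, add_reverse_complement = FALSE)
    expect_identical(graph_kmers(g4), graph_kmers(g3))
  }
})

test_that("every k-mer lands in exactly one unitig", {
  set.seed(51)
  seqs <- vapply(1:4, function(i) rand_nt_seq(25), character(1))
  g <- build_graph(seqs, 5, add_reverse_complement = FALSE)
  u <- spell_unitigs(g)
  all_u_kmers <- unlist(lapply(u$sequence, windows_of, k = 5))
  expect_setequal(unique(all_u_kmers), graph_kmers(g))
  expect_equal(sum(u$n_kmers), n_kmers(g))
})

test_that("cleaning never deletes the path between solid anchors", {
  # a solid through-path (count 5) with an erroneous spur; the whole
  # through-path must survive tips + bubbles
  set.seed(61)
  core <- rand_nt_seq(40)
  err <- paste0(substr(core, 1, 20), "A")  # read with one wrong trailing base
  g <- build_graph(c(rep(core, 5), err), 6, add_reverse_complement = FALSE)
  gc <- clean_graph(g)
  for (w in windows_of(core, 6)) expect_true(has_kmer(gc, w))
})

test_that("graph TSV dump has one row per k-mer with its count", {
  g <- build_graph(c("ACGT", "ACGT"), 3, add_reverse_complement = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  df <- read.delim(path)
  expect_equal(df$kmer, c("ACG", "CGT"))
  expect_equal(df$count, c(2L, 2L))
})
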