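# Exact, multiplicity-aware de Bruijn graph.
#
# The graph is a hash map (environment) from k-mer to its multiplicity: the
# number of occurrences across the input sequences (plus reverse complements
# when requested). Edges are implicit: (u, v) exists iff the (k-1)-suffix of u
# equals the (k-1)-prefix of v and both are stored. Membership is exact — no
# false positives and no false negatives — which is what makes the
# multiplicity usable as an error signal downstream.

#' Build an exact multiplicity-aware de Bruijn graph
#'
#' Every length-`k` window of every input sequence contributes one count to
#' its k-mer; windows containing any character outside the alphabet (e.g. `N`)
#' contribute nothing. For nucleotide graphs the reverse complement of every
#' sequence is counted as well by default, so both strands are represented and
#' downstream traversal never needs reverse-complement logic.
#'
#' @param sequences character vector of sequences (reads and/or contigs).
#' @param k k-mer length, an integer >= 2.
#' @param alphabet `"nt"` or `"aa"`.
#' @param add_reverse_complement also count the reverse complement of each
#'   sequence. Default `TRUE` for nucleotide input; an error for amino acids.
#' @return An object of class `kmer_graph` with fields `k`, `alphabet`,
#'   `counts` (environment k-mer -> integer multiplicity) and `contig_only`
#'   (environment marking k-mers supported only by carried contigs, empty
#'   unless set by [iterate_graph()]).
#' @examples
#' g <- build_graph("ACGTACGT", k = 4, add_reverse_complement = FALSE)
#' graph_kmers(g)
#' @export
build_graph <- function(sequences, k, alphabet = "nt",
                        add_reverse_complement = (alphabet == "nt")) {
  alphabet <- match.arg(alphabet, names(GT_ALPHABETS))
  if (length(sequences) == 0L) stop("no input sequences")
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (add_reverse_complement && alphabet != "nt")
    stop("reverse complement is undefined for the amino-acid alphabet")

  sequences <- toupper(as.character(sequences))
  if (add_reverse_complement) sequences <- c(sequences, revcomp(sequences))

  kmers <- extract_kmers(sequences, k, alphabet)
  if (length(kmers) == 0L && all(nchar(sequences) < k))
    warning("k = ", k, " exceeds every sequence length; graph is empty")

  counts <- new.env(hash = TRUE, parent = emptyenv())
  if (length(kmers)) {
    tab <- table(kmers)
    nm <- names(tab)
    cnt <- as.integer(tab)
    for (i in seq_along(nm)) assign(nm[i], cnt[i], envir = counts)
  }
  structure(
    list(k = k, alphabet = alphabet, chars = alphabet_chars(alphabet),
         counts = counts,
         contig_only = new.env(hash = TRUE, parent = emptyenv()),
         n_windows = length(kmers)),
    class = "kmer_graph"
  )
}

# All valid k-length windows of `sequences`, with multiplicity.
extract_kmers <- function(sequences, k, alphabet) {
  alpha <- alphabet_chars(alphabet)
  out <- vector("list", length(sequences))
  for (si in seq_along(sequences)) {
    s <- sequences[si]
    n <- nchar(s)
    if (n < k) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- cumsum(!(chars %in% alpha))
    starts <- seq_len(n - k + 1L)
    ok <- (bad[starts + k - 1L] - c(0L, bad)[starts]) == 0L
    if (!any(ok)) next
    out[[si]] <- substring(s, starts[ok], starts[ok] + k - 1L)
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: k=%d, alphabet=%s, %d k-mers, total multiplicity %d\n",
              x$k, x$alphabet, n_kmers(x), total_multiplicity(x)))
  invisible(x)
}

#' Stored k-mers of a graph (sorted)
#' @param g a `kmer_graph`.
#' @return character vector of stored k-mers, lexicographically sorted.
#' @export
graph_kmers <- function(g) sort(ls(g$counts))

#' Number of distinct stored k-mers
#' @param g a `kmer_graph`.
#' @export
n_kmers <- function(g) length(ls(g$counts))

#' Sum of stored multiplicities
#' @param g a `kmer_graph`.
#' @export
total_multiplicity <- function(g) {
  nm <- ls(g$counts)
  if (!length(nm)) return(0L)
  sum(vapply(nm, function(x) get(x, envir = g$counts), integer(1)))
}

#' Exact membership query
#' @param g a `kmer_graph`.
#' @param u candidate k-mer.
#' @return `TRUE` iff `u` occurred in the input.
#' @export
has_kmer <- function(g, u) exists(u, envir = g$counts, inherits = FALSE)

#' Multiplicity of a stored k-mer
#' @param g a `kmer_graph`.
#' @param u stored k-mer.
#' @return integer multiplicity (>= 1).
#' @export
kmer_count <- function(g, u) {
  if (!has_kmer(g, u))
    stop(errorCondition(paste0("k-mer not in graph: ", u),
                        class = "gtasm_missing_kmer"))
  get(u, envir = g$counts, inherits = FALSE)
}

#' Successor k-mers
#'
#' The stored k-mers reachable from `u` by one edge, i.e. those whose
#' (k-1)-prefix equals the (k-1)-suffix of `u`. Querying an unstored k-mer is
#' an error (condition class `gtasm_missing_kmer`), distinct from a stored
#' k-mer with no successors (empty result).
#'
#' @param g a `kmer_graph`.
#' @param u stored k-mer.
#' @return character vector of successors (possibly empty), sorted.
#' @export
successors <- function(g, u) {
  if (!has_kmer(g, u))
    stop(errorCondition(paste0("k-mer not in graph: ", u),
                        class = "gtasm_missing_kmer"))
  cand <- paste0(substr(u, 2L, g$k), g$chars)
  cand[vapply(cand, exists, logical(1), envir = g$counts, inherits = FALSE)]
}

#' Predecessor k-mers
#' @param g a `kmer_graph`.
#' @param u stored k-mer.
#' @return character vector of predecessors (possibly empty), sorted.
#' @export
predecessors <- function(g, u) {
  if (!has_kmer(g, u))
    stop(errorCondition(paste0("k-mer not in graph: ", u),
                        class = "gtasm_missing_kmer"))
  cand <- paste0(g$chars, substr(u, 1L, g$k - 1L))
  cand[vapply(cand, exists, logical(1), envir = g$counts, inherits = FALSE)]
}

# Functional copy: cleaning operations return a new graph.
clone_graph <- function(g) {
  g2 <- g
  g2$counts <- list2env(as.list(g$counts, all.names = TRUE),
                        hash = TRUE, parent = emptyenv())
  g2$contig_only <- list2env(as.list(g$contig_only, all.names = TRUE),
                             hash = TRUE, parent = emptyenv())
  g2
}

delete_kmers <- function(g, kmers) {
  if (length(kmers)) rm(list = kmers, envir = g$counts)
  invisible(g)
}

# Spell the sequence of a k-mer path (first k-mer in full, then one
# character per subsequent k-mer).
spell_path <- function(path, k) {
  if (!length(path)) return("")
  paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
}

#' Remove short dead-end branches (tips)
#'
#' A tip is a simple dead-end path of at most `max_tip_len` k-mers hanging off
#' a branching node. A tip is deleted when its mean multiplicity is lower than
#' that of the strongest competing branch at the same node; on an exact tie
#' the lexicographically larger spelled path loses. Tips are sought in both
#' orientations (dead ends with no successors and with no predecessors).
#' Iterates internally until no further tip qualifies, so a second application
#' is a no-op.
#'
#' @param g a `kmer_graph`.
#' @param max_tip_len maximum tip length in k-mers (default `2 * k`).
#' @return a cleaned copy of `g`.
#' @export
remove_tips <- function(g, max_tip_len = 2L * g$k) {
  stopifnot(max_tip_len >= 1L)
  g <- clone_graph(g)
  for (round in 1:10) {
    doomed <- find_tip_kmers(g, max_tip_len, forward = TRUE)
    doomed <- union(doomed, find_tip_kmers(g, max_tip_len, forward = FALSE))
    if (!length(doomed)) break
    delete_kmers(g, doomed)
  }
  g
}

# Tips in one orientation. forward = TRUE finds dead ends with no successors
# (walking back to the branch node); forward = FALSE the mirror case.
find_tip_kmers <- function(g, max_tip_len, forward) {
  nxt <- if (forward) function(u) successors(g, u) else function(u) predecessors(g, u)
  prv <- if (forward) function(u) predecessors(g, u) else function(u) successors(g, u)
  all_k <- graph_kmers(g)
  dead <- all_k[vapply(all_k, function(u) length(nxt(u)) == 0L, logical(1))]
  doomed <- character(0)
  for (d in dead) {
    path <- d   # tip path, dead end first
    repeat {
      p <- prv(path[length(path)])
      if (length(p) != 1L) { path <- NULL; break }      # isolated or converging: not a tip
      if (length(nxt(p)) > 1L) break                    # p is the branch node
      if (length(path) >= max_tip_len) { path <- NULL; break }
      path <- c(path, p)
    }
    if (is.null(path) || length(path) > max_tip_len) next
    branch <- prv(path[length(path)])
    tip_first <- path[length(path)]                     # k-mer adjacent to branch
    rivals <- setdiff(nxt(branch), tip_first)
    if (!length(rivals)) next
    tip_mult <- mean(vapply(path, kmer_count, integer(1), g = g))
    tip_spell <- spell_path(rev(path), g$k)
    beaten <- FALSE
    for (r in rivals) {
      rp <- walk_nonbranching(g, r, max_tip_len, forward)
      r_mult <- mean(vapply(rp, kmer_count, integer(1), g = g))
      r_spell <- spell_path(rp, g$k)
      if (tip_mult < r_mult || (tip_mult == r_mult && tip_spell > r_spell)) {
        beaten <- TRUE
        break
      }
    }
    if (beaten) doomed <- union(doomed, path)
  }
  doomed
}

# Follow a non-branching path from `u` (inclusive) for up to `limit` k-mers.
walk_nonbranching <- function(g, u, limit, forward = TRUE) {
  nxt <- if (forward) function(x) successors(g, x) else function(x) predecessors(g, x)
  path <- u
  while (length(path) < limit) {
    s <- nxt(path[length(path)])
    if (length(s) != 1L || s %in% path) break
    path <- c(path, s)
  }
  path
}

#' Merge simple bubbles
#'
#' A bubble is a pair of vertex-disjoint simple paths sharing a source and a
#' sink, each of spelled length at most `max_bubble_len` and with spelled
#' lengths differing by at most `len_tol` characters — the signature of a
#' substitution error or a near-identical strain variant. The path with the
#' lower total multiplicity is deleted (ties: the lexicographically larger
#' spelled path loses). Nested bubbles are resolved by iterating to a
#' fixpoint (at most 10 rounds).
#'
#' @param g a `kmer_graph`.
#' @param max_bubble_len maximum spelled length of each bubble arm in
#'   characters (default `3 * k`).
#' @param len_tol maximum spelled-length difference between the arms
#'   (default 3).
#' @return a cleaned copy of `g`.
#' @export
merge_bubbles <- function(g, max_bubble_len = 3L * g$k, len_tol = 3L) {
  stopifnot(max_bubble_len >= g$k)
  g <- clone_graph(g)
  for (pop in 1:200) {   # one bubble resolved per scan; rescan to a fixpoint
    doomed <- find_bubble_kmers(g, max_bubble_len, len_tol)
    if (!length(doomed)) break
    delete_kmers(g, doomed)
  }
  g
}

find_bubble_kmers <- function(g, max_bubble_len, len_tol) {
  for (s in graph_kmers(g)) {
    outs <- successors(g, s)
    if (length(outs) < 2L) next
    arms <- lapply(outs, bubble_arm, g = g, max_len = max_bubble_len)
    for (i in seq_along(arms)) {
      for (j in seq_along(arms)) {
        if (i >= j) next
        a <- arms[[i]]; b <- arms[[j]]
        if (is.null(a) || is.null(b)) next
        if (a$sink != b$sink) next
        if (length(intersect(a$internal, b$internal))) next
        if (abs(a$len - b$len) > len_tol) next
        a_tot <- sum(vapply(a$internal, kmer_count, integer(1), g = g))
        b_tot <- sum(vapply(b$internal, kmer_count, integer(1), g = g))
        loser <-
          if (a_tot < b_tot) a
          else if (b_tot < a_tot) b
          else if (a$spell > b$spell) a else b
        # delete only k-mers private to the losing arm
        return(setdiff(loser$internal, c(a$sink, s)))
      }
    }
  }
  character(0)
}

# Walk a candidate bubble arm from `u` until a convergence node (in-degree
# >= 2) is reached. Returns internal nodes, sink, spelled length, spelled
# string, or NULL if the walk branches or exceeds max_len.
bubble_arm <- function(g, u, max_len) {
  internal <- character(0)
  cur <- u
  repeat {
    if (length(predecessors(g, cur)) >= 2L && length(internal) > 0L)
      return(list(internal = internal, sink = cur,
                  len = g$k + length(internal) - 1L,
                  spell = spell_path(internal, g$k)))
    if (cur %in% internal) return(NULL)  # cycle
    internal <- c(internal, cur)
    if (g$k + length(internal) - 1L > max_len) return(NULL)
    if (length(internal) == 1L && length(predecessors(g, cur)) >= 2L)
      return(NULL)  # immediate reconvergence, no internal path
    s <- successors(g, cur)
    if (length(s) != 1L) return(NULL)
    cur <- s
  }
}

#' Spell maximal non-branching paths (unitigs)
#'
#' Every stored k-mer is assigned to exactly one unitig; unitigs are maximal
#' non-branching paths, spelled as the first k-mer followed by the last
#' character of each subsequent k-mer. Isolated cycles are broken at their
#' lexicographically smallest k-mer.
#'
#' @param g a `kmer_graph`.
#' @return a data.frame with columns `sequence`, `n_kmers`, `min_mult`,
#'   `mean_mult`, ordered by sequence for determinism.
#' @export
spell_unitigs <- function(g) {
  all_k <- graph_kmers(g)
  if (!length(all_k))
    return(data.frame(sequence = character(0), n_kmers = integer(0),
                      min_mult = integer(0), mean_mult = numeric(0)))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  is_start <- function(u) {
    p <- predecessors(g, u)
    length(p) != 1L || length(successors(g, p)) != 1L
  }
  extend <- function(u) {
    path <- u
    assign(u, TRUE, envir = visited)
    repeat {
      s <- successors(g, path[length(path)])
      if (length(s) != 1L) break
      if (length(predecessors(g, s)) != 1L) break
      if (exists(s, envir = visited, inherits = FALSE)) break
      path <- c(path, s)
      assign(s, TRUE, envir = visited)
    }
    path
  }
  paths <- list()
  for (u in all_k) {
    if (exists(u, envir = visited, inherits = FALSE)) next
    if (is_start(u)) paths[[length(paths) + 1L]] <- extend(u)
  }
  # remaining unvisited k-mers lie on isolated cycles
  for (u in all_k) {
    if (exists(u, envir = visited, inherits = FALSE)) next
    paths[[length(paths) + 1L]] <- extend(u)
  }
  mults <- lapply(paths, function(p) vapply(p, kmer_count, integer(1), g = g))
  out <- data.frame(
    sequence = vapply(paths, spell_path, character(1), k = g$k),
    n_kmers = lengths(paths),
    min_mult = vapply(mults, min, integer(1)),
    mean_mult = vapply(mults, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out[order(out$sequence), , drop = FALSE]
}

#' Clean a graph: tips then bubbles, iterated to a fixpoint
#'
#' @param g a `kmer_graph`.
#' @param max_tip_len see [remove_tips()].
#' @param max_bubble_len,len_tol see [merge_bubbles()].
#' @param max_rounds hard cap on cleaning rounds (default 10).
#' @return a cleaned copy of `g`.
#' @export
clean_graph <- function(g, max_tip_len = 2L * g$k, max_bubble_len = 3L * g$k,
                        len_tol = 3L, max_rounds = 10L) {
  for (round in seq_len(max_rounds)) {
    before <- n_kmers(g)
    g <- remove_tips(g, max_tip_len)
    g <- merge_bubbles(g, max_bubble_len, len_tol)
    if (n_kmers(g) == before) break
  }
  g
}

#' Dump a graph as a two-column TSV (`kmer<TAB>count`)
#' @param g a `kmer_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  nm <- graph_kmers(g)
  df <- data.frame(kmer = nm,
                   count = vapply(nm, kmer_count, integer(1), g = g))
  write_tsv_atomic(df, path)
}
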