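# Combined weighted assembly graph (CAG) and HMM-guided best-path search.
#
# The CAG is the Cartesian product of a de Bruijn graph D and a profile HMM
# H: a vertex w pairs a k-mer w.u with an HMM node w.v. An edge (w, w')
# exists iff either
#   (1) (w.u, w'.u) is an edge of D, (w.v, w'.v) an edge of H, and w'.v is a
#       match or insert state, or
#   (2) w.u = w'.u, (w.v, w'.v) an edge of H, and w'.v is a delete state.
# Edge weights are ln P_transition plus, when w'.v is a match state,
# ln P_emission(position, c) with c the last character of w'.u. A k-mer seen
# only once in the reads adds ln(alpha) on top (the low-coverage penalty).
# The graph is never materialised: successors are enumerated on demand and
# the best start-to-end path is found by A* with an HMM-only admissible
# heuristic.

#' Low-coverage penalty configuration
#'
#' @param alpha prior probability that a multiplicity-1 k-mer is correct;
#'   edges entering such a k-mer get `+ln(alpha)`. In (0, 1]; `alpha = 1`
#'   disables the penalty exactly. Default 0.5.
#' @param exempt_contig_kmers if `TRUE`, k-mers supported only by carried
#'   contigs of the iterative construction (see [iterate_graph()]) are never
#'   penalized. Default `FALSE`.
#' @return a `penalty_config` list.
#' @export
penalty_config <- function(alpha = 0.5, exempt_contig_kmers = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single number in (0, 1]")
  structure(list(alpha = alpha, exempt_contig_kmers = exempt_contig_kmers),
            class = "penalty_config")
}

#' Apply the low-coverage penalty to an edge weight
#'
#' @param base_weight edge weight before the penalty (ln-probability terms).
#' @param multiplicity multiplicity of the k-mer the edge enters (>= 1).
#' @param cfg a [penalty_config()].
#' @param exempt bypass the penalty for this k-mer (contig-derived k-mers).
#' @return `base_weight + ln(alpha)` iff `multiplicity == 1` and not exempt,
#'   else `base_weight` unchanged.
#' @export
penalized_weight <- function(base_weight, multiplicity, cfg, exempt = FALSE) {
  if (any(multiplicity < 1L)) stop("multiplicity must be >= 1")
  ifelse(multiplicity == 1L & !exempt, base_weight + log(cfg$alpha), base_weight)
}

vertex_key <- function(kmer, j, state) paste(kmer, j, state, sep = "|")

#' Enumerate CAG successors of a vertex
#'
#' @param g a `kmer_graph`.
#' @param h a `profile_hmm` (must share `g`'s alphabet).
#' @param kmer de Bruijn component of the vertex (must be stored in `g`).
#' @param j HMM position of the vertex.
#' @param state HMM state: `"M"`, `"I"` or `"D"` (begin is `("M", 0)`).
#' @param cfg a [penalty_config()].
#' @param direction `"forward"` walks de Bruijn successors and emits the last
#'   character of the new k-mer; `"reverse"` walks predecessors and emits the
#'   first character (used with the reversed model).
#' @return data.frame with columns `kmer`, `j`, `state` (`"E"` marks the end
#'   node) and `weight` (natural-log). Edges of weight `-Inf` are omitted.
#' @export
cag_successors <- function(g, h, kmer, j, state, cfg = penalty_config(),
                           direction = "forward") {
  v <- cag_succ_vec(g, h, kmer, j, state, cfg, direction)
  data.frame(kmer = v$kmer, j = v$j, state = v$state, weight = v$weight,
             stringsAsFactors = FALSE)
}

# Plain-vector successor enumeration: the A* hot path.
cag_succ_vec <- function(g, h, kmer, j, state, cfg, direction) {
  if (!has_kmer(g, kmer))
    stop(errorCondition(paste0("k-mer not in graph: ", kmer),
                        class = "gtasm_missing_kmer"))
  L <- h$L
  moves <- switch(state,
    M = list(c("MM", "M"), c("MI", "I"), c("MD", "D")),
    I = list(c("IM", "M"), c("II", "I")),
    D = list(c("DM", "M"), c("DD", "D")),
    stop("invalid state: ", state))
  nbr <- NULL   # graph neighbours, fetched lazily
  ln_alpha <- log(cfg$alpha)
  out_k <- character(12L); out_j <- integer(12L); out_s <- character(12L)
  out_w <- numeric(12L); n_out <- 0L
  tr <- h$trans
  for (mv in moves) {
    tt <- mv[1]; target <- mv[2]
    tw <- tr[j + 1L, tt]
    if (!is.finite(tw)) next
    if (target == "M" && j == L) {            # silent transition into end
      n_out <- n_out + 1L
      out_k[n_out] <- kmer; out_j[n_out] <- L; out_s[n_out] <- "E"; out_w[n_out] <- tw
    } else if (target == "D") {
      if (j + 1L > L) next                    # no new k-mer: never penalized
      n_out <- n_out + 1L
      out_k[n_out] <- kmer; out_j[n_out] <- j + 1L; out_s[n_out] <- "D"; out_w[n_out] <- tw
    } else {
      if (is.null(nbr)) {
        cand <- if (direction == "forward") paste0(substr(kmer, 2L, g$k), g$chars)
                else paste0(g$chars, substr(kmer, 1L, g$k - 1L))
        keep <- logical(length(cand))
        for (ci in seq_along(cand))
          keep[ci] <- exists(cand[ci], envir = g$counts, inherits = FALSE)
        nbr <- cand[keep]
      }
      cpos <- if (direction == "forward") g$k else 1L
      for (v in nbr) {
        w <- tw
        j2 <- j
        if (target == "M") {
          j2 <- j + 1L
          ew <- h$em[j2, substr(v, cpos, cpos)]
          if (!is.finite(ew)) next
          w <- w + ew
        }
        if (get(v, envir = g$counts, inherits = FALSE) == 1L &&
            !(cfg$exempt_contig_kmers &&
              exists(v, envir = g$contig_only, inherits = FALSE)))
          w <- w + ln_alpha
        if (is.finite(w)) {
          n_out <- n_out + 1L
          out_k[n_out] <- v; out_j[n_out] <- j2; out_s[n_out] <- target; out_w[n_out] <- w
        }
      }
    }
  }
  idx <- seq_len(n_out)
  list(kmer = out_k[idx], j = out_j[idx], state = out_s[idx], weight = out_w[idx])
}

#' Admissible A* heuristic from the HMM alone
#'
#' Backward dynamic programming over the model, ignoring the de Bruijn graph
#' and the low-coverage penalty and scoring every match step with its best
#' possible emission. The result upper-bounds the true best remaining score
#' from any vertex at (position, state), so A* guided by it is exact.
#'
#' @param h a `profile_hmm`.
#' @return an (L+1) x 3 matrix (columns M, I, D); row j+1 is position j.
#' @export
hmm_heuristic <- function(h) {
  L <- h$L
  emmax <- apply(h$em, 1L, max)
  best <- matrix(-Inf, nrow = L + 1L, ncol = 3L,
                 dimnames = list(NULL, c("M", "I", "D")))
  tr <- h$trans
  for (j in L:0) {
    r <- j + 1L
    if (j == L) {
      best[r, "D"] <- tr[r, "DM"]
      best[r, "I"] <- tr[r, "IM"]
      best[r, "M"] <- max(tr[r, "MM"], tr[r, "MI"] + best[r, "I"])
    } else {
      nextM <- emmax[j + 1L] + best[r + 1L, "M"]
      best[r, "D"] <- max(tr[r, "DM"] + nextM, tr[r, "DD"] + best[r + 1L, "D"])
      best[r, "I"] <- tr[r, "IM"] + nextM   # insert self-loops only lose score
      best[r, "M"] <- max(tr[r, "MM"] + nextM,
                          tr[r, "MI"] + best[r, "I"],
                          tr[r, "MD"] + best[r + 1L, "D"])
    }
  }
  best
}

#' HMM-guided best-path search (A*)
#'
#' Finds the maximum-total-weight CAG path from a starting vertex to any
#' terminating vertex (a vertex whose HMM component is the end node). The
#' heuristic from [hmm_heuristic()] is admissible and consistent, so the
#' first terminating vertex popped is globally optimal and every vertex is
#' expanded at most once. Ties in f-score pop with the higher g-score first,
#' then the lexicographically smaller k-mer, making results deterministic.
#'
#' @param g a `kmer_graph`.
#' @param h a `profile_hmm` (the reversed model for `direction = "reverse"`).
#' @param start_kmer stored k-mer anchoring the search.
#' @param start_j HMM match position of the anchor (1..L).
#' @param cfg a [penalty_config()].
#' @param max_expansions cap on vertex expansions; if hit (or if no
#'   terminating vertex is reachable), the best-scoring dead-end path found
#'   so far is returned with `partial = TRUE`. Default 1e6.
#' @param direction `"forward"` or `"reverse"` (see [cag_successors()]).
#' @param heur precomputed [hmm_heuristic()] matrix (computed if `NULL`).
#' @return a `search_result`: list with `score`, `path` (data.frame of
#'   vertices from start to terminal), `chars` (characters emitted by the
#'   graph moves, in move order), `sequence` (start k-mer plus emitted
#'   characters, in graph orientation), `partial`, `direction`, `expansions`.
#' @export
astar_best_path <- function(g, h, start_kmer, start_j, cfg = penalty_config(),
                            max_expansions = 1e6, direction = "forward",
                            heur = NULL) {
  stopifnot(start_j >= 1L, start_j <= h$L)
  if (!has_kmer(g, start_kmer)) stop("start k-mer not stored in graph")
  if (is.null(heur)) heur <- hmm_heuristic(h)
  hval <- function(j, state) if (state == "E") 0 else heur[j + 1L, state]

  gsc <- new.env(hash = TRUE, parent = emptyenv())
  closed <- new.env(hash = TRUE, parent = emptyenv())
  parent <- new.env(hash = TRUE, parent = emptyenv())

  # binary max-heap in local vectors (modified in place); priority: larger f
  # first, ties larger g first, ties lexicographically smaller k-mer first
  cap <- 256L
  hkey <- character(cap); hf <- numeric(cap); hg <- numeric(cap); hm <- character(cap)
  hn <- 0L

  skey <- vertex_key(start_kmer, start_j, "M")
  assign(skey, 0, envir = gsc)
  hn <- 1L
  hkey[1L] <- skey; hf[1L] <- hval(start_j, "M"); hg[1L] <- 0; hm[1L] <- start_kmer

  best_dead <- NULL; best_dead_g <- -Inf
  goal <- NULL
  expansions <- 0L
  while (hn > 0L) {
    # pop the top entry
    top_key <- hkey[1L]; top_g <- hg[1L]
    hkey[1L] <- hkey[hn]; hf[1L] <- hf[hn]; hg[1L] <- hg[hn]; hm[1L] <- hm[hn]
    hn <- hn - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; b <- i
      if (l <= hn && (hf[l] > hf[b] || (hf[l] == hf[b] &&
          (hg[l] > hg[b] || (hg[l] == hg[b] && hm[l] < hm[b]))))) b <- l
      if (r <= hn && (hf[r] > hf[b] || (hf[r] == hf[b] &&
          (hg[r] > hg[b] || (hg[r] == hg[b] && hm[r] < hm[b]))))) b <- r
      if (b == i) break
      tc <- hkey[i]; hkey[i] <- hkey[b]; hkey[b] <- tc
      tn <- hf[i]; hf[i] <- hf[b]; hf[b] <- tn
      tn <- hg[i]; hg[i] <- hg[b]; hg[b] <- tn
      tc <- hm[i]; hm[i] <- hm[b]; hm[b] <- tc
      i <- b
    }

    key <- top_key
    if (exists(key, envir = closed, inherits = FALSE)) next
    gv <- get(key, envir = gsc, inherits = FALSE)
    if (top_g < gv - 1e-12) next     # stale entry
    assign(key, TRUE, envir = closed)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    kmer <- parts[1]; j <- as.integer(parts[2]); state <- parts[3]
    if (state == "E") { goal <- key; break }
    expansions <- expansions + 1L
    if (expansions > max_expansions) break
    succ <- cag_succ_vec(g, h, kmer, j, state, cfg, direction)
    live <- 0L
    if (length(succ$kmer)) for (i2 in seq_along(succ$kmer)) {
      k2 <- succ$kmer[i2]; j2 <- succ$j[i2]; s2 <- succ$state[i2]
      key2 <- vertex_key(k2, j2, s2)
      if (exists(key2, envir = closed, inherits = FALSE)) next
      g2 <- gv + succ$weight[i2]
      old <- if (exists(key2, envir = gsc, inherits = FALSE))
        get(key2, envir = gsc, inherits = FALSE) else -Inf
      live <- live + 1L
      if (g2 > old) {
        assign(key2, g2, envir = gsc)
        assign(key2, key, envir = parent)
        # push
        if (hn + 1L > length(hkey)) {
          hkey <- c(hkey, character(length(hkey)))
          hf <- c(hf, numeric(length(hf)))
          hg <- c(hg, numeric(length(hg)))
          hm <- c(hm, character(length(hm)))
        }
        hn <- hn + 1L
        hkey[hn] <- key2; hf[hn] <- g2 + hval(j2, s2); hg[hn] <- g2; hm[hn] <- k2
        i <- hn
        while (i > 1L) {
          p <- i %/% 2L
          if (hf[i] > hf[p] || (hf[i] == hf[p] &&
              (hg[i] > hg[p] || (hg[i] == hg[p] && hm[i] < hm[p])))) {
            tc <- hkey[i]; hkey[i] <- hkey[p]; hkey[p] <- tc
            tn <- hf[i]; hf[i] <- hf[p]; hf[p] <- tn
            tn <- hg[i]; hg[i] <- hg[p]; hg[p] <- tn
            tc <- hm[i]; hm[i] <- hm[p]; hm[p] <- tc
            i <- p
          } else break
        }
      }
    }
    if (live == 0L && gv > best_dead_g) { best_dead <- key; best_dead_g <- gv }
  }

  partial <- is.null(goal)
  end_key <- if (!partial) goal else if (!is.null(best_dead)) best_dead else skey
  # reconstruct
  keys <- end_key
  while (keys[1] != skey) {
    keys <- c(get(keys[1], envir = parent, inherits = FALSE), keys)
  }
  pieces <- strsplit(keys, "|", fixed = TRUE)
  path <- data.frame(kmer = vapply(pieces, `[`, "", 1L),
                     j = as.integer(vapply(pieces, `[`, "", 2L)),
                     state = vapply(pieces, `[`, "", 3L),
                     stringsAsFactors = FALSE)
  moved <- path$state %in% c("M", "I") & c(FALSE, rep(TRUE, nrow(path) - 1L))
  cpos <- if (direction == "forward") g$k else 1L
  chars <- substr(path$kmer[moved], cpos, cpos)
  seq_out <- if (direction == "forward") {
    paste0(start_kmer, paste(chars, collapse = ""))
  } else {
    paste0(paste(rev(chars), collapse = ""), start_kmer)
  }
  structure(
    list(score = get(end_key, envir = gsc, inherits = FALSE),
         path = path, chars = chars, sequence = seq_out,
         partial = partial, direction = direction, expansions = expansions),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result (%s): score %.4f, %d vertices, %spartial\n",
              x$direction, x$score, nrow(x$path), if (x$partial) "" else "not "))
  invisible(x)
}

#' Recompute and validate a search result against the CAG
#'
#' Re-derives every edge of the path from [cag_successors()] and checks that
#' the summed weights equal the reported score.
#'
#' @param res a `search_result`.
#' @param g,h,cfg the graph, model and penalty used for the search.
#' @param tol score tolerance (default 1e-9).
#' @return the recomputed score, invisibly; errors if any edge is invalid.
#' @export
validate_search_result <- function(res, g, h, cfg = penalty_config(), tol = 1e-9) {
  p <- res$path
  total <- 0
  if (nrow(p) > 1L) for (i in 2:nrow(p)) {
    succ <- cag_successors(g, h, p$kmer[i - 1L], p$j[i - 1L], p$state[i - 1L],
                           cfg, res$direction)
    hit <- which(succ$kmer == p$kmer[i] & succ$j == p$j[i] & succ$state == p$state[i])
    if (length(hit) != 1L)
      stop("path step ", i, " is not a CAG edge")
    total <- total + succ$weight[hit]
  }
  if (abs(total - res$score) > tol)
    stop(sprintf("recomputed score %.12f != reported %.12f", total, res$score))
  invisible(total)
}
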