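# Independent oracles and instance generators shared across tests.
# Everything here re-derives expected values from first principles, without
# calling the package's graph-successor or search code paths.

NT <- c("A", "C", "G", "T")

rand_nt_seq <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

# All k-windows of a string (no alphabet filtering; inputs are clean ACGT).
windows_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# Brute-force successor map: all-pairs (k-1)-overlap comparison.
brute_successors <- function(kmers, u) {
  k <- nchar(u)
  sort(kmers[substr(kmers, 1L, k - 1L) == substr(u, 2L, k)])
}

# Random profile HMM via Dirichlet-ish rows (rgamma normalised). Built with
# the package constructor but with externally drawn parameters.
random_hmm <- function(L, conc = 1) {
  rdir <- function(n) { x <- stats::rgamma(n, conc) + 1e-4; x / sum(x) }
  trans <- matrix(-Inf, L + 1L, 7L,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (j in 0:L) {
    for (st in c("M", "I", "D")) {
      cols <- switch(st,
                     M = if (j < L) c("MM", "MI", "MD") else c("MM", "MI"),
                     I = c("IM", "II"),
                     D = if (j == 0L) character(0) else if (j < L) c("DM", "DD") else "DM")
      if (length(cols)) trans[j + 1L, cols] <- log(rdir(length(cols)))
    }
  }
  em <- t(vapply(seq_len(L), function(j) log(rdir(4L)), numeric(4)))
  colnames(em) <- NT
  gtasm:::new_profile_hmm(L, "nt", trans, em)
}

# An HMM whose only transitions are M->M with probability 1 (all-match),
# with the given emission matrix rows (probabilities).
all_match_hmm <- function(em_prob) {
  L <- nrow(em_prob)
  trans <- matrix(-Inf, L + 1L, 7L,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  trans[, "MM"] <- 0          # ln 1
  trans[, "IM"] <- 0          # unreachable I/D states still need normalised rows
  trans[2:(L + 1L), "DM"] <- 0
  em <- log(em_prob)
  colnames(em) <- NT
  gtasm:::new_profile_hmm(L, "nt", trans, em)
}

# Independent Viterbi over a single sequence under the package's scoring
# semantics: match edges score transition + emission, insert edges consume a
# character but score transition only, delete edges score transition only.
# Returns the best begin-to-end path score for the full sequence.
oracle_viterbi <- function(h, s) {
  n <- nchar(s)
  L <- h$L
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  tr <- h$trans
  NEG <- -Inf
  M <- matrix(NEG, L + 1L, n + 1L)   # [j+1, i+1]: at M_j having consumed i chars
  I <- matrix(NEG, L + 1L, n + 1L)
  D <- matrix(NEG, L + 1L, n + 1L)
  M[1L, 1L] <- 0                     # begin
  for (i in 0:n) {
    for (j in 0:L) {
      r <- j + 1L; ci <- i + 1L
      if (j >= 1L && i >= 1L) {
        e <- h$em[j, ch[i]]
        M[r, ci] <- e + max(M[r - 1L, ci - 1L] + tr[r - 1L, "MM"],
                            I[r - 1L, ci - 1L] + tr[r - 1L, "IM"],
                            D[r - 1L, ci - 1L] + tr[r - 1L, "DM"])
      }
      if (i >= 1L)
        I[r, ci] <- max(M[r, ci - 1L] + tr[r, "MI"],
                        I[r, ci - 1L] + tr[r, "II"])
      if (j >= 1L)
        D[r, ci] <- max(M[r - 1L, ci] + tr[r - 1L, "MD"],
                        D[r - 1L, ci] + tr[r - 1L, "DD"])
    }
  }
  max(M[L + 1L, n + 1L] + tr[L + 1L, "MM"],
      I[L + 1L, n + 1L] + tr[L + 1L, "IM"],
      D[L + 1L, n + 1L] + tr[L + 1L, "DM"])
}

# Independent combined-graph oracle: enumerate all product vertices and
# edges from first principles, then find the exact best start-to-end path by
# iterated relaxation (exact for longest path when every cycle has negative
# total weight, which holds since all edge weights are log-probabilities and
# penalties). Returns list(best = best end score or -Inf,
# value = named vector of best path scores from the start to every vertex).
oracle_cag_best <- function(kmers, counts, k, h, alpha, start_kmer, start_j,
                            max_pass = 10000L) {
  L <- h$L
  tr <- h$trans
  states <- c("M", "I", "D")
  vkey <- function(u, j, st) paste(u, j, st, sep = "|")
  ids <- new.env(hash = TRUE, parent = emptyenv())
  nv <- 0L
  vid <- function(key) {
    if (!exists(key, envir = ids, inherits = FALSE)) {
      nv <<- nv + 1L
      assign(key, nv, envir = ids)
    }
    get(key, envir = ids, inherits = FALSE)
  }
  succ_map <- lapply(kmers, function(u) kmers[substr(kmers, 1, k - 1) == substr(u, 2, k)])
  names(succ_map) <- kmers
  cnt <- stats::setNames(counts, kmers)
  ef <- ej <- ew <- list()
  add_edge <- function(a, b, w) {
    i <- length(ef) + 1L
    ef[[i]] <<- a; ej[[i]] <<- b; ew[[i]] <<- w
  }
  pen <- function(v) if (cnt[[v]] == 1L) log(alpha) else 0
  end_ids <- integer(0)
  for (u in kmers) {
    for (j in 0:L) {
      for (st in states) {
        if (st == "D" && j == 0L) next
        a <- vid(vkey(u, j, st))
        mvs <- switch(st,
          M = list(c("MM", "M"), c("MI", "I"), c("MD", "D")),
          I = list(c("IM", "M"), c("II", "I")),
          D = list(c("DM", "M"), c("DD", "D")))
        for (mv in mvs) {
          tw <- tr[j + 1L, mv[1]]
          if (!is.finite(tw)) next
          if (mv[2] == "M" && j == L) {
            b <- vid(vkey(u, L, "E")); end_ids <- union(end_ids, b)
            add_edge(a, b, tw)
          } else if (mv[2] == "D") {
            if (j + 1L <= L) add_edge(a, vid(vkey(u, j + 1L, "D")), tw)
          } else {
            for (v in succ_map[[u]]) {
              cc <- substr(v, k, k)
              w <- tw + pen(v)
              j2 <- j
              if (mv[2] == "M") { j2 <- j + 1L; w <- w + h$em[j2, cc] }
              if (is.finite(w)) add_edge(a, vid(vkey(v, j2, mv[2])), w)
            }
          }
        }
      }
    }
  }
  from <- unlist(ef); to <- unlist(ej); w <- unlist(ew)
  d <- rep(-Inf, nv)
  d[vid(vkey(start_kmer, start_j, "M"))] <- 0
  for (pass in seq_len(max_pass)) {
    cand <- d[from] + w
    ok <- is.finite(cand)
    if (!any(ok)) break
    upd <- tapply(cand[ok], to[ok], max)
    idx <- as.integer(names(upd))
    better <- upd > d[idx] + 1e-12
    if (!any(better)) break
    d[idx[better]] <- upd[better]
  }
  list(best = if (length(end_ids)) max(d[end_ids]) else -Inf, value = d)
}

# Random small combined-graph instance for oracle-equivalence testing.
random_cag_instance <- function(max_kmers = 40L, max_L = 8L, k = 4L) {
  n_seq <- sample(2:4, 1L)
  seqs <- vapply(seq_len(n_seq), function(i) rand_nt_seq(sample(8:16, 1L)),
                 character(1))
  # duplicate one sequence sometimes so multiplicities vary
  if (stats::runif(1) < 0.5) seqs <- c(seqs, seqs[1])
  g <- build_graph(seqs, k, add_reverse_complement = FALSE)
  km <- graph_kmers(g)
  if (length(km) < 2L || length(km) > max_kmers) return(NULL)
  h <- random_hmm(sample(3:max_L, 1L))
  start_kmer <- sample(km, 1L)
  start_j <- sample(seq_len(h$L), 1L)
  list(g = g, h = h, kmers = km,
       counts = vapply(km, function(x) kmer_count(g, x), integer(1)),
       start_kmer = start_kmer, start_j = start_j)
}
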