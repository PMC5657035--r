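# Starting vertices (seeds) and bidirectional assembly.
#
# A seed is a k-mer that occurs in the reads AND exactly matches a length-k
# degapped window of an aligned reference sequence; the window's alignment
# columns anchor it to HMM match positions. Searches extend from the seed in
# both directions: forward under the model from the last character's
# position, and leftward under the reversed model from the mirrored position
# of the first character. The two spelled extensions and the seed are merged
# into one contig.

#' Find starting vertices from a reference alignment
#'
#' @param g a `kmer_graph`.
#' @param ref_alignment named character vector of aligned reference
#'   sequences (the same alignment, or one column-compatible with the one,
#'   that defined the model's match columns).
#' @param h a `profile_hmm`. If built by [hmm_from_alignment()] its recorded
#'   match columns are used; otherwise match columns are recomputed from
#'   `ref_alignment` with `match_rule` and must yield exactly `h$L` columns.
#' @param match_rule gap-fraction rule used when match columns must be
#'   recomputed (default 0.5).
#' @return data.frame with one row per distinct (k-mer, position) pair:
#'   `kmer`, `j` (match position of the window's last character), `j_first`
#'   (match position of its first character), `ref` (sequence name). Windows
#'   ending in an insert column anchor to the nearest preceding match
#'   column; windows lying entirely within insert regions are skipped.
#' @export
find_start_vertices <- function(g, ref_alignment, h, match_rule = 0.5) {
  ref_alignment <- toupper(as.character(ref_alignment))
  if (is.null(names(ref_alignment)))
    names(ref_alignment) <- paste0("ref", seq_along(ref_alignment))
  W <- unique(nchar(ref_alignment))
  if (length(W) != 1L) stop("ragged reference alignment")
  mat_cols <- h$match_columns
  if (is.null(mat_cols)) {
    m <- do.call(rbind, strsplit(chartr(".", "-", ref_alignment), "", fixed = TRUE))
    gap_frac <- colMeans(m == "-")
    mat_cols <- which(gap_frac < match_rule)
  }
  if (length(mat_cols) != h$L)
    stop("reference alignment yields ", length(mat_cols),
         " match columns but the model has length ", h$L)
  # match position of each alignment column's nearest preceding match column
  col2pos <- findInterval(seq_len(W), mat_cols)   # 0 when before first match col

  k <- g$k
  out <- list()
  for (nm in names(ref_alignment)) {
    chars <- strsplit(chartr(".", "-", ref_alignment[[nm]]), "", fixed = TRUE)[[1]]
    res_cols <- which(chars != "-")
    degapped <- paste(chars[res_cols], collapse = "")
    n <- length(res_cols)
    if (n < k) next
    for (s in seq_len(n - k + 1L)) {
      kmer <- substr(degapped, s, s + k - 1L)
      if (!has_kmer(g, kmer)) next
      j_last <- col2pos[res_cols[s + k - 1L]]
      j_first <- col2pos[res_cols[s]]
      if (j_last < 1L || j_first < 1L) next   # window inside a leading insert region
      out[[length(out) + 1L]] <- data.frame(
        kmer = kmer, j = j_last, j_first = j_first, ref = nm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(kmer = character(0), j = integer(0),
                      j_first = integer(0), ref = character(0)))
  seeds <- do.call(rbind, out)
  seeds <- seeds[!duplicated(seeds[, c("kmer", "j")]), , drop = FALSE]
  seeds <- seeds[order(seeds$j, seeds$kmer), , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}

#' Assemble one contig from a seed, extending in both directions
#'
#' Runs the forward search from the seed's last-character position under `h`
#' and the reverse search from the mirrored first-character position under
#' `h_rev`, then merges: contig = (reversed leftward extension) + seed k-mer
#' + rightward extension; contig score = forward score + reverse score.
#'
#' @param g a `kmer_graph`.
#' @param h,h_rev the model and its [reverse_hmm()].
#' @param seed one row of [find_start_vertices()] output (list or
#'   single-row data.frame with `kmer`, `j`, `j_first`).
#' @param cfg a [penalty_config()].
#' @param max_expansions per-direction A* expansion cap.
#' @param heur,heur_rev optional precomputed heuristics for `h` and `h_rev`.
#' @return a `gene_contig`: list with `sequence`, `score`, `fwd_score`,
#'   `rev_score`, `partial`, `seed_kmer`, `seed_j`, `length`; or `NULL` when
#'   both directions are partial and the merged length is below k (logged).
#' @export
bidirectional_assemble <- function(g, h, h_rev, seed, cfg = penalty_config(),
                                   max_expansions = 1e6,
                                   heur = NULL, heur_rev = NULL) {
  fwd <- astar_best_path(g, h, seed$kmer, seed$j, cfg,
                         max_expansions = max_expansions,
                         direction = "forward", heur = heur)
  jr <- h$L + 1L - seed$j_first
  rev <- astar_best_path(g, h_rev, seed$kmer, jr, cfg,
                         max_expansions = max_expansions,
                         direction = "reverse", heur = heur_rev)
  left <- paste(base::rev(rev$chars), collapse = "")
  sequence <- paste0(left, fwd$sequence)
  partial <- fwd$partial || rev$partial
  if (partial && nchar(sequence) < g$k) {
    message("discarding seed ", seed$kmer, ": both directions partial and contig shorter than k")
    return(NULL)
  }
  structure(
    list(sequence = sequence, score = fwd$score + rev$score,
         fwd_score = fwd$score, rev_score = rev$score,
         partial = partial, seed_kmer = seed$kmer, seed_j = seed$j,
         length = nchar(sequence)),
    class = "gene_contig"
  )
}

#' @export
print.gene_contig <- function(x, ...) {
  cat(sprintf("gene_contig: %d %s, score %.3f%s (seed %s @ %d)\n",
              x$length, "chars", x$score,
              if (x$partial) " [partial]" else "", x$seed_kmer, x$seed_j))
  invisible(x)
}

#' Search all seeds and collect contigs
#'
#' Seeds whose k-mer is already contained in an emitted contig are skipped
#' (they would re-derive the same path), and contigs whose k-mer set is a
#' subset of an already-emitted contig's are dropped — the standard seed
#' dereplication of HMM-guided assemblers.
#'
#' @param g a `kmer_graph`.
#' @param h the model; its reverse is built internally.
#' @param seeds data.frame from [find_start_vertices()].
#' @param cfg a [penalty_config()].
#' @param max_expansions per-direction A* cap.
#' @param max_seeds search at most this many seeds, sampled evenly across
#'   the seed list (default `Inf`).
#' @return list of `gene_contig` objects, ordered by seed identifier.
#' @export
search_seeds <- function(g, h, seeds, cfg = penalty_config(),
                         max_expansions = 1e6, max_seeds = Inf) {
  if (!nrow(seeds)) return(list())
  if (is.finite(max_seeds) && nrow(seeds) > max_seeds) {
    idx <- unique(round(seq(1L, nrow(seeds), length.out = max_seeds)))
    seeds <- seeds[idx, , drop = FALSE]
  }
  h_rev <- reverse_hmm(h)
  heur <- hmm_heuristic(h)
  heur_rev <- hmm_heuristic(h_rev)
  emitted <- new.env(hash = TRUE, parent = emptyenv())  # k-mers of emitted contigs
  contigs <- list()
  for (i in seq_len(nrow(seeds))) {
    sd <- seeds[i, ]
    if (exists(sd$kmer, envir = emitted, inherits = FALSE)) next
    ctg <- bidirectional_assemble(g, h, h_rev, sd, cfg, max_expansions,
                                  heur = heur, heur_rev = heur_rev)
    if (is.null(ctg)) next
    kk <- extract_kmers(ctg$sequence, g$k, g$alphabet)
    if (length(kk) && all(vapply(kk, exists, logical(1),
                                 envir = emitted, inherits = FALSE))) next
    for (x in unique(kk)) assign(x, TRUE, envir = emitted)
    contigs[[length(contigs) + 1L]] <- ctg
  }
  contigs
}
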