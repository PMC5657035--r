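# Iterative multi-k de Bruijn graph construction.
#
# G(R, k1) = DBG(R, k1); C(ki) = the de novo contigs (cleaned unitigs) of
# G(R, ki); G(R, k_{i+1}) = DBG(R ∪ C(ki), k_{i+1}). Contigs assembled at a
# smaller k supply k-mers that the reads alone cannot at a larger k, so
# coverage gaps bridged at small k stay connected at large k. Intermediate
# contigs are always plain unitigs, never HMM-guided products.

#' Multi-k plan
#'
#' @param k_list strictly increasing integer k-mer sizes (default
#'   `c(30, 36, 45)`, the default iterative mode).
#' @param max_tip_len,max_bubble_len,len_tol,max_rounds per-k cleaning
#'   parameters, each either a single value applied at every k or `NULL` for
#'   the k-dependent defaults of [clean_graph()].
#' @return a `k_plan` list.
#' @export
k_plan <- function(k_list = c(30L, 36L, 45L), max_tip_len = NULL,
                   max_bubble_len = NULL, len_tol = 3L, max_rounds = 10L) {
  k_list <- as.integer(k_list)
  if (!length(k_list) || any(is.na(k_list)) || any(k_list < 2L))
    stop("k_list must be non-empty integers >= 2")
  if (is.unsorted(k_list, strictly = TRUE))
    stop("k_list must be strictly increasing")
  structure(list(k_list = k_list, max_tip_len = max_tip_len,
                 max_bubble_len = max_bubble_len, len_tol = len_tol,
                 max_rounds = max_rounds),
            class = "k_plan")
}

plan_clean <- function(g, plan) {
  clean_graph(g,
              max_tip_len = plan$max_tip_len %||% (2L * g$k),
              max_bubble_len = plan$max_bubble_len %||% (3L * g$k),
              len_tol = plan$len_tol, max_rounds = plan$max_rounds)
}

#' Build the iterative de Bruijn graph over a k-mer plan
#'
#' At each k below the largest, the graph is built from the reads plus the
#' contigs carried from the previous step, cleaned, and its unitigs are
#' spelled and carried forward. The final graph (at the largest k) is
#' cleaned by default before HMM-guided search. K-mers of the final graph
#' that are supported only by carried contigs — absent from the reads at the
#' final k — are marked in the graph's `contig_only` set so the low-coverage
#' penalty can optionally exempt them.
#'
#' @param reads character vector of reads.
#' @param plan a [k_plan()] (a bare integer vector is accepted).
#' @param alphabet `"nt"` or `"aa"`.
#' @param add_reverse_complement forwarded to [build_graph()].
#' @param clean_intermediate clean each intermediate graph before spelling
#'   its contigs (default `TRUE`).
#' @param final_clean clean the final graph too (default `TRUE`).
#' @param keep_intermediates optional directory; when set, the carried
#'   contigs of each intermediate k are written there as FASTA.
#' @return an `iteration_state`: list with `current_k`, `graph` (the final
#'   `kmer_graph`), `carried_contigs` (the C(k_i) of the last intermediate
#'   step) and `k_list`.
#' @export
iterate_graph <- function(reads, plan, alphabet = "nt",
                          add_reverse_complement = (alphabet == "nt"),
                          clean_intermediate = TRUE, final_clean = TRUE,
                          keep_intermediates = NULL) {
  if (!inherits(plan, "k_plan")) plan <- k_plan(plan)
  if (!length(reads)) stop("no input reads")
  ks <- plan$k_list
  max_len <- max(nchar(reads))
  carried <- character(0)
  g <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k > max_len && (!length(carried) || k > max(nchar(carried))))
      stop("k = ", k, " exceeds every read and every carried contig; ",
           "no graph can be built at this k")
    input <- c(reads, carried)
    g <- build_graph(input, k, alphabet, add_reverse_complement)
    if (i < length(ks)) {
      if (clean_intermediate) g <- plan_clean(g, plan)
      carried <- spell_unitigs(g)$sequence
      if (!is.null(keep_intermediates) && length(carried)) {
        write_fasta(stats::setNames(carried, paste0("k", k, "_contig", seq_along(carried))),
                    file.path(keep_intermediates, sprintf("contigs_k%d.fasta", k)),
                    alphabet)
      }
      g <- NULL   # at most one graph alive at a time
    }
  }
  k_final <- ks[length(ks)]
  # mark k-mers unsupported by the reads alone at the final k
  if (length(carried)) {
    read_kmers <- unique(extract_kmers(
      if (add_reverse_complement) c(reads, revcomp(reads)) else reads,
      k_final, alphabet))
    in_reads <- new.env(hash = TRUE, parent = emptyenv())
    for (x in read_kmers) assign(x, TRUE, envir = in_reads)
    for (x in graph_kmers(g)) {
      if (!exists(x, envir = in_reads, inherits = FALSE))
        assign(x, TRUE, envir = g$contig_only)
    }
  }
  if (final_clean) g <- plan_clean(g, plan)
  structure(list(current_k = k_final, graph = g,
                 carried_contigs = carried, k_list = ks),
            class = "iteration_state")
}

#' @export
print.iteration_state <- function(x, ...) {
  cat(sprintf("iteration_state: k-list [%s], final graph at k=%d with %d k-mers\n",
              paste(x$k_list, collapse = ","), x$current_k, n_kmers(x$graph)))
  invisible(x)
}
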