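# End-to-end driver: iterative graph build -> seed finding -> HMM-guided
# bidirectional search -> post-processing. All outputs are written
# atomically and the fully resolved configuration is serialized into the
# output directory before any computation, as the reproducibility record.

#' Run the full gene-targeted assembly pipeline
#'
#' @param reads path to a FASTA/FASTQ file (gzip ok) or a character vector
#'   of read sequences.
#' @param refs path to an aligned FASTA of reference sequences, or a named
#'   character vector. Used to seed starting k-mers and, when `hmm` is
#'   `NULL`, to build the model.
#' @param out_dir output directory.
#' @param hmm optional path to a HMMER3 ASCII model; built from `refs` by
#'   [hmm_from_alignment()] when `NULL`.
#' @param k_list increasing k-mer sizes (default `c(30, 36, 45)`).
#' @param alpha low-coverage penalty (default 0.5); see [penalty_config()].
#' @param exempt_contig_kmers see [penalty_config()].
#' @param alphabet `"nt"` or `"aa"`; must match the model's alphabet.
#' @param min_nt,min_aa post-processing length thresholds (450 / 150).
#' @param cluster_threshold clustering identity (default 0.99).
#' @param max_expansions per-direction A* cap (default 1e6).
#' @param max_seeds cap on seeds searched (default `Inf`).
#' @param hmm_pseudocount Laplace pseudocount used when the model is built
#'   from `refs` (default 0.1). Small reference panels need a small
#'   pseudocount: with add-one smoothing on a handful of sequences, match
#'   emissions flatten toward 1/4 while unobserved delete-delete transitions
#'   sit at 1/2, and an all-delete path can outscore faithful matching.
#' @param final_clean clean the final graph before search (default `TRUE`).
#' @param keep_intermediates optional directory for per-k contig FASTA.
#' @return (invisibly) list with `contigs` (raw `gene_contig` list),
#'   `clusters` (post-processing table), `seeds`, `graph`, and the paths of
#'   the files written: `contigs.fasta` (raw), `representatives.fasta`,
#'   `clusters.tsv`, `seed_report.tsv`, `config.yaml`.
#' @export
run_pipeline <- function(reads, refs, out_dir, hmm = NULL,
                         k_list = c(30L, 36L, 45L), alpha = 0.5,
                         exempt_contig_kmers = FALSE, alphabet = "nt",
                         min_nt = 450L, min_aa = 150L,
                         cluster_threshold = 0.99, max_expansions = 1e6,
                         max_seeds = Inf, final_clean = TRUE,
                         hmm_pseudocount = 0.1, keep_intermediates = NULL) {
  alphabet <- match.arg(alphabet, c("nt", "aa"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(
    reads = if (is.character(reads) && length(reads) == 1L && file.exists(reads))
      normalizePath(reads) else sprintf("<%d in-memory sequences>", length(reads)),
    refs = if (is.character(refs) && length(refs) == 1L && file.exists(refs))
      normalizePath(refs) else sprintf("<%d in-memory sequences>", length(refs)),
    hmm = if (is.null(hmm)) "<built from reference alignment>" else normalizePath(hmm),
    k_list = as.integer(k_list), alpha = alpha,
    exempt_contig_kmers = exempt_contig_kmers, alphabet = alphabet,
    min_nt = min_nt, min_aa = min_aa, cluster_threshold = cluster_threshold,
    max_expansions = max_expansions, max_seeds = max_seeds,
    final_clean = final_clean, hmm_pseudocount = hmm_pseudocount,
    max_tip_len = "2k", max_bubble_len = "3k", bubble_len_tol = 3,
    clean_max_rounds = 10)
  atomic_write(file.path(out_dir, "config.yaml"),
               function(tmp) yaml::write_yaml(config, tmp))

  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_seqs(reads, alphabet)
  if (is.character(refs) && length(refs) == 1L && file.exists(refs))
    refs <- read_seqs(refs, alphabet)
  if (!length(reads)) stop("no reads")

  h <- if (is.null(hmm))
    hmm_from_alignment(refs, alphabet = alphabet, pseudocount = hmm_pseudocount)
  else read_hmmer3(hmm)
  if (h$alphabet != alphabet)
    stop("alphabet mismatch: model is ", h$alphabet, " but pipeline is ", alphabet)

  message("building iterative de Bruijn graph, k = ",
          paste(k_list, collapse = ","))
  state <- iterate_graph(reads, k_plan(k_list), alphabet,
                         final_clean = final_clean,
                         keep_intermediates = keep_intermediates)
  g <- state$graph
  message("final graph: ", n_kmers(g), " k-mers at k = ", g$k)

  seeds <- find_start_vertices(g, refs, h)
  cfg <- penalty_config(alpha, exempt_contig_kmers)
  raw_path <- file.path(out_dir, "contigs.fasta")
  if (!nrow(seeds)) {
    warning("no seeds: no read k-mer matches the reference alignment")
    write_fasta(character(0), raw_path, alphabet)
    write_fasta(character(0), file.path(out_dir, "representatives.fasta"), alphabet)
    empty <- data.frame()
    return(invisible(list(contigs = list(), clusters = empty, seeds = seeds,
                          graph = g, out_dir = out_dir)))
  }
  message(nrow(seeds), " seeds; searching (alpha = ", alpha, ")")
  contigs <- search_seeds(g, h, seeds, cfg, max_expansions, max_seeds)
  message(length(contigs), " raw contigs")

  if (length(contigs)) {
    nm <- sprintf("contig%05d score=%.4f seed=%s partial=%s",
                  seq_along(contigs),
                  vapply(contigs, `[[`, numeric(1), "score"),
                  vapply(contigs, `[[`, character(1), "seed_kmer"),
                  tolower(vapply(contigs, `[[`, logical(1), "partial")))
    write_fasta(stats::setNames(contig_seqs(contigs), nm), raw_path, alphabet)
    seed_report <- data.frame(
      seed_kmer = vapply(contigs, `[[`, character(1), "seed_kmer"),
      hmm_position = vapply(contigs, `[[`, integer(1), "seed_j"),
      fwd_score = vapply(contigs, `[[`, numeric(1), "fwd_score"),
      rev_score = vapply(contigs, `[[`, numeric(1), "rev_score"),
      contig_length = vapply(contigs, `[[`, integer(1), "length"))
    write_tsv_atomic(seed_report, file.path(out_dir, "seed_report.tsv"))
  } else {
    write_fasta(character(0), raw_path, alphabet)
  }

  clusters <- postprocess_contigs(contigs, min_nt, min_aa,
                                  cluster_threshold, alphabet)
  write_tsv_atomic(clusters[, setdiff(names(clusters), "sequence")],
                   file.path(out_dir, "clusters.tsv"))
  reps <- clusters[clusters$representative, , drop = FALSE]
  write_fasta(stats::setNames(reps$sequence,
                              sprintf("cluster%03d len=%d", reps$cluster_id, reps$length)),
              file.path(out_dir, "representatives.fasta"), alphabet)
  message(nrow(reps), " representative contigs after post-processing")
  invisible(list(contigs = contigs, clusters = clusters, seeds = seeds,
                 graph = g, out_dir = out_dir))
}
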