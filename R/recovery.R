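# Recovery metrics against simulated truth: per-gene recovered fraction,
# mismatches per 100 kbp of aligned contig, and a misassembly count. A
# desk-scale analogue of reference-based assembly evaluation.

nt_submat <- function() Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

# Best local alignment of a contig against a gene, trying both strands.
best_local_aln <- function(contig, gene) {
  mat <- nt_submat()
  a_f <- Biostrings::pairwiseAlignment(Biostrings::DNAString(contig),
                                       Biostrings::DNAString(gene),
                                       type = "local", substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  rc <- revcomp(contig)
  a_r <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rc),
                                       Biostrings::DNAString(gene),
                                       type = "local", substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  if (Biostrings::score(a_f) >= Biostrings::score(a_r))
    list(aln = a_f, strand = "+", query = contig)
  else list(aln = a_r, strand = "-", query = rc)
}

aln_stats <- function(a) {
  aln <- a$aln
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       q_start = Biostrings::start(p), q_end = Biostrings::end(p),
       s_start = Biostrings::start(s), s_end = Biostrings::end(s),
       nmatch = Biostrings::nmatch(aln), nmismatch = Biostrings::nmismatch(aln),
       width = Biostrings::nchar(aln))
}

#' Recovery report of contigs against true gene sequences
#'
#' Aligns each contig locally to every true gene (both strands) and reports
#' sensitivity and accuracy:
#' * gene fraction — per gene, the percentage of its length covered by the
#'   best local alignments of the contigs assigned to it;
#' * mismatches per 100 kbp — substitutions in those alignments per 100,000
#'   aligned contig bases;
#' * misassemblies — contigs whose alignment splits across two genes, or
#'   jumps more than `breakpoint` bases within one gene: after the best
#'   local alignment, any unaligned contig flank of at least `min_flank`
#'   bases is realigned, and a flank whose own best hit is a different gene
#'   (or a displaced region of the same gene) marks the contig misassembled.
#'
#' @param contigs character vector of contig sequences (or `gene_contig`
#'   list).
#' @param genes named character vector of true gene sequences.
#' @param min_flank minimum unaligned flank length to test for chimerism
#'   (default 30).
#' @param breakpoint within-gene jump, in bases, that counts as a
#'   misassembly (default 1000).
#' @return list with `per_gene` (data.frame: gene, length, covered,
#'   fraction in percent), `mismatches_per_100kbp`, `aligned_bases`,
#'   `mismatches`, `misassemblies`, `n_contigs`.
#' @export
recovery_report <- function(contigs, genes, min_flank = 30L, breakpoint = 1000L) {
  seqs <- contig_seqs(contigs)
  covered <- lapply(genes, function(g) logical(nchar(g)))
  mismatches <- 0; aligned <- 0; misassemblies <- 0L
  for (ctg in seqs) {
    if (!nchar(ctg)) next
    alns <- lapply(genes, best_local_aln, contig = ctg)
    scores <- vapply(alns, function(a) Biostrings::score(a$aln), numeric(1))
    gi <- which.max(scores)
    st <- aln_stats(alns[[gi]])
    covered[[gi]][st$s_start:st$s_end] <- TRUE
    mismatches <- mismatches + st$nmismatch
    aligned <- aligned + (st$q_end - st$q_start + 1L)
    # chimera check on unaligned flanks
    mis <- FALSE
    for (flank in list(c(1L, st$q_start - 1L),
                       c(st$q_end + 1L, nchar(ctg)))) {
      flen <- flank[2] - flank[1] + 1L
      if (flen < min_flank) next
      fseq <- substr(alns[[gi]]$query, flank[1], flank[2])
      falns <- lapply(genes, best_local_aln, contig = fseq)
      fscores <- vapply(falns, function(a) Biostrings::score(a$aln), numeric(1))
      fgi <- which.max(fscores)
      fst <- aln_stats(falns[[fgi]])
      if (fst$nmatch < 0.9 * flen) next   # flank does not align anywhere: not a chimera call
      if (fgi != gi) { mis <- TRUE; break }
      jump <- if (flank[1] == 1L) abs(st$s_start - fst$s_end) else abs(fst$s_start - st$s_end)
      if (jump > breakpoint) { mis <- TRUE; break }
    }
    if (mis) misassemblies <- misassemblies + 1L
  }
  per_gene <- data.frame(
    gene = names(genes),
    length = nchar(genes),
    covered = vapply(covered, sum, integer(1)),
    stringsAsFactors = FALSE)
  per_gene$fraction <- 100 * per_gene$covered / per_gene$length
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       mismatches_per_100kbp = if (aligned > 0) mismatches / aligned * 1e5 else 0,
       aligned_bases = aligned, mismatches = mismatches,
       misassemblies = misassemblies, n_contigs = length(seqs))
}
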