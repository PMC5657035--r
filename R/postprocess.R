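# Contig post-processing: length filter and greedy identity clustering.
#
# Raw contigs are filtered at a minimum length (450 nt or 150 aa by
# default), then clustered greedily longest-first at a fractional identity
# threshold (0.99 by default), keeping the longest member of each cluster —
# the founder — as its representative.

#' Filter contigs by minimum length
#'
#' @param contigs list of `gene_contig` objects, or a character vector of
#'   sequences.
#' @param min_nt minimum length for nucleotide contigs (default 450).
#' @param min_aa minimum length for amino-acid contigs (default 150).
#' @param space `"nt"` or `"aa"` — which threshold applies.
#' @return the retained contigs, input order preserved. The boundary is
#'   inclusive: a 450-nt contig passes a 450-nt threshold.
#' @export
length_filter <- function(contigs, min_nt = 450L, min_aa = 150L, space = "nt") {
  stopifnot(min_nt > 0L, min_aa > 0L)
  space <- match.arg(space, c("nt", "aa"))
  min_len <- if (space == "nt") min_nt else min_aa
  lens <- contig_lengths(contigs)
  contigs[lens >= min_len]
}

contig_seqs <- function(contigs) {
  if (is.character(contigs)) contigs
  else vapply(contigs, function(x) x$sequence, character(1))
}

contig_lengths <- function(contigs) nchar(contig_seqs(contigs))

# Fractional identity of a global alignment with free end gaps, over the
# aligned span (which, with overlap alignment of a shorter sequence against
# a longer one, is the shorter sequence's aligned length).
pair_identity <- function(a, b, space) {
  if (space == "nt") {
    pa <- Biostrings::DNAString(a); pb <- Biostrings::DNAString(b)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  } else {
    pa <- Biostrings::AAString(a); pb <- Biostrings::AAString(b)
    chars <- alphabet_chars("aa")
    mat <- matrix(-1, length(chars), length(chars), dimnames = list(chars, chars))
    diag(mat) <- 1
  }
  aln <- Biostrings::pairwiseAlignment(pa, pb, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0L) return(0)
  Biostrings::nmatch(aln) / cols
}

#' Cluster contigs at an identity threshold, longest first
#'
#' Greedy clustering: contigs are sorted by decreasing length (ties by
#' sequence, for determinism); each contig joins the first existing cluster
#' whose representative it matches at `>= identity_threshold` fractional
#' identity (global alignment with free end gaps, identity counted over the
#' aligned columns of the shorter sequence); otherwise it founds a new
#' cluster. The representative of a cluster is its founder — necessarily
#' its longest member.
#'
#' @param contigs list of `gene_contig` objects or character vector.
#' @param identity_threshold fraction in (0, 1] (default 0.99).
#' @param space `"nt"` or `"aa"`.
#' @return a data.frame with one row per input contig (input order):
#'   `contig_id`, `cluster_id`, `representative` (logical), `length`,
#'   `score` (NA for bare sequences), `sequence`.
#' @export
cluster_identity <- function(contigs, identity_threshold = 0.99, space = "nt") {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  space <- match.arg(space, c("nt", "aa"))
  seqs <- contig_seqs(contigs)
  scores <- if (is.character(contigs)) rep(NA_real_, length(contigs))
            else vapply(contigs, function(x) x$score %||% NA_real_, numeric(1))
  n <- length(seqs)
  out <- data.frame(contig_id = seq_len(n),
                    cluster_id = rep(NA_integer_, n),
                    representative = rep(FALSE, n), length = nchar(seqs),
                    score = scores, sequence = seqs, stringsAsFactors = FALSE)
  if (!n) return(out)
  ord <- order(-out$length, out$sequence)
  reps <- integer(0)   # contig_id of each cluster's representative
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pair_identity(seqs[i], seqs[reps[ci]], space) >= identity_threshold) {
        out$cluster_id[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      out$cluster_id[i] <- length(reps)
      out$representative[i] <- TRUE
    }
  }
  out
}

#' Full post-processing: length filter then clustering
#'
#' @param contigs list of `gene_contig` objects or character vector.
#' @param min_nt,min_aa see [length_filter()].
#' @param identity_threshold,space see [cluster_identity()].
#' @return the [cluster_identity()] table of the retained contigs.
#' @export
postprocess_contigs <- function(contigs, min_nt = 450L, min_aa = 150L,
                                identity_threshold = 0.99, space = "nt") {
  kept <- length_filter(contigs, min_nt, min_aa, space)
  cluster_identity(kept, identity_threshold, space)
}
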