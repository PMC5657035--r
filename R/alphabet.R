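#' @keywords internal
"_PACKAGE"

# Alphabets are identified by short ids used throughout the package:
# "nt" (A,C,G,T) and "aa" (the 20 standard amino acids).

GT_ALPHABETS <- list(
  nt = c("A", "C", "G", "T"),
  aa = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

#' Alphabet characters for an alphabet id
#'
#' @param alphabet `"nt"` or `"aa"`.
#' @return Character vector of single letters.
#' @keywords internal
alphabet_chars <- function(alphabet) {
  alphabet <- match.arg(alphabet, names(GT_ALPHABETS))
  GT_ALPHABETS[[alphabet]]
}

#' Reverse complement of nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the file contents (leading `>` vs `@`);
#' gzip-compressed files are handled transparently by Biostrings.
#'
#' @param path file path.
#' @param alphabet `"nt"` or `"aa"`; amino-acid input must be FASTA.
#' @return named character vector of sequences (uppercased).
#' @export
read_seqs <- function(path, alphabet = "nt") {
  alphabet <- match.arg(alphabet, names(GT_ALPHABETS))
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  fmt <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  ss <- if (alphabet == "nt") {
    Biostrings::readDNAStringSet(path, format = fmt)
  } else {
    Biostrings::readAAStringSet(path, format = fmt)
  }
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' Writes atomically (temp file in the target directory, then rename).
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param alphabet `"nt"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = "nt") {
  alphabet <- match.arg(alphabet, names(GT_ALPHABETS))
  if (length(seqs) && is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  ss <- if (alphabet == "nt") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  atomic_write(path, function(tmp) Biostrings::writeXStringSet(ss, tmp))
}

# Write `path` via a temp file in the same directory, then rename, so an
# interrupted run never leaves a truncated file under the final name.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), pattern = ".partial_")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

#' Write a TSV table atomically
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @keywords internal
write_tsv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
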