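# HMMER3 ASCII model input/output.
#
# Only the core of the format is handled: the HMMER3 header, NAME/LENG/ALPH
# header lines, the HMM symbol block, the optional COMPO line, the node-0
# insert-emission and transition lines, and one three-line block per model
# position. Scores in the file are negated natural logs of probabilities;
# '*' denotes probability zero. Annotation columns after the match emissions
# (MAP/CONS/RF/MM/CS) and E-value calibration statistics are ignored.

hmmer_alph <- function(alph) {
  switch(toupper(alph),
         DNA = "nt", RNA = "nt", NUCLEOTIDE = "nt",
         AMINO = "aa", AA = "aa",
         stop("unsupported HMMER alphabet: ", alph))
}

parse_score <- function(tok, lineno) {
  out <- numeric(length(tok))
  star <- tok == "*"
  out[star] <- -Inf
  vals <- suppressWarnings(as.numeric(tok[!star]))
  if (anyNA(vals))
    stop("line ", lineno, ": unparseable score field '",
         tok[!star][which(is.na(vals))[1]], "'")
  out[!star] <- -vals   # file stores -ln p
  out
}

#' Read a profile HMM from a HMMER3 ASCII file
#'
#' @param path path to a `.hmm` file (plain text).
#' @return a `profile_hmm`. Negated-log score fields are converted to
#'   natural-log probabilities; `*` becomes `-Inf`. The model length is taken
#'   from the `LENG` header and checked against the node blocks.
#' @export
read_hmmer3 <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    stop("line 1: not a HMMER3 ASCII file")
  hdr <- function(key) {
    i <- grep(paste0("^", key, "\\s"), lines)
    if (!length(i)) stop("missing required header line: ", key)
    sub(paste0("^", key, "\\s+"), "", lines[i[1]])
  }
  name <- hdr("NAME")
  L <- as.integer(hdr("LENG"))
  if (is.na(L) || L < 1L) stop("invalid LENG header")
  alphabet <- hmmer_alph(hdr("ALPH"))
  chars <- alphabet_chars(alphabet)

  ih <- grep("^HMM\\s", lines)
  if (!length(ih)) stop("missing HMM symbol line")
  sym <- strsplit(trimws(lines[ih[1]]), "\\s+")[[1]][-1]
  if (!identical(sym, chars))
    stop("line ", ih[1], ": symbol order ", paste(sym, collapse = " "),
         " does not match the ", alphabet, " alphabet")
  i <- ih[1] + 2L   # skip the transition-name line
  if (grepl("^\\s*COMPO\\s", lines[i])) i <- i + 1L

  K <- length(chars)
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  # node 0: insert emissions, then transitions
  ins_em <- matrix(NA_real_, nrow = L + 1L, ncol = K, dimnames = list(NULL, chars))
  trans <- matrix(NA_real_, nrow = L + 1L, ncol = 7L, dimnames = list(NULL, TRANS_NAMES))
  em <- matrix(NA_real_, nrow = L, ncol = K, dimnames = list(NULL, chars))

  tk <- toks(i)
  if (length(tk) < K) stop("line ", i, ": expected ", K, " insert-emission fields")
  ins_em[1L, ] <- parse_score(tk[1:K], i)
  i <- i + 1L
  tk <- toks(i)
  if (length(tk) < 7L) stop("line ", i, ": expected 7 transition fields")
  trans[1L, ] <- parse_score(tk[1:7], i)
  i <- i + 1L

  for (node in seq_len(L)) {
    tk <- toks(i)
    if (length(tk) < K + 1L || suppressWarnings(as.integer(tk[1])) != node)
      stop("line ", i, ": expected match-emission line for node ", node)
    em[node, ] <- parse_score(tk[2:(K + 1L)], i)
    i <- i + 1L
    tk <- toks(i)
    if (length(tk) < K) stop("line ", i, ": expected insert-emission line")
    ins_em[node + 1L, ] <- parse_score(tk[1:K], i)
    i <- i + 1L
    tk <- toks(i)
    if (length(tk) < 7L) stop("line ", i, ": expected transition line")
    trans[node + 1L, ] <- parse_score(tk[1:7], i)
    i <- i + 1L
  }
  if (!grepl("^//", lines[i])) stop("line ", i, ": expected terminating //")
  new_profile_hmm(L, alphabet, trans, em, ins_em = ins_em, name = name,
                  tol = 1e-4)
}

fmt_score <- function(x) ifelse(is.infinite(x), "*", sprintf("%.7f", -x))

#' Write a profile HMM as HMMER3 ASCII
#'
#' Writes the subset of the format that [read_hmmer3()] understands
#' (no COMPO line, no annotation columns, no calibration statistics), so a
#' model round-trips through write/read.
#'
#' @param h a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(h, path) {
  alph <- if (h$alphabet == "nt") "DNA" else "amino"
  out <- c(
    "HMMER3/f [gtasm]",
    paste0("NAME  ", h$name),
    paste0("LENG  ", h$L),
    paste0("ALPH  ", alph),
    paste0("HMM  ", paste(h$chars, collapse = "  ")),
    paste0("     ", paste(c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d"),
                          collapse = "  ")),
    paste0("      ", paste(fmt_score(h$ins_em[1L, ]), collapse = "  ")),
    paste0("      ", paste(fmt_score(h$trans[1L, ]), collapse = "  "))
  )
  for (node in seq_len(h$L)) {
    out <- c(out,
      paste0("  ", node, "  ", paste(fmt_score(h$em[node, ]), collapse = "  ")),
      paste0("      ", paste(fmt_score(h$ins_em[node + 1L, ]), collapse = "  ")),
      paste0("      ", paste(fmt_score(h$trans[node + 1L, ]), collapse = "  ")))
  }
  out <- c(out, "//")
  atomic_write(path, function(tmp) writeLines(out, tmp))
}
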