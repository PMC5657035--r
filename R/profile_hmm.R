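# Profile hidden Markov model of a gene family.
#
# A model of length L has match/insert/delete states per alignment column,
# a begin node (treated as match position 0) and an end node. Transitions are
# stored as an (L+1) x 7 matrix of natural-log probabilities; row j holds the
# transitions out of position j: M->M, M->I, M->D, I->M, I->I, D->M, D->D.
# Row 0 is the begin node (no delete state); in row L the M->M, I->M and D->M
# entries are the transitions into the end node. Match emissions are an
# L x |alphabet| matrix of natural-log probabilities. Insert emissions are
# stored for file round-trips but are never used in scoring: path weights
# give insert and delete edges a transition term only.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

new_profile_hmm <- function(L, alphabet, trans, em, ins_em = NULL,
                            match_columns = NULL, name = "model", tol = 1e-6) {
  chars <- alphabet_chars(alphabet)
  if (is.null(ins_em)) {
    ins_em <- matrix(log(1 / length(chars)), nrow = L + 1L, ncol = length(chars))
    colnames(ins_em) <- chars
  }
  h <- structure(
    list(L = as.integer(L), alphabet = alphabet, chars = chars,
         trans = trans, em = em, ins_em = ins_em,
         match_columns = match_columns, name = name),
    class = "profile_hmm"
  )
  validate_hmm(h, tol = tol)
  h
}

# Legal outgoing transition sets per state at position j of a length-L model.
legal_trans <- function(j, state, L) {
  switch(state,
         M = if (j < L) c("MM", "MI", "MD") else c("MM", "MI"),
         I = c("IM", "II"),
         D = if (j == 0L) character(0) else if (j < L) c("DM", "DD") else "DM")
}

validate_hmm <- function(h, tol = 1e-6) {
  stopifnot(h$L >= 1L, nrow(h$trans) == h$L + 1L, nrow(h$em) == h$L)
  for (j in 0:h$L) {
    for (st in c("M", "I", "D")) {
      cols <- legal_trans(j, st, h$L)
      if (!length(cols)) next
      s <- sum(exp(h$trans[j + 1L, cols]))
      if (abs(s - 1) > tol)
        stop(sprintf("transitions out of %s_%d sum to %.8f, not 1", st, j, s))
      illegal <- setdiff(TRANS_NAMES[substr(TRANS_NAMES, 1, 1) ==
                                       c(M = "M", I = "I", D = "D")[st]], cols)
      if (any(is.finite(h$trans[j + 1L, illegal])))
        stop(sprintf("illegal transition out of %s_%d has positive probability", st, j))
    }
  }
  for (j in seq_len(h$L)) {
    s <- sum(exp(h$em[j, ]))
    if (abs(s - 1) > tol)
      stop(sprintf("match emissions at position %d sum to %.8f, not 1", j, s))
  }
  invisible(h)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': length %d, alphabet %s\n",
              x$name, x$L, x$alphabet))
  invisible(x)
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose gap fraction is below `match_rule` become match columns
#' (a gap fraction exactly at the boundary makes an insert column). State
#' paths are read off each sequence in the standard way — a residue in a
#' match column visits the match state, a gap there the delete state, a
#' residue in an insert column the insert state of the preceding match
#' position — and transition/emission probabilities are Laplace-smoothed
#' relative frequencies. A state never visited gets a uniform distribution
#' over its legal targets.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   lengths; `-` or `.` are gaps).
#' @param alphabet `"nt"`, `"aa"`, or `"auto"` (detected from the residues).
#' @param match_rule gap-fraction threshold below which a column is a match
#'   column (default 0.5).
#' @param pseudocount Laplace pseudocount for transitions and emissions
#'   (default 1).
#' @param name model name.
#' @return a `profile_hmm`. The alignment columns chosen as match columns are
#'   recorded in `$match_columns` so reference windows can later be anchored
#'   to model positions.
#' @export
hmm_from_alignment <- function(alignment, alphabet = "auto", match_rule = 0.5,
                               pseudocount = 1, name = "model") {
  alignment <- toupper(as.character(alignment))
  if (length(alignment) < 2L) stop("need at least 2 aligned sequences")
  W <- unique(nchar(alignment))
  if (length(W) != 1L) stop("ragged alignment: sequences have unequal aligned lengths")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  mat[mat == "."] <- "-"
  residues <- setdiff(unique(as.vector(mat)), "-")
  if (identical(alphabet, "auto"))
    alphabet <- if (all(residues %in% GT_ALPHABETS$nt)) "nt" else "aa"
  alphabet <- match.arg(alphabet, names(GT_ALPHABETS))
  chars <- alphabet_chars(alphabet)
  if (!all(residues %in% chars))
    stop("alignment contains characters outside the ", alphabet, " alphabet: ",
         paste(setdiff(residues, chars), collapse = ","))

  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < match_rule)
  L <- length(match_cols)
  if (L == 0L) stop("no match columns under the gap-fraction rule")

  tcount <- matrix(0, nrow = L + 1L, ncol = 7L, dimnames = list(NULL, TRANS_NAMES))
  ecount <- matrix(0, nrow = L, ncol = length(chars), dimnames = list(NULL, chars))
  is_match <- seq_len(W) %in% match_cols

  for (r in seq_len(nrow(mat))) {
    prev <- c("M", 0L)   # begin
    m <- 0L
    for (col in seq_len(W)) {
      ch <- mat[r, col]
      if (is_match[col]) {
        m <- m + 1L
        st <- if (ch == "-") "D" else "M"
        if (st == "M") ecount[m, ch] <- ecount[m, ch] + 1
        tcount <- add_trans(tcount, prev, c(st, m))
        prev <- c(st, m)
      } else if (ch != "-") {
        tcount <- add_trans(tcount, prev, c("I", m))
        prev <- c("I", m)
      }
    }
    # transition into end (recorded as *->M out of position L)
    tcount <- add_trans(tcount, prev, c("M", L + 1L))
  }

  trans <- matrix(-Inf, nrow = L + 1L, ncol = 7L, dimnames = list(NULL, TRANS_NAMES))
  for (j in 0:L) {
    for (st in c("M", "I", "D")) {
      cols <- legal_trans(j, st, L)
      if (!length(cols)) next
      n <- tcount[j + 1L, cols]
      tot <- sum(n) + pseudocount * length(cols)
      trans[j + 1L, cols] <- if (tot > 0) log((n + pseudocount) / tot)
                             else log(rep(1 / length(cols), length(cols)))
    }
  }
  em <- matrix(NA_real_, nrow = L, ncol = length(chars), dimnames = list(NULL, chars))
  for (j in seq_len(L)) {
    n <- ecount[j, ]
    tot <- sum(n) + pseudocount * length(chars)
    em[j, ] <- if (tot > 0) log((n + pseudocount) / tot)
               else log(rep(1 / length(chars), length(chars)))
  }
  new_profile_hmm(L, alphabet, trans, em, match_columns = match_cols, name = name)
}

# Accumulate one observed transition between states coded as c(type, position).
add_trans <- function(tcount, from, to) {
  jf <- as.integer(from[2]); jt <- as.integer(to[2])
  type <- paste0(from[1], to[1])
  key <- if (to[1] == "I") {
    if (from[1] == "M") "MI" else if (from[1] == "I") "II" else NA
  } else type   # M->M, M->D, I->M, D->M, D->D (and *->end coded as *->M)
  # D->I and I->D are outside the 7-transition topology; such (rare)
  # observations are dropped, as in plan-7 model building
  if (is.na(key) || !key %in% TRANS_NAMES) return(tcount)
  tcount[jf + 1L, key] <- tcount[jf + 1L, key] + 1
  tcount
}

#' Reverse a profile HMM
#'
#' Produces the model used to guide leftward extension: position j of the
#' reversed model carries the match-emission distribution of position
#' L + 1 - j of the original, and every transition edge is reversed. The
#' mass attributed to a reversed edge is the expected number of times the
#' original edge is traversed in a generative pass from begin to end (state
#' visit frequency times conditional transition probability); outgoing mass
#' is then renormalised per state and begin/end swap roles. Weighting by
#' traversal frequency rather than by raw conditional probability keeps
#' transitions out of rarely (or never) visited states from distorting the
#' reversed model, and makes the reversal exact on branch-free (all-match)
#' models: the reversed model generates exactly the reversed sequences of
#' the original, with identical scores.
#'
#' @param h a `profile_hmm`.
#' @return the reversed `profile_hmm`.
#' @export
reverse_hmm <- function(h) {
  L <- h$L
  p <- exp(h$trans)
  # expected visit counts per state in one begin-to-end generative pass;
  # insert self-loops contribute geometrically
  vM <- numeric(L + 2L); vI <- numeric(L + 1L); vD <- numeric(L + 2L)
  vM[1L] <- 1
  for (j in 0:L) {
    r <- j + 1L
    vI[r] <- vM[r] * p[r, "MI"]
    if (p[r, "II"] < 1) vI[r] <- vI[r] / (1 - p[r, "II"])
    vM[r + 1L] <- vM[r] * p[r, "MM"] + vI[r] * p[r, "IM"] + vD[r] * p[r, "DM"]
    if (j < L) vD[r + 1L] <- vM[r] * p[r, "MD"] + vD[r] * p[r, "DD"]
  }
  visits <- cbind(M = vM[1:(L + 1L)], I = vI, D = vD[1:(L + 1L)])
  mass <- matrix(0, nrow = L + 1L, ncol = 7L, dimnames = list(NULL, TRANS_NAMES))
  # reversed-edge type and row for each original transition type at row j:
  # original edge X_j -> Y_j' maps to mirrored edge Y* -> X* at row L - j.
  map <- c(MM = "MM", MI = "IM", MD = "DM", IM = "MI", II = "II",
           DM = "MD", DD = "DD")
  for (j in 0:L) {
    for (tt in TRANS_NAMES) {
      m <- visits[j + 1L, substr(tt, 1L, 1L)] * p[j + 1L, tt]
      if (m > 0) mass[L - j + 1L, map[[tt]]] <- mass[L - j + 1L, map[[tt]]] + m
    }
  }
  trans <- matrix(-Inf, nrow = L + 1L, ncol = 7L, dimnames = list(NULL, TRANS_NAMES))
  for (j in 0:L) {
    for (st in c("M", "I", "D")) {
      cols <- legal_trans(j, st, L)
      if (!length(cols)) next
      m <- mass[j + 1L, cols]
      trans[j + 1L, cols] <- if (sum(m) > 0) log(m / sum(m))
                             else log(rep(1 / length(cols), length(cols)))
    }
  }
  em <- h$em[rev(seq_len(L)), , drop = FALSE]
  ins <- h$ins_em[rev(seq_len(L + 1L)), , drop = FALSE]
  new_profile_hmm(L, h$alphabet, trans, em, ins_em = ins,
                  match_columns = NULL, name = paste0(h$name, "_rev"))
}
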