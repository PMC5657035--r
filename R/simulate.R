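# Synthetic gene-family simulator.
#
# Emulates the conditions the assembler is built for: a family of related
# gene sequences, shotgun reads with positionally varying coverage
# (including near-zero-coverage intervals crossed only by sparsely tiled
# reads), per-base substitution errors (the source of multiplicity-1
# k-mers), and off-target background reads. Substitution-only error model:
# no indels, so the family alignment is the trivial gap-free one and model
# building from it is exact.
#
# One seed governs the whole simulation. Each stage draws from its own
# stream, seeded as seed + a fixed stage offset (ancestor +0, family +1,
# read sampling +2, errors +3, background +4), so adding reads never
# perturbs the genes and vice versa.

#' Simulation configuration
#'
#' @param seed RNG seed for the whole simulation.
#' @param gene_length gene length in nt.
#' @param n_family_members number of related gene sequences.
#' @param pairwise_divergence expected substitution fraction between two
#'   family members (each member is mutated from a common ancestor at half
#'   this rate).
#' @param coverage coverage profile: `list(type = "flat", depth = )`,
#'   `list(type = "gradient", from = , to = )`, or
#'   `list(type = "gap", depth = , gap_start = , gap_len = , stride = )`.
#'   In a gap profile, randomly placed reads never overlap the gap interval;
#'   the gap is crossed only by a single deterministic tiling of reads
#'   `stride` apart, so adjacent tiles overlap by `read_length - stride`
#'   characters — enough to stay connected at k below that overlap but not
#'   above it.
#' @param read_length read length in nt.
#' @param substitution_error_rate per-base substitution error rate.
#' @param background_reads number of random off-target reads.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, gene_length = 300L, n_family_members = 5L,
                       pairwise_divergence = 0.05,
                       coverage = list(type = "flat", depth = 30),
                       read_length = 50L, substitution_error_rate = 0.001,
                       background_reads = 20L) {
  stopifnot(gene_length >= read_length,
            pairwise_divergence >= 0, pairwise_divergence <= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1)
  structure(list(seed = as.integer(seed), gene_length = as.integer(gene_length),
                 n_family_members = as.integer(n_family_members),
                 pairwise_divergence = pairwise_divergence,
                 coverage = coverage, read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 background_reads = as.integer(background_reads)),
            class = "sim_config")
}

with_stage_seed <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + offset)
  expr
}

random_nt <- function(n) paste(sample(GT_ALPHABETS$nt, n, replace = TRUE), collapse = "")

mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(GT_ALPHABETS$nt, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), n = length(hit))
}

#' Simulate a gene family and shotgun reads
#'
#' Deterministic given `cfg$seed`. Returns the true gene sequences, their
#' (gap-free) alignment, the reads, and a truth table recording each read's
#' origin and injected errors plus each gene's achieved per-position depth.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (named character), `alignment` (identical to
#'   `genes`: substitution-only families align without gaps), `reads` (named
#'   character), `truth` (data.frame: read, member, start, strand,
#'   n_errors; background reads have member `NA`), `depth` (list of
#'   per-position achieved depth vectors per gene) and `config`.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$gene_length; RL <- cfg$read_length
  ancestor <- with_stage_seed(cfg, 0L, random_nt(G))
  genes <- with_stage_seed(cfg, 1L, {
    out <- character(cfg$n_family_members)
    for (i in seq_len(cfg$n_family_members))
      out[i] <- mutate_seq(ancestor, cfg$pairwise_divergence / 2)$seq
    stats::setNames(out, sprintf("member%02d", seq_len(cfg$n_family_members)))
  })

  starts_strands <- with_stage_seed(cfg, 2L, {
    lapply(seq_along(genes), function(gi) sample_read_positions(cfg))
  })
  prof <- cfg$coverage

  reads <- character(0); truth <- list()
  depth <- lapply(genes, function(x) integer(G))
  with_stage_seed(cfg, 3L, {
    for (gi in seq_along(genes)) {
      ss <- starts_strands[[gi]]
      if (!length(ss$start)) next
      for (ri in seq_along(ss$start)) {
        s <- ss$start[ri]
        frag <- substr(genes[[gi]], s, s + RL - 1L)
        mut <- mutate_seq(frag, cfg$substitution_error_rate)
        rd <- if (ss$strand[ri] == "-") revcomp(mut$seq) else mut$seq
        id <- sprintf("g%02d_r%04d", gi, ri)
        reads[[id]] <- rd
        depth[[gi]][s:(s + RL - 1L)] <- depth[[gi]][s:(s + RL - 1L)] + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          read = id, member = names(genes)[gi], start = s,
          strand = ss$strand[ri], n_errors = mut$n, stringsAsFactors = FALSE)
      }
    }
  })
  if (cfg$background_reads > 0L) {
    bg <- with_stage_seed(cfg, 4L, {
      vapply(seq_len(cfg$background_reads), function(i) random_nt(RL), character(1))
    })
    names(bg) <- sprintf("bg_r%04d", seq_along(bg))
    reads <- c(reads, bg)
    for (id in names(bg))
      truth[[length(truth) + 1L]] <- data.frame(
        read = id, member = NA_character_, start = NA_integer_,
        strand = NA_character_, n_errors = 0L, stringsAsFactors = FALSE)
  }
  list(genes = genes, alignment = genes, reads = reads,
       truth = do.call(rbind, truth), depth = depth, config = cfg)
}

# Read start positions and strands for one gene under the coverage profile.
sample_read_positions <- function(cfg) {
  G <- cfg$gene_length; RL <- cfg$read_length
  prof <- cfg$coverage
  ns <- G - RL + 1L
  if (prof$type == "flat") {
    n <- ceiling(prof$depth * G / RL)
    starts <- sample.int(ns, n, replace = TRUE)
  } else if (prof$type == "gradient") {
    n <- ceiling(mean(c(prof$from, prof$to)) * G / RL)
    w <- seq(prof$from, prof$to, length.out = ns)
    starts <- sample.int(ns, n, replace = TRUE, prob = pmax(w, 1e-9))
  } else if (prof$type == "gap") {
    gap <- prof$gap_start:(prof$gap_start + prof$gap_len - 1L)
    n <- ceiling(prof$depth * G / RL)
    cand <- sample.int(ns, 4L * n, replace = TRUE)
    outside <- !vapply(cand, function(s) any(s:(s + RL - 1L) %in% gap), logical(1))
    starts <- cand[outside][seq_len(min(n, sum(outside)))]
    tile <- seq(max(1L, prof$gap_start - RL + 1L),
                min(ns, prof$gap_start + prof$gap_len - 1L),
                by = prof$stride)
    starts <- c(starts, tile)
  } else stop("unknown coverage profile type: ", prof$type)
  strand <- sample(c("+", "-"), length(starts), replace = TRUE)
  if (prof$type == "gap") {
    # the tiled bridge reads keep the forward strand so their overlap chain
    # is deterministic
    strand[seq(length(starts) - length(tile) + 1L, length(starts))] <- "+"
  }
  list(start = starts, strand = strand)
}

#' Write a simulation to disk
#'
#' Writes `reads.fastq.gz` (constant qualities), `refs.aln.fasta`,
#' `truth.tsv`, and `model.hmm` (profile HMM built from the alignment).
#'
#' @param sim output of [simulate_family()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atomic_write(file.path(dir, "reads.fastq.gz"), function(tmp) {
    con <- gzfile(tmp, "wt")
    on.exit(close(con))
    for (id in names(sim$reads)) {
      writeLines(c(paste0("@", id), sim$reads[[id]], "+",
                   strrep("I", nchar(sim$reads[[id]]))), con)
    }
  })
  write_fasta(sim$alignment, file.path(dir, "refs.aln.fasta"))
  write_tsv_atomic(sim$truth, file.path(dir, "truth.tsv"))
  h <- hmm_from_alignment(sim$alignment, alphabet = "nt", pseudocount = 0.1)
  write_hmmer3(h, file.path(dir, "model.hmm"))
  invisible(dir)
}
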