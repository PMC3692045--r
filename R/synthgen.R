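#' Configuration for synthetic benchmark generation
#'
#' The defaults define the package's standard benchmark: 1000 positives of
#' 100 bp — the element length used when training on ChIP-seq peak midpoints
#' — with the consensus `AAGGTC` planted at probability 0.9 on a random
#' strand, iid background at GC 0.42 (mammalian genome-wide average), and a
#' 10x negative set.
#'
#' @param n_pos Number of positive sequences.
#' @param seq_length Sequence length in bp.
#' @param motifs List of motif specs, each
#'   `list(consensus = <ACGT string>, p = <planting probability>,
#'   class = "positive" | "negative_only")`. `"positive"` motifs are planted
#'   in positives only; `"negative_only"` motifs only in negatives (a
#'   repressor-like feature whose absence predicts the positive class).
#' @param gc_background Background GC fraction.
#' @param fold_increase Negatives per positive.
#' @param require_one If `TRUE`, every positive carries at least one
#'   positive-class motif (planting indicators are redrawn until one fires)
#'   — the combinatorial, accessory-factor setting.
#' @param seed Integer seed; all randomness derives from it.
#' @param genome_spec For [generate_toy_genome()]: list of
#'   `list(chrom, length, masked_frac)`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pos = 1000L, seq_length = 100L,
                         motifs = list(list(consensus = "AAGGTC", p = 0.9,
                                            class = "positive")),
                         gc_background = 0.42, fold_increase = 10L,
                         require_one = FALSE, seed = 1L,
                         genome_spec = list(list(chrom = "chrA",
                                                 length = 1e6,
                                                 masked_frac = 0.1),
                                            list(chrom = "chrB",
                                                 length = 1e6,
                                                 masked_frac = 0.1))) {
  stopifnot(n_pos >= 1, seq_length >= 1, gc_background >= 0,
            gc_background <= 1, fold_increase >= 1)
  for (m in motifs) {
    stopifnot(all(c("consensus", "p", "class") %in% names(m)),
              m$p >= 0, m$p <= 1,
              m$class %in% c("positive", "negative_only"))
    if (grepl("[^ACGT]", m$consensus))
      stop("motif consensus must be over ACGT: ", m$consensus)
    if (nchar(m$consensus) > seq_length)
      stop("seq_length shorter than motif ", m$consensus)
  }
  structure(list(n_pos = as.integer(n_pos),
                 seq_length = as.integer(seq_length), motifs = motifs,
                 gc_background = gc_background,
                 fold_increase = as.integer(fold_increase),
                 require_one = require_one, seed = as.integer(seed),
                 genome_spec = genome_spec),
            class = "synth_config")
}

# n iid background sequences at the configured GC
random_background <- function(n, len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)   # A C G T
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""),
    character(1))
}

#' Generate a soft-masked toy genome
#'
#' Each chromosome is iid background at the configured GC; the requested
#' masked fraction is laid down as contiguous lowercase stretches (1 kb
#' each, non-overlapping), emulating RepeatMasker soft-masking. Seeded and
#' byte-deterministic.
#'
#' @param config A `synth_config` (uses `genome_spec`, `gc_background`,
#'   `seed`).
#' @return Named character vector of chromosome sequences.
#' @export
generate_toy_genome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed + 1000L, {
    out <- lapply(config$genome_spec, function(sp) {
      stopifnot(sp$masked_frac >= 0, sp$masked_frac <= 1)
      len <- as.integer(sp$length)
      s <- random_background(1L, len, config$gc_background)
      if (sp$masked_frac > 0) {
        stretch <- min(1000L, len)
        n_str <- round(sp$masked_frac * len / stretch)
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        masked <- logical(len)
        placed <- 0L
        guard <- 0L
        while (placed < n_str && guard < 100L * n_str) {
          guard <- guard + 1L
          st <- sample.int(len - stretch + 1L, 1L)
          span <- st:(st + stretch - 1L)
          if (any(masked[span])) next
          masked[span] <- TRUE
          placed <- placed + 1L
        }
        ch[masked] <- tolower(ch[masked])
        s <- paste(ch, collapse = "")
      }
      s
    })
    names(out) <- vapply(config$genome_spec, `[[`, character(1), "chrom")
    unlist(out)
  })
}

# overwrite seq with motif (or its revcomp) at a random position/strand;
# returns list(seq, pos, strand)
plant_motif <- function(seq, consensus) {
  L <- nchar(consensus); n <- nchar(seq)
  pos <- sample.int(n - L + 1L, 1L)
  strand <- if (stats::runif(1) < 0.5) "+" else "-"
  ins <- if (strand == "+") consensus else revcomp(consensus)
  seq <- paste0(substring(seq, 1L, pos - 1L), ins,
                substring(seq, pos + L, n))
  list(seq = seq, pos = pos, strand = strand)
}

#' Generate labeled planted-motif sequence sets
#'
#' Positives are background with each `"positive"`-class motif planted
#' independently (one occurrence, uniform position, random strand) at its
#' planting probability; `"negative_only"` motifs are planted only in
#' negatives, so the classifier must learn that their *absence* predicts
#' the positive class. Negatives are otherwise pure background. Seeded and
#' deterministic.
#'
#' @param config A `synth_config`.
#' @return A list of class `synth_sets`: `positives`, `negatives` (named
#'   character vectors), `truth` (`data.frame` of planted motif, sequence,
#'   position, strand), `config`.
#' @export
generate_labeled_sets <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n_neg <- config$n_pos * config$fold_increase
  pos_motifs <- Filter(function(m) m$class == "positive", config$motifs)
  neg_motifs <- Filter(function(m) m$class == "negative_only", config$motifs)
  with_local_seed(config$seed, {
    pos <- random_background(config$n_pos, config$seq_length,
                             config$gc_background)
    names(pos) <- sprintf("pos_%d", seq_len(config$n_pos))
    neg <- random_background(n_neg, config$seq_length, config$gc_background)
    names(neg) <- sprintf("neg_%d", seq_len(n_neg))
    truth <- list()
    plant_into <- function(seqs, motifs, require_one = FALSE) {
      for (i in seq_along(seqs)) {
        repeat {
          fire <- stats::runif(length(motifs)) < vapply(motifs, `[[`,
                                                        numeric(1), "p")
          if (!require_one || any(fire) || !length(motifs)) break
        }
        for (j in which(fire)) {
          pl <- plant_motif(seqs[[i]], motifs[[j]]$consensus)
          seqs[[i]] <- pl$seq
          truth[[length(truth) + 1L]] <<- data.frame(
            seq_id = names(seqs)[i], motif = motifs[[j]]$consensus,
            pos = pl$pos, strand = pl$strand, stringsAsFactors = FALSE)
        }
      }
      seqs
    }
    pos <- plant_into(pos, pos_motifs, config$require_one)
    neg <- plant_into(neg, neg_motifs)
    structure(list(positives = pos, negatives = neg,
                   truth = if (length(truth)) do.call(rbind, truth)
                           else data.frame(seq_id = character(),
                                           motif = character(),
                                           pos = integer(),
                                           strand = character()),
                   config = config),
              class = "synth_sets")
  })
}

#' @export
print.synth_sets <- function(x, ...) {
  cat("synthetic planted-motif sets:", length(x$positives), "positives,",
      length(x$negatives), "negatives,", nrow(x$truth), "planted sites\n")
  invisible(x)
}
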