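#' Construct a position weight matrix
#'
#' Positions are rows, bases the columns `A, C, G, T`; every row is a
#' probability vector.
#'
#' @param matrix Numeric matrix, L positions x 4 bases (A,C,G,T order).
#' @param name Motif name.
#' @param nsites Number of sites metadata (MEME header).
#' @param source_weight Optional SVM weight of the source kmer.
#' @return A list of class `pwm`.
#' @export
pwm <- function(matrix, name, nsites = 20L, source_weight = NULL) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 1L, all(matrix >= 0))
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("PWM rows must each sum to 1")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = matrix, nsites = as.integer(nsites),
                 source_weight = source_weight),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "(", nrow(x$matrix), "positions )\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Length (number of positions) of a PWM
#' @param x A `pwm`.
#' @export
length.pwm <- function(x) nrow(x$matrix)

#' Reverse complement of a PWM
#' @param p A `pwm`.
#' @return The `pwm` scanned from the other strand: positions reversed,
#'   A/T and C/G columns swapped.
#' @export
pwm_revcomp <- function(p) {
  m <- p$matrix[rev(seq_len(nrow(p$matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  pwm(m, p$name, p$nsites, p$source_weight)
}

# consensus-delta PWM: 1 - 3*alpha on the kmer's base, alpha elsewhere
kmer_pwm <- function(kmer, alpha = 0.01, name = kmer, source_weight = NULL) {
  code <- encode_seq(kmer)
  if (any(is.na(code))) stop("kmer must be over ACGT: ", kmer)
  m <- matrix(alpha, length(code), 4L)
  m[cbind(seq_along(code), code + 1L)] <- 1 - 3 * alpha
  pwm(m, name, source_weight = source_weight)
}

#' Top- and bottom-weighted kmers as MEME-format PWMs
#'
#' Takes the ranked weights table and emits one consensus-delta PWM per
#' selected kmer: probability `1 - 3*alpha` on the kmer's base at each
#' position, `alpha` on the others. At most 50 kmers total may be requested.
#'
#' @param weights Ranked table from [extract_weights()] (or
#'   [read_weights()]).
#' @param n_top Number of most-positive-weight kmers.
#' @param n_bottom Number of most-negative-weight kmers.
#' @param alpha Pseudocount probability, in `(0, 1/3)`.
#' @return List of `pwm` objects (named `<kmer>_top<i>` / `<kmer>_bottom<i>`
#'   name fields carry the kmer), writable with [write_meme()].
#' @export
kmers_to_meme <- function(weights, n_top = 10L, n_bottom = 10L,
                          alpha = 0.01) {
  stopifnot(is.data.frame(weights), nrow(weights) >= 1L,
            n_top >= 0, n_bottom >= 0, alpha > 0, alpha < 1 / 3)
  if (n_top + n_bottom > 50L)
    stop("at most 50 kmers may be converted (requested ",
         n_top + n_bottom, ")")
  if (n_top + n_bottom == 0L) stop("request at least one kmer")
  if (n_top + n_bottom > nrow(weights))
    stop("weights table has fewer kmers than requested")
  top <- utils::head(weights, n_top)
  bot <- utils::tail(weights, n_bottom)
  bot <- bot[rev(seq_len(nrow(bot))), ]        # most negative first
  rows <- rbind(top, bot)
  mapply(function(km, w) kmer_pwm(km, alpha, name = km, source_weight = w),
         rows$kmer, rows$weight, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write PWMs in MEME minimal format
#'
#' Versioned header, uniform ACGT background, one
#' `letter-probability matrix:` block per motif. Probabilities print with
#' six decimals, so write -> [read_meme()] -> write reproduces the text
#' byte for byte.
#'
#' @param pwms A `pwm` or list of `pwm`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.250000 C 0.250000 G 0.250000 T 0.250000", "")
  for (p in pwms) {
    lines <- c(lines,
               paste("MOTIF", p$name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(p$matrix), p$nsites),
               apply(p$matrix, 1L, function(r)
                 paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from MEME minimal format
#'
#' @param path Path to a MEME minimal motif file (ACGT alphabet).
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF blocks in '", path, "'")
  out <- list()
  for (s in starts) {
    name <- sub("^MOTIF\\s+", "", lines[s])
    name <- sub("\\s.*$", "", name)
    h <- s + 1L
    while (h <= length(lines) && !grepl("^letter-probability matrix:",
                                        lines[h])) h <- h + 1L
    if (h > length(lines)) stop("motif '", name, "' has no matrix block")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[h]))
    ns <- if (grepl("nsites=", lines[h]))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[h])) else 20L
    rows <- lines[(h + 1L):(h + w)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    # renormalize away 6-decimal rounding
    out[[name]] <- pwm(m / rowSums(m), name, nsites = ns)
  }
  out
}

#' Maximum log-odds score of a PWM over a sequence
#'
#' The best `sum(log2(p_pos(base) / background(base)))` over every offset on
#' both strands — the classical single-PWM baseline against which the
#' kmer-SVM is compared. `N` positions contribute 0.
#'
#' @param seq A single DNA sequence.
#' @param p A `pwm`.
#' @param background Base probabilities (A,C,G,T), default uniform.
#' @return Maximum log-odds score in bits. A sequence shorter than the
#'   motif returns `-Inf` with a warning.
#' @export
pwm_max_logodds <- function(seq, p, background = rep(0.25, 4)) {
  stopifnot(inherits(p, "pwm"), length(seq) == 1L)
  code <- encode_seq(seq)
  L <- nrow(p$matrix)
  if (length(code) < L) {
    warning("sequence shorter than motif; returning -Inf")
    return(-Inf)
  }
  best <- -Inf
  for (m in list(p$matrix, pwm_revcomp(p)$matrix)) {
    S <- log2(t(m) / background)               # 4 x L score table
    nw <- length(code) - L + 1L
    tot <- numeric(nw)
    for (j in seq_len(L)) {
      sj <- S[, j][code[j:(j + nw - 1L)] + 1L]
      sj[is.na(sj)] <- 0                       # N contributes log2(1) = 0
      tot <- tot + sj
    }
    best <- max(best, tot)
  }
  best
}

#' Vectorized PWM max-log-odds over a sequence set
#' @param seqs Character vector of sequences.
#' @inheritParams pwm_max_logodds
#' @return Numeric vector of scores.
#' @export
pwm_scan <- function(seqs, p, background = rep(0.25, 4))
  vapply(seqs, pwm_max_logodds, numeric(1), p = p, background = background)

# per-position (column) similarity between two base-probability 4-vectors
column_score <- function(a, b, metric) {
  switch(metric,
    pearson = {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    },
    euclidean = -sqrt(sum((a - b)^2)),
    sandelin_wasserman = 2 - sum((a - b)^2),
    stop("unknown metric: ", metric))
}

#' Column-wise similarity between two PWMs
#'
#' Scans every ungapped offset of the target against the query, in both
#' target orientations, requiring at least `min_overlap` aligned positions.
#' Per-position scores: Pearson correlation of the two 4-vectors; negated
#' Euclidean distance; or the Sandelin-Wasserman score `2 - sum((p - q)^2)`.
#' The reported similarity is the mean per-position score over the best
#' alignment's overlap.
#'
#' @param query,target `pwm` objects.
#' @param metric `"pearson"`, `"euclidean"` or `"sandelin_wasserman"`.
#' @param min_overlap Minimum aligned positions (default 4; motifs shorter
#'   than this are rejected).
#' @return A list of class `motif_match`: `query`, `target`, `metric`,
#'   `best_offset` (target start relative to query start), `orientation`
#'   (`"forward"`/`"revcomp"`), `similarity`, `overlap`.
#' @export
pwm_similarity <- function(query, target,
                           metric = c("pearson", "euclidean",
                                      "sandelin_wasserman"),
                           min_overlap = 4L) {
  metric <- match.arg(metric)
  stopifnot(inherits(query, "pwm"), inherits(target, "pwm"))
  lq <- nrow(query$matrix); lt <- nrow(target$matrix)
  if (min(lq, lt) < min_overlap)
    stop("motifs too short for min_overlap = ", min_overlap)
  best <- NULL
  for (orient in c("forward", "revcomp")) {
    tm <- if (orient == "forward") target$matrix else pwm_revcomp(target)$matrix
    for (off in (-(lt - min_overlap)):(lq - min_overlap)) {
      qi <- max(1L, 1L + off); ti <- max(1L, 1L - off)
      ov <- min(lq - qi, lt - ti) + 1L
      if (ov < min_overlap) next
      sc <- mean(vapply(seq_len(ov) - 1L, function(d)
        column_score(query$matrix[qi + d, ], tm[ti + d, ], metric),
        numeric(1)))
      if (is.null(best) || sc > best$similarity)
        best <- list(query = query$name, target = target$name,
                     metric = metric, best_offset = off,
                     orientation = orient, similarity = sc, overlap = ov)
    }
  }
  structure(best, class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s]: similarity %.4f (offset %d, %s, overlap %d)\n",
              x$query, x$target, x$metric, x$similarity, x$best_offset,
              x$orientation, x$overlap))
  invisible(x)
}

#' Rank database motifs by similarity to a query
#'
#' @param query A `pwm`.
#' @param database Non-empty list of `pwm`s.
#' @inheritParams pwm_similarity
#' @return A `data.frame` of matches sorted by descending similarity, ties
#'   broken by target name: `target`, `similarity`, `offset`, `orientation`,
#'   `overlap`.
#' @export
rank_matches <- function(query, database,
                         metric = c("pearson", "euclidean",
                                    "sandelin_wasserman"),
                         min_overlap = 4L) {
  metric <- match.arg(metric)
  stopifnot(length(database) >= 1L)
  ms <- lapply(database, pwm_similarity, query = query, metric = metric,
               min_overlap = min_overlap)
  df <- data.frame(target = vapply(ms, `[[`, character(1), "target"),
                   similarity = vapply(ms, `[[`, numeric(1), "similarity"),
                   offset = vapply(ms, `[[`, integer(1), "best_offset"),
                   orientation = vapply(ms, `[[`, character(1), "orientation"),
                   overlap = vapply(ms, `[[`, integer(1), "overlap"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$similarity, df$target), ]
  rownames(df) <- NULL
  df
}
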