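#' Read a (multi-)FASTA file
#'
#' Sequences are returned as a named character vector, one element per record.
#' Case is preserved exactly: lowercase bases carry the soft-masking (repeat)
#' annotation used by [compute_profile()] and the null-set sampler. Record ids
#' are the header text up to the first whitespace. Characters outside
#' `A,C,G,T,N` (either case) are mapped to `N` with a warning, so real genomes
#' with stray IUPAC ambiguity codes still load.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @seealso [write_fasta()], [extract_sequences()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    bad <- names(seqs)[!nzchar(seqs)][1L]
    stop("empty sequence for record '", bad, "' (line ",
         .fasta_header_line(path, bad), ") in '", path, "'")
  }
  nonstd <- grepl("[^ACGTNacgtn]", seqs)
  if (any(nonstd)) {
    warning(sum(nonstd), " record(s) contain non-ACGTN codes; mapped to N")
    seqs[nonstd] <- gsub("[^ACGTNacgtn]", "N", seqs[nonstd])
  }
  seqs
}

# line number of a header, for parse-error messages only
.fasta_header_line <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep(paste0("^>", id, "(\\s|$)"), lines)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Write sequences to FASTA
#'
#' Lines wrap at 60 columns; case (soft-masking) is preserved, so
#' `read_fasta(write_fasta(x))` reproduces `x` exactly.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap column, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' Coordinates are the standard BED dialect: 0-based, half-open. Columns
#' beyond the first three (name, score, strand) are kept when present.
#'
#' @param path Path to a tab-separated BED file (at least 3 columns).
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (ncol(df) < 3L) stop("BED file '", path, "' has fewer than 3 columns")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df <- df[seq_len(min(ncol(df), 6L))]
  validate_intervals(df, context = path)
  df
}

#' @rdname read_bed
#' @param intervals Interval `data.frame` as returned by [read_bed()].
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate genomic intervals
#'
#' Checks the half-open interval invariants `0 <= start < end`; errors name
#' the first offending row.
#'
#' @param intervals A `data.frame` with columns `chrom`, `start`, `end`.
#' @param context Optional label (e.g. a file name) for error messages.
#' @return The validated `data.frame`, invisibly.
#' @export
validate_intervals <- function(intervals, context = "intervals") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (!is.numeric(intervals$start) || !is.numeric(intervals$end))
    stop(context, ": start/end must be numeric")
  bad <- which(intervals$start >= intervals$end | intervals$start < 0)
  if (length(bad))
    stop(context, ": invalid interval at line ", bad[1L], " (",
         intervals$chrom[bad[1L]], ":", intervals$start[bad[1L]], "-",
         intervals$end[bad[1L]], "); need 0 <= start < end")
  invisible(intervals)
}

#' Extract interval sequences from a genome
#'
#' Case (soft-masking) is preserved from the genome. Record ids encode the
#' coordinates as `chrom:start-end`.
#'
#' @param intervals Interval `data.frame` (see [read_bed()]).
#' @param genome Named character vector of chromosome sequences
#'   (from [read_fasta()]).
#' @return Named character vector of sequences, one per interval.
#' @export
extract_sequences <- function(intervals, genome) {
  validate_intervals(intervals)
  miss <- setdiff(unique(intervals$chrom), names(genome))
  if (length(miss)) stop("chromosome(s) not in genome: ",
                         paste(miss, collapse = ", "))
  lens <- nchar(genome)[intervals$chrom]
  over <- which(intervals$end > lens)
  if (length(over))
    stop("interval beyond chromosome end at line ", over[1L], " (",
         intervals$chrom[over[1L]], ":", intervals$start[over[1L]], "-",
         intervals$end[over[1L]], ", chrom length ", lens[over[1L]], ")")
  out <- substring(genome[intervals$chrom], intervals$start + 1L,
                   intervals$end)
  names(out) <- sprintf("%s:%d-%d", intervals$chrom,
                        as.integer(intervals$start),
                        as.integer(intervals$end))
  out
}

#' Per-sequence profile: length, GC fraction, repeat fraction
#'
#' GC is counted case-insensitively over non-N bases; the repeat fraction is
#' the fraction of soft-masked (lowercase) bases. An all-N sequence gets
#' `gc = 0` with `gc_defined = FALSE` rather than an error, so batch
#' profiling never aborts.
#'
#' @param seqs Character vector of sequences (named or not).
#' @return A `data.frame` with columns `id`, `length`, `gc`, `repeat`,
#'   `n_frac`, `gc_defined`.
#' @export
compute_profile <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (any(!nzchar(seqs))) stop("empty sequence in input")
  len <- nchar(seqs)
  n_gc  <- nchar(gsub("[^GCgc]", "", seqs))
  n_low <- nchar(gsub("[^acgtn]", "", seqs))
  n_n   <- nchar(gsub("[^Nn]", "", seqs))
  denom <- len - n_n
  gc <- ifelse(denom > 0, n_gc / denom, 0)
  out <- data.frame(
    id = if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs),
    length = len, gc = gc, n_frac = n_n / len,
    gc_defined = denom > 0, stringsAsFactors = FALSE
  )
  out[["repeat"]] <- n_low / len
  out[c("id", "length", "gc", "repeat", "n_frac", "gc_defined")]
}

#' Sequence profile of a region set
#'
#' Extracts the intervals' sequences and reports per-region length, GC and
#' repeat fraction plus set-level summaries — the profile that null-set
#' generation matches.
#'
#' @inheritParams extract_sequences
#' @return A list of class `sequence_profile`: `records` (per-region
#'   `data.frame`, including the interval coordinates) and `summary`
#'   (mean/median of each statistic).
#' @export
profile_report <- function(intervals, genome) {
  seqs <- extract_sequences(intervals, genome)
  prof <- compute_profile(seqs)
  rec <- cbind(intervals[c("chrom", "start", "end")], prof[-1L])
  rec$id <- prof$id
  smry <- vapply(c("length", "gc", "repeat"), function(v)
    c(mean = mean(rec[[v]]), median = stats::median(rec[[v]])),
    numeric(2))
  structure(list(records = rec, summary = t(smry)),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat("Sequence profile of", nrow(x$records), "regions\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Build a prefix-sum genome index
#'
#' Per chromosome, cumulative counts of G/C bases, soft-masked (lowercase)
#' bases and N bases, so GC fraction, repeat fraction and N fraction of any
#' window are O(1) lookups. Window statistics from the index agree exactly
#' with [compute_profile()] on the extracted window.
#'
#' @param genome Named character vector of chromosome sequences.
#' @return A list of class `genome_index`; per chromosome `len` plus prefix
#'   vectors `gc`, `rpt`, `nn` of length `len + 1`.
#' @export
build_genome_index <- function(genome) {
  stopifnot(is.character(genome), length(genome) >= 1L,
            !is.null(names(genome)))
  idx <- lapply(genome, function(s) {
    code <- utf8ToInt(s)
    is_gc  <- code %in% utf8ToInt("GCgc")
    is_low <- code >= utf8ToInt("a")          # ASCII lowercase
    is_n   <- code %in% utf8ToInt("Nn")
    list(len = length(code),
         gc  = c(0, cumsum(is_gc)),
         rpt = c(0, cumsum(is_low)),
         nn  = c(0, cumsum(is_n)))
  })
  structure(idx, class = "genome_index")
}

#' O(1) window statistics from a genome index
#'
#' Vectorized over windows: `start`/`end` are 0-based half-open on a single
#' chromosome.
#'
#' @param index A `genome_index` from [build_genome_index()].
#' @param chrom Chromosome name.
#' @param start,end Numeric vectors of window coordinates (0-based half-open).
#' @return A `data.frame` with columns `length`, `gc`, `repeat`, `n_frac`,
#'   `gc_defined` (same conventions as [compute_profile()]).
#' @export
index_window_stats <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "genome_index"))
  ci <- index[[chrom]]
  if (is.null(ci)) stop("chromosome not in index: ", chrom)
  if (any(start < 0) || any(end > ci$len) || any(start >= end))
    stop("window out of range on ", chrom)
  len <- end - start
  gc  <- ci$gc[end + 1L]  - ci$gc[start + 1L]
  low <- ci$rpt[end + 1L] - ci$rpt[start + 1L]
  nn  <- ci$nn[end + 1L]  - ci$nn[start + 1L]
  denom <- len - nn
  out <- data.frame(length = len,
                    gc = ifelse(denom > 0, gc / denom, 0),
                    n_frac = nn / len, gc_defined = denom > 0)
  out[["repeat"]] <- low / len
  out[c("length", "gc", "repeat", "n_frac", "gc_defined")]
}
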