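#' Configuration for null-set generation
#'
#' Tolerances are absolute differences in fraction units (0.02 means the
#' negative's GC may differ from its source positive's by at most two
#' percentage points). After `max_attempts` failed draws for one negative,
#' both tolerances are doubled once for another `max_attempts` draws; if that
#' also fails the positive is skipped with a warning, so generation always
#' terminates.
#'
#' @param fold_increase Negatives per positive (integer >= 1).
#' @param gc_tolerance,repeat_tolerance Maximum absolute difference from the
#'   source positive, in `[0, 1]`.
#' @param seed Integer seed; the whole sampling stream derives from it.
#' @param excluded Optional interval `data.frame` of additional regions that
#'   negatives may not overlap.
#' @param max_attempts Draws per negative before the tolerance fallback.
#' @param max_n_frac Windows with more than this fraction of N bases are
#'   ineligible (assembly gaps).
#' @return A list of class `nullgen_config`.
#' @export
null_config <- function(fold_increase = 1L, gc_tolerance = 0.02,
                        repeat_tolerance = 0.02, seed = 1L,
                        excluded = NULL, max_attempts = 10000L,
                        max_n_frac = 0.1) {
  stopifnot(fold_increase >= 1, gc_tolerance >= 0, gc_tolerance <= 1,
            repeat_tolerance >= 0, repeat_tolerance <= 1, max_attempts >= 1)
  if (!is.null(excluded)) validate_intervals(excluded, "excluded")
  structure(list(fold_increase = as.integer(fold_increase),
                 gc_tolerance = gc_tolerance,
                 repeat_tolerance = repeat_tolerance,
                 seed = as.integer(seed), excluded = excluded,
                 max_attempts = as.integer(max_attempts),
                 max_n_frac = max_n_frac),
            class = "nullgen_config")
}

# all strict-tolerance candidate starts on one chromosome, via vectorized
# prefix-sum differences over every window start
scan_candidates <- function(ci, len, gc_target, rpt_target, gtol, rtol,
                            max_n_frac) {
  starts <- 0:(ci$len - len)
  nn <- ci$nn[starts + len + 1L] - ci$nn[starts + 1L]
  ok <- nn <= max_n_frac * len & nn < len
  gc <- (ci$gc[starts + len + 1L] - ci$gc[starts + 1L]) / (len - nn)
  ok <- ok & abs(gc - gc_target) <= gtol
  rpt <- (ci$rpt[starts + len + 1L] - ci$rpt[starts + 1L]) / len
  ok <- ok & abs(rpt - rpt_target) <= rtol
  keep <- which(ok)
  list(start = starts[keep], gc = gc[keep], rpt = rpt[keep])
}

# run code under a temporary Mersenne-Twister stream, restoring global state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Generate a profile-matched null (negative) interval set
#'
#' For each requested negative, a source positive is taken from a seeded
#' random cycling order and a window of exactly the positive's length is
#' drawn uniformly on the *same chromosome*, accepted when its GC and repeat
#' fractions are within tolerance of the positive's and it overlaps no
#' positive, excluded region, or previously accepted negative by even one
#' base pair. By construction the accepted set closely matches the positive
#' set's sequence profile (length exactly; GC/repeat within tolerance).
#'
#' @param positives Interval `data.frame` of the positive regions.
#' @param index A `genome_index` from [build_genome_index()].
#' @param config A `nullgen_config` from [null_config()].
#' Random draws are the fast path; if `max_attempts` draws fail, every
#' window start on the chromosome is scanned exhaustively at the strict
#' tolerance (prefix sums make this cheap), so a matching negative is found
#' whenever one exists. Only when no strict match exists at all are both
#' tolerances doubled once for a second exhaustive scan; after that the
#' positive is skipped with a warning.
#'
#' @return Interval `data.frame` of negatives (`chrom`, `start`, `end`,
#'   `name` = `neg_<i>`), with a per-negative report `data.frame` attached as
#'   attribute `"report"` (columns: chrom, start, end, source_positive, gc,
#'   repeat, attempts) and any skipped positives as attribute `"skipped"`.
#'   Identical inputs and config give byte-identical output.
#' @export
generate_null_set <- function(positives, index, config = null_config()) {
  stopifnot(inherits(index, "genome_index"),
            inherits(config, "nullgen_config"))
  validate_intervals(positives, "positives")
  if (nrow(positives) == 0L) stop("positive set is empty")
  miss <- setdiff(unique(positives$chrom), names(index))
  if (length(miss)) stop("positives on chromosome(s) not in index: ",
                         paste(miss, collapse = ", "))

  npos <- nrow(positives)
  pos_stats <- do.call(rbind, lapply(split(seq_len(npos), positives$chrom),
    function(ii) {
      st <- index_window_stats(index, positives$chrom[ii[1L]],
                               positives$start[ii], positives$end[ii])
      st$row <- ii
      st
    }))
  pos_stats <- pos_stats[order(pos_stats$row), ]

  # per-chromosome blocked intervals (positives + excluded), grown as
  # negatives are accepted
  blocked <- list()
  add_block <- function(chrom, s, e) {
    b <- blocked[[chrom]]
    if (is.null(b)) b <- list(start = numeric(), end = numeric())
    b$start <- c(b$start, s); b$end <- c(b$end, e)
    blocked[[chrom]] <<- b
  }
  for (i in seq_len(npos))
    add_block(positives$chrom[i], positives$start[i], positives$end[i])
  if (!is.null(config$excluded))
    for (i in seq_len(nrow(config$excluded)))
      add_block(config$excluded$chrom[i], config$excluded$start[i],
                config$excluded$end[i])
  overlaps_blocked <- function(chrom, s, e) {
    b <- blocked[[chrom]]
    !is.null(b) && any(s < b$end & e > b$start)
  }

  target <- config$fold_increase * npos
  out_chrom <- character(target); out_start <- numeric(target)
  out_source <- integer(target); out_gc <- numeric(target)
  out_rpt <- numeric(target); out_att <- integer(target)
  skipped <- integer()

  with_local_seed(config$seed, {
    # cycle positives in seeded random order, one negative per visit
    visit <- as.vector(vapply(seq_len(config$fold_increase),
                              function(f) sample.int(npos),
                              integer(npos)))
    n_acc <- 0L
    for (p in visit) {
      chrom <- positives$chrom[p]
      ci <- index[[chrom]]
      len <- pos_stats$length[p]
      if (ci$len < len) { skipped <- c(skipped, p); next }
      accepted <- FALSE
      tries_total <- 0L
      gtol <- config$gc_tolerance; rtol <- config$repeat_tolerance
      accept <- function(s, w_gc, w_rpt) {
        n_acc <<- n_acc + 1L
        out_chrom[n_acc] <<- chrom; out_start[n_acc] <<- s
        out_source[n_acc] <<- p; out_gc[n_acc] <<- w_gc
        out_rpt[n_acc] <<- w_rpt; out_att[n_acc] <<- tries_total
        add_block(chrom, s, s + len)
        accepted <<- TRUE
      }
      for (a in seq_len(config$max_attempts)) {     # randomized fast path
        tries_total <- tries_total + 1L
        s <- floor(stats::runif(1, 0, ci$len - len + 1))
        e <- s + len
        # inline prefix-sum lookups (hot loop; index_window_stats agrees)
        nn <- ci$nn[e + 1L] - ci$nn[s + 1L]
        if (nn > config$max_n_frac * len || nn == len) next
        w_gc <- (ci$gc[e + 1L] - ci$gc[s + 1L]) / (len - nn)
        if (abs(w_gc - pos_stats$gc[p]) > gtol) next
        w_rpt <- (ci$rpt[e + 1L] - ci$rpt[s + 1L]) / len
        if (abs(w_rpt - pos_stats[["repeat"]][p]) > rtol) next
        if (overlaps_blocked(chrom, s, e)) next
        accept(s, w_gc, w_rpt)
        break
      }
      if (!accepted) {
        # exhaustive scans: strict tolerance first, doubled only if no
        # strict match exists anywhere on the chromosome
        for (phase in 1:2) {
          cand <- scan_candidates(ci, len, pos_stats$gc[p],
                                  pos_stats[["repeat"]][p], gtol, rtol,
                                  config$max_n_frac)
          if (length(cand$start)) {
            ord <- sample.int(length(cand$start))
            for (ci2 in ord) {
              tries_total <- tries_total + 1L
              s <- cand$start[ci2]
              if (overlaps_blocked(chrom, s, s + len)) next
              accept(s, cand$gc[ci2], cand$rpt[ci2])
              break
            }
          }
          if (accepted) break
          gtol <- 2 * gtol; rtol <- 2 * rtol   # single bounded relaxation
        }
      }
      if (!accepted) skipped <- c(skipped, p)
    }
    n_acc
  }) -> n_acc

  if (length(skipped))
    warning(length(skipped), " negative(s) skipped after tolerance fallback")
  keep <- seq_len(n_acc)
  lens <- pos_stats$length[out_source[keep]]
  neg <- data.frame(chrom = out_chrom[keep], start = out_start[keep],
                    end = out_start[keep] + lens,
                    name = sprintf("neg_%d", keep),
                    stringsAsFactors = FALSE)
  report <- data.frame(chrom = neg$chrom, start = neg$start, end = neg$end,
                       source_positive = out_source[keep],
                       gc = out_gc[keep], stringsAsFactors = FALSE)
  report[["repeat"]] <- out_rpt[keep]
  report$attempts <- out_att[keep]
  attr(neg, "report") <- report
  attr(neg, "skipped") <- skipped
  neg
}

# sup-distance between two empirical CDFs (two-sample KS statistic)
ks_distance <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

#' How well does a negative set match its positives' profile?
#'
#' Reports two-sample Kolmogorov-Smirnov distances between the positive and
#' negative distributions of length, GC and repeat fraction, plus the
#' per-negative tolerance verification against its source positive when the
#' negatives carry a [generate_null_set()] report.
#'
#' @param positives,negatives Interval `data.frame`s.
#' @param index A `genome_index`.
#' @param config The `nullgen_config` used for generation (for the tolerance
#'   check); optional.
#' @return A list: `ks` (named distances), `tolerance_pass` (fraction of
#'   negatives within tolerance, or `NA` without a report/config),
#'   `profiles` (both per-set stat `data.frame`s).
#' @export
match_quality <- function(positives, negatives, index, config = NULL) {
  stopifnot(nrow(positives) > 0, nrow(negatives) > 0)
  stat_of <- function(df) {
    out <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$chrom),
      function(ii) {
        st <- index_window_stats(index, df$chrom[ii[1L]], df$start[ii],
                                 df$end[ii])
        st$row <- ii
        st
      }))
    out[order(out$row), ]
  }
  ps <- stat_of(positives); ns <- stat_of(negatives)
  ks <- c(length = ks_distance(ps$length, ns$length),
          gc = ks_distance(ps$gc, ns$gc))
  ks[["repeat"]] <- ks_distance(ps[["repeat"]], ns[["repeat"]])
  pass <- NA_real_
  rep_df <- attr(negatives, "report")
  if (!is.null(rep_df) && !is.null(config)) {
    src <- rep_df$source_positive
    ok <- abs(ns$gc - ps$gc[src]) <= 2 * config$gc_tolerance &
      abs(ns[["repeat"]] - ps[["repeat"]][src]) <= 2 * config$repeat_tolerance
    strict <- abs(ns$gc - ps$gc[src]) <= config$gc_tolerance &
      abs(ns[["repeat"]] - ps[["repeat"]][src]) <= config$repeat_tolerance
    pass <- mean(strict)
    attr(pass, "within_fallback") <- mean(ok)
  }
  list(ks = ks, tolerance_pass = pass,
       profiles = list(positives = ps, negatives = ns))
}
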