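# Independent brute-force oracles, written with string/pair arithmetic only
# so they share no code path with the implementation they check.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (s <= rc) s else rc
}

# distinct canonical kmers of length k, by enumerating all 4^k strings
oracle_space_size <- function(k) {
  all <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
  kmers <- apply(all, 1, paste, collapse = "")
  length(unique(vapply(kmers, oracle_canonical, character(1))))
}

# raw canonical count dictionary of one sequence (uppercased, N-windows skipped)
oracle_counts <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(table(character(0)))
  wins <- substring(s, 1:(n - k + 1), k:n)
  wins <- wins[!grepl("N", wins)]
  if (!length(wins)) return(table(character(0)))
  table(vapply(wins, oracle_canonical, character(1)))
}

# spectrum kernel from raw count dictionaries, L2-normalized
oracle_kernel <- function(s1, s2, k) {
  c1 <- oracle_counts(s1, k); c2 <- oracle_counts(s2, k)
  if (!length(c1) || !length(c2)) return(0)
  shared <- intersect(names(c1), names(c2))
  sum(c1[shared] * c2[shared]) /
    sqrt(sum(c1^2)) / sqrt(sum(c2^2))
}

# AUROC as pairwise concordance probability, ties counted half
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels > 0]; sn <- scores[labels < 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, p), collapse = ""),
    character(1))
}

# n non-overlapping fixed-length windows on a toy genome
random_disjoint_intervals <- function(chroms, chrom_len, n, len) {
  repeat {
    df <- data.frame(chrom = sample(chroms, n, TRUE),
                     start = sample.int(chrom_len - len, n),
                     stringsAsFactors = FALSE)
    df$end <- df$start + len
    clash <- FALSE
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, ]; d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) clash <- TRUE
    }
    if (!clash) return(df)
  }
}

# TRUE if any two intervals in the frame share >= 1 bp
any_overlap <- function(df) {
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]; d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) return(TRUE)
  }
  FALSE
}

# small shared toy genome + index, built once per test run
toy_genome_small <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- synth_config(genome_spec = list(
        list(chrom = "chrA", length = 3e5, masked_frac = 0.1),
        list(chrom = "chrB", length = 3e5, masked_frac = 0.1)))
      g <- generate_toy_genome(cfg)
      val <<- list(genome = g, index = build_genome_index(g))
    }
    val
  }
})
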