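#' Reverse complement of DNA strings
#'
#' Vectorized; case is preserved (soft-masking survives), `N` maps to `N`.
#'
#' @param seqs Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seqs)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# A=0 C=1 G=2 T=3 lookup over ASCII codes; anything else is NA
.base_code <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A") + 1L] <- 0L; tab[utf8ToInt("a") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L; tab[utf8ToInt("c") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L; tab[utf8ToInt("g") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L; tab[utf8ToInt("t") + 1L] <- 3L
  tab
})

encode_seq <- function(seq) .base_code[utf8ToInt(seq) + 1L]

# index of a kmer under base-4 encoding (lexicographic == numeric order)
kmer_to_index <- function(kmers) {
  k <- nchar(kmers[1L])
  codes <- vapply(kmers, function(s) encode_seq(s), integer(k), USE.NAMES = FALSE)
  if (k == 1L) codes <- matrix(codes, nrow = 1L)
  as.vector(4^((k - 1L):0) %*% codes)
}

index_to_kmer <- function(idx, k) {
  letters4 <- c("A", "C", "G", "T")
  out <- matrix("", length(idx), k)
  for (j in seq_len(k))
    out[, j] <- letters4[(idx %/% 4^(k - j)) %% 4 + 1]
  apply(out, 1L, paste, collapse = "")
}

# reverse-complement index for every kmer index 0..4^k-1 (vectorized)
rc_index <- function(idx, k) {
  rc <- 0
  for (j in seq_len(k))                 # j-th position from the left
    rc <- rc + (3 - (idx %/% 4^(k - j)) %% 4) * 4^(j - 1L)
  rc
}

#' Canonical representative of a kmer / reverse-complement pair
#'
#' TFs bind double-stranded DNA, so a kmer and its reverse complement are the
#' same feature; the canonical form is the lexicographic minimum of the pair.
#' Idempotent, and `canonical_kmer(x) == canonical_kmer(revcomp(x))`.
#'
#' @param kmers Character vector over `A,C,G,T` (uppercased first).
#' @return Character vector of canonical kmers.
#' @export
canonical_kmer <- function(kmers) {
  kmers <- toupper(kmers)
  if (any(grepl("[^ACGT]", kmers)))
    stop("canonical_kmer requires kmers over ACGT only")
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Build a strand-collapsed kmer feature space
#'
#' One block per kmer length: all `4^k` kmers collapsed to canonical
#' reverse-complement representatives, ordered lexicographically, blocks
#' concatenated in ascending `k`. A single `k` gives the spectrum-kernel
#' feature map; a contiguous range gives the weighted spectrum kernel with
#' equal block weighting. Each block has `(4^k + p(k)) / 2` features, where
#' `p(k) = 4^(k/2)` counts the reverse-complement palindromes (even `k` only).
#'
#' @param k_values Integer vector of kmer lengths, each in `1..12`.
#' @return A list of class `kmer_space`: `k_values`, per-block canonical
#'   `kmers`, `block_sizes`, `offsets`, `n_features`, and per-block integer
#'   maps from raw kmer index to block column.
#' @export
build_feature_space <- function(k_values) {
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1L) || any(k_values > 12L))
    stop("k values must be in 1..12")
  blocks <- lapply(k_values, function(k) {
    idx <- 0:(4^k - 1)
    canon <- pmin(idx, rc_index(idx, k))
    reps <- which(canon == idx) - 1L          # canonical representatives
    col_of_canon <- integer(4^k)
    col_of_canon[reps + 1L] <- seq_along(reps)
    list(kmers = index_to_kmer(reps, k),
         canon_col = col_of_canon[canon + 1L],   # raw index+1 -> block column
         size = length(reps))
  })
  sizes <- vapply(blocks, `[[`, integer(1), "size")
  structure(list(k_values = k_values,
                 kmers = lapply(blocks, `[[`, "kmers"),
                 canon_col = lapply(blocks, `[[`, "canon_col"),
                 block_sizes = sizes,
                 offsets = cumsum(c(0L, sizes[-length(sizes)])),
                 n_features = sum(sizes)),
            class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat("kmer feature space: k =", paste(x$k_values, collapse = ","),
      "|", x$n_features, "canonical features\n")
  invisible(x)
}

#' Feature names of a kmer space
#' @param space A `kmer_space`.
#' @return Character vector of canonical kmers, in feature-coordinate order.
#' @export
feature_kmers <- function(space) {
  stopifnot(inherits(space, "kmer_space"))
  unlist(space$kmers, use.names = FALSE)
}

# per-sequence raw canonical counts for one k block; NULL if no countable kmer
block_counts <- function(code, k, canon_col, size) {
  n <- length(code)
  if (n < k) return(NULL)
  nw <- n - k + 1L
  val <- code[seq_len(nw)] * 4^(k - 1L)
  if (k > 1L)
    for (j in 2:k)
      val <- val + code[j:(j + nw - 1L)] * 4^(k - j)
  val <- val[!is.na(val)]                      # windows containing N skipped
  if (!length(val)) return(NULL)
  tabulate(canon_col[val + 1L], nbins = size)
}

#' Map sequences to normalized strand-collapsed kmer count vectors
#'
#' Counting is case-insensitive (masking is metadata, not sequence content);
#' windows containing `N` are skipped. Each k-block is scaled to unit
#' Euclidean norm, blocks enter with equal weight `1/sqrt(#k)`, so the full
#' vector has unit norm whenever every block is nonzero — making the
#' spectrum kernel the plain inner product with `k(x, x) = 1`. Vectors are
#' exactly strand-invariant: `featurize_set(s) == featurize_set(revcomp(s))`.
#'
#' @param seqs Character vector of sequences (named for row names).
#' @param space A `kmer_space` from [build_feature_space()].
#' @return A sparse `dgCMatrix` (`Matrix`), sequences in rows, canonical
#'   kmers in columns. Sequences with no countable kmer give all-zero rows,
#'   listed in attribute `"zero_rows"` (with a warning).
#' @export
featurize_set <- function(seqs, space) {
  stopifnot(inherits(space, "kmer_space"), is.character(seqs),
            length(seqs) >= 1L)
  if (any(!nzchar(seqs))) stop("empty sequence in input")
  nk <- length(space$k_values)
  wt <- 1 / sqrt(nk)
  ii <- vector("list", length(seqs))
  jj <- vector("list", length(seqs))
  xx <- vector("list", length(seqs))
  zero <- logical(length(seqs))
  for (s in seq_along(seqs)) {
    code <- encode_seq(seqs[[s]])
    j_acc <- integer(0); x_acc <- numeric(0)
    for (b in seq_len(nk)) {
      cnt <- block_counts(code, space$k_values[b], space$canon_col[[b]],
                          space$block_sizes[b])
      if (is.null(cnt)) next
      nz <- which(cnt > 0)
      v <- cnt[nz] / sqrt(sum(cnt[nz]^2)) * wt
      j_acc <- c(j_acc, space$offsets[b] + nz)
      x_acc <- c(x_acc, v)
    }
    if (!length(j_acc)) zero[s] <- TRUE
    ii[[s]] <- rep.int(s, length(j_acc))
    jj[[s]] <- j_acc
    xx[[s]] <- x_acc
  }
  if (any(zero))
    warning(sum(zero), " sequence(s) yielded no countable kmer (zero vector)")
  m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(seqs), space$n_features),
                            dimnames = list(names(seqs), feature_kmers(space)))
  attr(m, "zero_rows") <- which(zero)
  attr(m, "k_values") <- space$k_values
  m
}

#' Feature vector of a single sequence
#'
#' Dense convenience wrapper around [featurize_set()].
#'
#' @param seq A single sequence.
#' @inheritParams featurize_set
#' @return Named numeric vector over the canonical kmer features.
#' @export
featurize <- function(seq, space) {
  stopifnot(length(seq) == 1L)
  m <- suppressWarnings(featurize_set(seq, space))
  stats::setNames(as.numeric(m[1L, ]), colnames(m))
}

#' Spectrum kernel between two feature vectors
#'
#' The inner product of normalized kmer count vectors: symmetric, in
#' `[0, 1]`, and `k(x, x) = 1` for any sequence with countable kmers.
#'
#' @param a,b Feature vectors over the same `kmer_space` (from
#'   [featurize()]).
#' @return Scalar kernel value.
#' @export
spectrum_kernel <- function(a, b) {
  if (length(a) != length(b))
    stop("feature vectors come from different feature spaces")
  sum(a * b)
}

#' Spectrum-kernel Gram matrix of a featurized set
#'
#' @param x Sparse feature matrix from [featurize_set()].
#' @return Dense symmetric Gram matrix.
#' @export
kernel_matrix <- function(x) as.matrix(Matrix::tcrossprod(x))
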