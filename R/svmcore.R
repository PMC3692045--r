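#' Training configuration for the kmer-SVM
#'
#' `C` is the soft-margin cost for negatives; positives get `C * PSW`
#' (positive-set weight), which compensates class imbalance when the
#' negative set is a multiple of the positive set. `E` is the solver's
#' termination tolerance (largest projected-gradient violation); results are
#' insensitive to it over a wide range. With `kernel = "spectrum"` a single
#' `k` is used; `"weighted_spectrum"` uses the contiguous range
#' `k_min..k_max` with equal block weighting.
#'
#' @param kernel `"spectrum"` or `"weighted_spectrum"`.
#' @param k Kmer length (spectrum kernel). Default 6.
#' @param k_min,k_max Kmer range (weighted spectrum kernel).
#' @param C Regularization weight, positive. Default 1.
#' @param E Solver tolerance, positive. Default 1e-5.
#' @param PSW Positive-set weight, a positive number or `"auto"` for
#'   `1 + ln(N/P)` (see [auto_psw()]).
#' @param n_folds Cross-validation folds, >= 2. Default 5.
#' @param seed Integer seed for fold assignment and solver epoch ordering.
#' @param max_epochs Solver epoch cap.
#' @return A list of class `train_config`.
#' @export
train_config <- function(kernel = c("spectrum", "weighted_spectrum"),
                         k = 6L, k_min = 5L, k_max = 8L,
                         C = 1, E = 1e-5, PSW = "auto",
                         n_folds = 5L, seed = 1L, max_epochs = 3000L) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, E > 0, n_folds >= 2)
  if (!identical(PSW, "auto")) stopifnot(is.numeric(PSW), PSW > 0)
  k_values <- if (kernel == "spectrum") as.integer(k)
              else seq(as.integer(k_min), as.integer(k_max))
  if (any(k_values < 1L) || any(k_values > 12L))
    stop("k values must be in 1..12")
  structure(list(kernel = kernel, k_values = k_values, C = C, E = E,
                 PSW = PSW, n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 max_epochs = as.integer(max_epochs)),
            class = "train_config")
}

#' Default positive-set weight
#'
#' `1 + ln(N/P)`: weighs positives more heavily when the negative set is
#' large, floored at 1 when `N < P`.
#'
#' @param P,N Positive and negative set sizes (>= 1).
#' @return The positive-set weight.
#' @export
auto_psw <- function(P, N) {
  stopifnot(P >= 1, N >= 1)
  max(1, 1 + log(N / P))
}

resolve_psw <- function(config, P, N)
  if (identical(config$PSW, "auto")) auto_psw(P, N) else config$PSW

# stack featurized positives over negatives; y in {+1, -1}
stack_sets <- function(pos, neg) {
  stopifnot(ncol(pos) == ncol(neg))
  list(X = rbind(pos, neg),
       y = c(rep(1, nrow(pos)), rep(-1, nrow(neg))))
}

# low-level fit in the explicit feature space; bias via augmented constant
# feature (so the dual expansion uses the kernel k(x,z) = x'z + 1)
fit_linear_svm <- function(X, y, Ci, E, max_epochs, seed) {
  Xb <- methods::cbind2(X, rep(1, nrow(X)))
  Xt <- Matrix::t(Xb)
  fit <- dcd_svm(Xt@p, Xt@i, Xt@x, nrow(Xt), y, Ci, E, max_epochs, seed)
  if (!fit$converged)
    warning("SVM solver stopped at max_epochs with violation ",
            format(fit$violation, digits = 3))
  list(weights = fit$w[seq_len(ncol(X))], bias = fit$w[ncol(X) + 1L],
       alpha = fit$alpha, epochs = fit$epochs, converged = fit$converged)
}

#' Train the kmer-SVM on featurized positive and negative sets
#'
#' A soft-margin linear SVM in the explicit canonical-kmer feature space,
#' fitted by dual coordinate descent. Because the spectrum kernel is the
#' inner product of this feature map, the model is mathematically identical
#' to the kernelized dual and the primal weight vector *is* the kmer weight
#' table. Misclassification cost is `C * PSW` for positives and `C` for
#' negatives. Deterministic given config and inputs.
#'
#' @param pos,neg Sparse feature matrices from [featurize_set()] (rows =
#'   sequences), over the same feature space.
#' @param config A `train_config`.
#' @return A list of class `kmersvm_model`: `weights` (named by canonical
#'   kmer), `bias`, `alpha` (dual coefficients, positives first), `config`,
#'   counts `P`/`N`, resolved `psw`, solver `epochs`; posterior slots `A`,`B`
#'   are `NA` until [calibrate()] / [fit_posterior()].
#' @export
train <- function(pos, neg, config = train_config()) {
  stopifnot(inherits(config, "train_config"),
            nrow(pos) >= 1, nrow(neg) >= 1)
  d <- stack_sets(pos, neg)
  P <- nrow(pos); N <- nrow(neg)
  psw <- resolve_psw(config, P, N)
  Ci <- ifelse(d$y > 0, config$C * psw, config$C)
  fit <- fit_linear_svm(d$X, d$y, Ci, config$E, config$max_epochs,
                        config$seed)
  structure(list(weights = stats::setNames(fit$weights, colnames(pos)),
                 bias = fit$bias, alpha = fit$alpha,
                 epochs = fit$epochs, converged = fit$converged,
                 config = config, P = P, N = N, psw = psw,
                 A = NA_real_, B = NA_real_),
            class = "kmersvm_model")
}

#' @export
print.kmersvm_model <- function(x, ...) {
  cat("kmer-SVM model: ", length(x$weights), " features | P = ", x$P,
      ", N = ", x$N, ", PSW = ", round(x$psw, 4), "\n", sep = "")
  if (!is.na(x$A))
    cat("posterior calibration: A = ", format(x$A, digits = 6),
        ", B = ", format(x$B, digits = 6), "\n", sep = "")
  invisible(x)
}

# seeded stratified fold assignment; sizes differ by <= 1 within each class
stratified_folds <- function(n_pos, n_neg, n_folds, seed) {
  with_local_seed(seed, {
    f_pos <- sample(rep_len(seq_len(n_folds), n_pos))
    f_neg <- sample(rep_len(seq_len(n_folds), n_neg))
    c(f_pos, f_neg)
  })
}

#' Cross-validated predictions
#'
#' Stratified, seeded n-fold partition; each fold is scored by a model
#' trained on the other folds, so every sequence receives exactly one
#' held-out score. These pooled scores feed the ROC/PR curves and the
#' posterior calibration.
#'
#' @inheritParams train
#' @return A `data.frame` (class `cv_predictions`): `seq_id`, `fold`,
#'   `label` (+1/-1), `score`.
#' @export
cross_validate <- function(pos, neg, config = train_config()) {
  P <- nrow(pos); N <- nrow(neg)
  if (config$n_folds > min(P, N))
    stop("n_folds exceeds the size of a class")
  folds <- stratified_folds(P, N, config$n_folds, config$seed)
  d <- stack_sets(pos, neg)
  ids <- rownames(d$X)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_len(P + N))
  psw <- resolve_psw(config, P, N)
  out <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    Ci <- ifelse(d$y[tr] > 0, config$C * psw, config$C)
    fit <- fit_linear_svm(d$X[tr, , drop = FALSE], d$y[tr], Ci,
                          config$E, config$max_epochs, config$seed + f)
    sc <- as.numeric(d$X[!tr, , drop = FALSE] %*% fit$weights) + fit$bias
    out[[f]] <- data.frame(seq_id = ids[!tr], fold = f,
                           label = d$y[!tr], score = sc,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_predictions", "data.frame")
  res
}

#' Ranked kmer weight table
#'
#' Every canonical kmer with its SVM weight, descending (ties broken
#' lexicographically). Large positive weights mark kmers whose presence
#' favors the positive class; large negative weights mark kmers whose
#' absence does. The posterior calibration parameters and training config
#' travel with the table as attributes and in the written header.
#'
#' @param model A `kmersvm_model`.
#' @return A `data.frame`: `kmer`, `revcomp`, `weight`, sorted by descending
#'   weight; attributes `A`, `B`, `bias`, `config`.
#' @export
extract_weights <- function(model) {
  stopifnot(inherits(model, "kmersvm_model"))
  km <- names(model$weights)
  df <- data.frame(kmer = km, revcomp = revcomp(km),
                   weight = unname(model$weights),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$kmer), ]
  rownames(df) <- NULL
  attr(df, "A") <- model$A; attr(df, "B") <- model$B
  attr(df, "bias") <- model$bias; attr(df, "config") <- model$config
  df
}

#' Write / read the weights table
#'
#' Header lines carry the posterior parameters, bias and config; rows are
#' `(kmer, revcomp, weight)` in rank order, so the table alone suffices to
#' score new sequences.
#'
#' @param weights Table from [extract_weights()].
#' @param path File path.
#' @return `path` (write) or the table with attributes restored (read).
#' @export
write_weights <- function(weights, path) {
  cfg <- attr(weights, "config")
  hdr <- c(sprintf("#A=%.17g", attr(weights, "A")),
           sprintf("#B=%.17g", attr(weights, "B")),
           sprintf("#bias=%.17g", attr(weights, "bias")),
           sprintf("#config=kernel:%s;k:%s;C:%g;E:%g;PSW:%s;n_folds:%d;seed:%d",
                   cfg$kernel, paste(cfg$k_values, collapse = ","), cfg$C,
                   cfg$E, as.character(cfg$PSW), cfg$n_folds, cfg$seed),
           "kmer\trevcomp\tweight")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(weights, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    h <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(h)) return(NA_real_)
    as.numeric(sub(paste0("^#", key, "="), "", h[1L]))
  }
  df <- utils::read.table(path, sep = "\t", skip = length(hdr) + 1L,
                          col.names = c("kmer", "revcomp", "weight"),
                          stringsAsFactors = FALSE)
  attr(df, "A") <- getv("A"); attr(df, "B") <- getv("B")
  attr(df, "bias") <- getv("bias")
  df
}

#' Platt scaling: sigmoid posterior from scores
#'
#' Fits `P(positive | s) = 1 / (1 + exp(A*s + B))` by regularized maximum
#' likelihood (Platt's method with the standard numerically stable Newton
#' iteration and out-of-sample target values). `A < 0` when higher scores
#' mean more positive. Fit on pooled cross-validated scores, not training
#' scores, to avoid resubstitution bias.
#'
#' @param scores Numeric decision values.
#' @param labels Labels in `{+1, -1}` (or a `cv_predictions` table in place
#'   of `scores`).
#' @return Named numeric `c(A, B)`.
#' @export
fit_posterior <- function(scores, labels = NULL) {
  if (inherits(scores, "cv_predictions")) {
    labels <- scores$label
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(-1, 1)))
  if (length(unique(labels)) < 2L)
    stop("posterior calibration needs both classes")
  n1 <- sum(labels > 0); n0 <- sum(labels < 0)
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n0 + 2)   # regularized targets
  t <- ifelse(labels > 0, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  fval <- function(A, B) {
    f <- A * scores + B
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  F <- fval(A, B)
  sigma <- 1e-12
  for (it in 1:100) {
    f <- A * scores + B
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(scores * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(scores^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(scores * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    # backtracking line search on the regularized negative log-likelihood
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      F2 <- fval(A2, B2)
      if (F2 < F + 1e-4 * step * (g1 * dA + g2 * dB)) {
        A <- A2; B <- B2; F <- F2
        break
      }
      step <- step / 2
      if (step < 1e-10) return(c(A = A, B = B))
    }
  }
  c(A = A, B = B)
}

#' Attach posterior calibration to a model
#'
#' @param model A `kmersvm_model`.
#' @param cv Pooled CV predictions from [cross_validate()].
#' @return The model with `A`, `B` filled in.
#' @export
calibrate <- function(model, cv) {
  ab <- fit_posterior(cv)
  model$A <- ab[["A"]]; model$B <- ab[["B"]]
  model
}

#' Posterior probability of the positive class
#' @param score Numeric SVM scores.
#' @param A,B Calibration parameters (see [fit_posterior()]).
#' @return Probabilities in `(0, 1)`.
#' @export
posterior_prob <- function(score, A, B) {
  f <- A * score + B
  p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
  # keep the open interval even where the sigmoid saturates in double
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Score sequences with a trained model
#'
#' `score = weights . featurize(seq) + bias`; the posterior comes from the
#' model's Platt calibration (NA if not calibrated). Sequences shorter than
#' the smallest k get the bias alone, with a warning and a flag.
#'
#' @param seqs Named character vector of sequences.
#' @param model A `kmersvm_model` (calibrated via [calibrate()] for
#'   posteriors).
#' @param space The `kmer_space` the model was trained over.
#' @return A `data.frame`: `seq_id`, `score`, `posterior`, `flagged`.
#' @export
score_sequences <- function(seqs, model, space) {
  stopifnot(inherits(model, "kmersvm_model"),
            length(model$weights) == space$n_features)
  X <- suppressWarnings(featurize_set(seqs, space))
  zero <- attr(X, "zero_rows")
  if (length(zero))
    warning(length(zero),
            " sequence(s) shorter than k or all-N; scored as bias alone")
  sc <- as.numeric(X %*% model$weights) + model$bias
  post <- if (is.na(model$A)) rep(NA_real_, length(sc))
          else posterior_prob(sc, model$A, model$B)
  ids <- if (is.null(names(seqs))) sprintf("seq_%d", seq_along(seqs))
         else names(seqs)
  data.frame(seq_id = ids, score = sc, posterior = post,
             flagged = seq_along(seqs) %in% zero,
             stringsAsFactors = FALSE)
}

#' One-call pipeline: featurize, cross-validate, train, calibrate
#'
#' The convenience front end: CV predictions give honest performance and the
#' Platt calibration; the reported weights come from a final model trained
#' on all data.
#'
#' @param pos_seqs,neg_seqs Named character vectors of sequences.
#' @param config A `train_config`.
#' @return A list of class `kmersvm_fit`: `model` (calibrated), `cv`
#'   (pooled predictions), `space`, `weights` (ranked table).
#' @export
kmersvm <- function(pos_seqs, neg_seqs, config = train_config()) {
  space <- build_feature_space(config$k_values)
  pos <- featurize_set(pos_seqs, space)
  neg <- featurize_set(neg_seqs, space)
  cv <- cross_validate(pos, neg, config)
  model <- train(pos, neg, config)
  model <- calibrate(model, cv)
  structure(list(model = model, cv = cv, space = space,
                 weights = extract_weights(model)),
            class = "kmersvm_fit")
}

#' @export
print.kmersvm_fit <- function(x, ...) {
  print(x$model)
  r <- roc_curve(x$cv$score, x$cv$label)
  p <- pr_curve(x$cv$score, x$cv$label)
  cat(sprintf("pooled CV: AUROC %.4f | AUPRC %.4f\n", r$area, p$area))
  cat("top kmers:", paste(utils::head(x$weights$kmer, 5), collapse = " "),
      "\n")
  invisible(x)
}

#' Tile a genome into overlapping windows
#'
#' Per chromosome, windows of length `c` start at 0, `c - v`, `2(c - v)`,
#' ... so consecutive windows overlap by exactly `v` bp. A final shorter
#' window is emitted only when at least `c / 2` bp would otherwise remain
#' uncovered, avoiding near-empty windows at chromosome ends.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   `genome_index`.
#' @param chunk Window length `c` in bp.
#' @param overlap Overlap `v` in bp, `0 <= v < c`.
#' @return Interval `data.frame` of windows (`chrom`, `start`, `end`).
#' @export
split_genome <- function(genome, chunk, overlap = 0L) {
  stopifnot(chunk > 0, overlap >= 0)
  if (overlap >= chunk) stop("overlap must be smaller than chunk length")
  lens <- if (inherits(genome, "genome_index"))
    vapply(genome, `[[`, numeric(1), "len") else nchar(genome)
  step <- chunk - overlap
  out <- lapply(names(lens), function(ch) {
    len <- lens[[ch]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    full <- starts[starts + chunk <= len]
    covered <- if (length(full)) max(full) + chunk else 0L
    tail_start <- if (length(full)) max(full) + step else 0L
    rows <- data.frame(chrom = rep(ch, length(full)), start = full,
                       end = full + chunk, stringsAsFactors = FALSE)
    if (len - covered >= chunk / 2 && tail_start < len)
      rows <- rbind(rows, data.frame(chrom = ch, start = tail_start,
                                     end = len, stringsAsFactors = FALSE))
    rows
  })
  do.call(rbind, out)
}
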