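# small separable toy problem: positives always carry AAGGTC, negatives never
separable_toy <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      set.seed(301)
      drop_motif <- function(s) gsub("AAGGTC|GACCTT", "ACACAC", s)
      pos <- random_dna(60, 60); neg <- drop_motif(random_dna(60, 60))
      pos <- vapply(pos, function(s) {
        at <- sample.int(55, 1)
        paste0(substr(s, 1, at - 1), "AAGGTC",
               substr(drop_motif(s), at + 6, 60))
      }, character(1))
      names(pos) <- sprintf("p%d", 1:60); names(neg) <- sprintf("n%d", 1:60)
      sp <- build_feature_space(6)
      val <<- list(pos_seqs = pos, neg_seqs = neg, space = sp,
                   pos = featurize_set(pos, sp),
                   neg = featurize_set(neg, sp))
    }
    val
  }
})

test_that("auto_psw follows 1 + ln(N/P) with a floor at 1", {
  expect_equal(auto_psw(100, 100), 1.0, tolerance = 1e-12)
  expect_equal(auto_psw(10, 100), 1 + log(10), tolerance = 1e-12)
  expect_equal(auto_psw(100, 100 * exp(2)), 3.0, tolerance = 1e-12)
  expect_equal(auto_psw(100, 10), 1.0)     # floored when N < P
  expect_error(auto_psw(0, 10))
})

test_that("training separates a separable toy set and finds the motif", {
  toy <- separable_toy()
  model <- train(toy$pos, toy$neg, train_config(seed = 1))
  sc <- score_sequences(c(toy$pos_seqs, toy$neg_seqs), model, toy$space)
  y <- c(rep(1, 60), rep(-1, 60))
  expect_equal(mean(sign(sc$score) == y), 1.0)        # 100% training accuracy
  expect_gt(min(sc$score[1:60]), max(sc$score[61:120]))
  w <- extract_weights(model)
  expect_identical(w$kmer[1], "AAGGTC")
  expect_identical(w$revcomp[1], "GACCTT")
  expect_equal(nrow(w), 2080L)                        # every feature once
  expect_false(is.unsorted(-w$weight))
})

test_that("weight-table scores equal the dual kernel expansion", {
  toy <- separable_toy()
  model <- train(toy$pos, toy$neg, train_config(seed = 2))
  X <- rbind(toy$pos, toy$neg)
  y <- c(rep(1, 60), rep(-1, 60))
  set.seed(19)
  held <- featurize_set(random_dna(50, 60), toy$space)
  primal <- as.numeric(held %*% model$weights) + model$bias
  # dual expansion with the bias-augmented kernel k(x,z) = x'z + 1
  K <- as.matrix(held %*% Matrix::t(X)) + 1
  dual <- as.numeric(K %*% (model$alpha * y))
  expect_lt(max(abs(primal - dual)), 1e-6)
  # and the weight table reproduces score - bias by linearity
  w <- extract_weights(model)
  q <- c(q1 = random_dna(1, 60))
  v <- featurize(q, toy$space)
  expect_equal(sum(w$weight * v[w$kmer]) + model$bias,
               score_sequences(q, model, toy$space)$score[1],
               tolerance = 1e-10)
})

test_that("duplicating negatives while halving their cost leaves the optimum unchanged", {
  toy <- separable_toy()
  sp2 <- build_feature_space(3)
  set.seed(59)
  pos <- featurize_set(random_dna(30, 40), sp2)
  neg <- featurize_set(random_dna(30, 40, gc = 0.6), sp2)
  obj <- function(model, pos, neg, c_pos, c_neg) {
    sc <- function(X) as.numeric(X %*% model$weights) + model$bias
    0.5 * (sum(model$weights^2) + model$bias^2) +
      c_pos * sum(pmax(0, 1 - sc(pos))) +
      c_neg * sum(pmax(0, 1 + sc(neg)))
  }
  m1 <- train(pos, neg, train_config(C = 1, PSW = 1, seed = 3))
  neg2 <- rbind(neg, neg)
  m2 <- train(pos, neg2, train_config(C = 0.5, PSW = 2, seed = 3))
  o1 <- obj(m1, pos, neg, 1, 1)
  o2 <- obj(m2, pos, neg2, 0.5 * 2, 0.5)
  expect_equal(o1, o2, tolerance = 1e-3)
})

test_that("raising PSW never lowers training-set sensitivity", {
  # overlapping classes so the cost trade-off actually binds
  set.seed(61)
  sp <- build_feature_space(4)
  pos <- featurize_set(random_dna(40, 50, gc = 0.55), sp)
  neg <- featurize_set(random_dna(120, 50, gc = 0.45), sp)
  sens <- vapply(c(0.25, 1, 4, 16, 64), function(psw) {
    m <- train(pos, neg, train_config(C = 0.1, PSW = psw, seed = 5))
    mean(as.numeric(pos %*% m$weights) + m$bias > 0)
  }, numeric(1))
  expect_false(is.unsorted(sens))
})

test_that("looser solver tolerance cannot increase epochs; AUROC is E-insensitive", {
  toy <- separable_toy()
  eps <- c(1e-3, 1e-4, 1e-5)
  epochs <- vapply(eps, function(E)
    train(toy$pos, toy$neg, train_config(E = E, seed = 7))$epochs,
    numeric(1))
  expect_false(is.unsorted(epochs))    # tighter E => at least as many epochs

  cfg <- synth_config(n_pos = 120, seq_length = 60, fold_increase = 2,
                      seed = 11)
  sets <- generate_labeled_sets(cfg)
  auc_of <- function(E) {
    fit <- kmersvm(sets$positives, sets$negatives,
                   train_config(E = E, n_folds = 3, seed = 11))
    roc_curve(fit$cv)$area
  }
  expect_lt(abs(auc_of(1e-5) - auc_of(1e-3)), 0.01)
})

test_that("agreement with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  toy <- separable_toy()
  set.seed(71)
  pos <- toy$pos[1:40, ]; neg <- toy$neg[1:40, ]
  model <- train(pos, neg, train_config(C = 1, PSW = 1, seed = 9))
  X <- as.matrix(rbind(pos, neg))
  y <- factor(c(rep(1, 40), rep(-1, 40)), levels = c(1, -1))
  ref <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                    cost = 1, scale = FALSE, tolerance = 1e-5)
  ref_sc <- as.numeric(as.matrix(X %*% crossprod(ref$SV, ref$coefs))) - ref$rho
  own_sc <- as.numeric(X %*% model$weights) + model$bias
  expect_identical(sign(own_sc), sign(ref_sc))
  expect_gt(cor(own_sc, ref_sc), 0.99)
})

test_that("cross-validation partitions are stratified, seeded, exhaustive", {
  toy <- separable_toy()
  cfg <- train_config(n_folds = 5, seed = 13)
  cv <- cross_validate(toy$pos, toy$neg, cfg)
  expect_equal(nrow(cv), 120)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_identical(sort(cv$seq_id), sort(c(rownames(toy$pos),
                                           rownames(toy$neg))))
  tab <- table(cv$fold, cv$label)
  expect_lte(max(tab) - min(tab), 1)   # class-stratified, sizes within 1
  expect_identical(cross_validate(toy$pos, toy$neg, cfg), cv)
  cv2 <- cross_validate(toy$pos, toy$neg, train_config(n_folds = 5,
                                                       seed = 14))
  expect_false(identical(cv$score, cv2$score))
  expect_error(cross_validate(toy$pos[1:3, ], toy$neg, train_config(
    n_folds = 5)), "n_folds")
})

test_that("planted activating and repressive kmers get signed weights", {
  cfg <- synth_config(n_pos = 150, seq_length = 60, fold_increase = 3,
                      motifs = list(list(consensus = "AAGGTC", p = 0.95,
                                         class = "positive"),
                                    list(consensus = "CACGTG", p = 0.8,
                                         class = "negative_only")),
                      seed = 21)
  sets <- generate_labeled_sets(cfg)
  fit <- kmersvm(sets$positives, sets$negatives,
                 train_config(n_folds = 3, seed = 21))
  w <- fit$weights
  expect_identical(w$kmer[1], "AAGGTC")                 # top positive weight
  expect_lt(w$weight[w$kmer == "CACGTG"], 0)            # repressor negative
})

test_that("Platt scaling is symmetric, monotone and proper on (0,1)", {
  set.seed(87)
  scores <- c(1 + rnorm(200, 0, 0.05), -1 + rnorm(200, 0, 0.05))
  labels <- c(rep(1, 200), rep(-1, 200))
  ab <- fit_posterior(scores, labels)
  expect_lt(ab[["A"]], 0)
  expect_lt(abs(ab[["B"]]), 0.1)
  expect_gt(posterior_prob(0, ab[["A"]], ab[["B"]]), 0.45)
  expect_lt(posterior_prob(0, ab[["A"]], ab[["B"]]), 0.55)
  grid <- seq(-2, 2, 0.1)                       # the scores' working range
  p <- posterior_prob(grid, ab[["A"]], ab[["B"]])
  expect_true(all(diff(p) > 0))                 # strictly monotone
  wide <- posterior_prob(seq(-1e3, 1e3, 50), ab[["A"]], ab[["B"]])
  expect_true(all(wide > 0 & wide < 1))         # open interval everywhere
  expect_error(fit_posterior(scores[1:200], labels[1:200]), "both classes")
})

test_that("scoring is strand-invariant and degrades gracefully", {
  toy <- separable_toy()
  model <- calibrate(train(toy$pos, toy$neg, train_config(seed = 1)),
                     cross_validate(toy$pos, toy$neg,
                                    train_config(seed = 1)))
  set.seed(91)
  qs <- random_dna(20, 80)
  names(qs) <- sprintf("q%d", 1:20)
  fw <- score_sequences(qs, model, toy$space)
  rc <- stats::setNames(revcomp(qs), names(qs))
  bw <- score_sequences(rc, model, toy$space)
  expect_equal(fw$score, bw$score, tolerance = 1e-12)
  expect_true(all(fw$posterior > 0 & fw$posterior < 1))

  # sequence shorter than k: bias alone, flagged
  expect_warning(sh <- score_sequences(c(tiny = "ACG"), model, toy$space),
                 "bias alone")
  expect_equal(sh$score, model$bias)
  expect_true(sh$flagged)
})

test_that("split_genome tiles chromosomes with the stated boundary rule", {
  g1k <- c(chr1 = paste(rep("A", 1000), collapse = ""))
  w <- split_genome(g1k, chunk = 500, overlap = 100)
  expect_equal(w$start, c(0, 400))
  expect_equal(w$end, c(500, 900))     # 100 uncovered bp < 250: tail dropped

  g300 <- c(c1 = paste(rep("A", 300), collapse = ""))
  w2 <- split_genome(g300, chunk = 100, overlap = 0)
  expect_equal(w2$start, c(0, 100, 200))
  expect_equal(w2$end, c(100, 200, 300))

  # consecutive windows overlap by exactly v and tile to the end
  g <- c(cX = paste(rep("A", 2350), collapse = ""))
  w3 <- split_genome(g, chunk = 400, overlap = 150)
  expect_true(all(diff(w3$start) == 250))
  ov <- w3$end[-nrow(w3)] - w3$start[-1]
  expect_true(all(ov == 150))
  expect_equal(w3$end[nrow(w3)], 2350)

  # uncovered tail of c/2 or more is emitted as a shorter window
  g1000 <- c(cY = paste(rep("A", 1000), collapse = ""))
  w4 <- split_genome(g1000, chunk = 400, overlap = 0)
  expect_equal(w4$start, c(0, 400, 800))
  expect_equal(w4$end, c(400, 800, 1000))    # 200 bp >= 200: emitted

  # chromosome shorter than half a chunk gives no window
  tiny <- c(s = "ACGTACGT")
  expect_equal(nrow(split_genome(tiny, chunk = 100, overlap = 10)), 0)
  expect_error(split_genome(g1k, chunk = 100, overlap = 100), "smaller")
})
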