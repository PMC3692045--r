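delta_pwm <- function(kmer, alpha = 0.01) kmersvm:::kmer_pwm(kmer, alpha)

test_that("kmer PWMs are consensus-delta and column-stochastic", {
  p <- delta_pwm("ACGT")
  expect_equal(nrow(p$matrix), 4)
  expect_equal(unname(p$matrix[1, ]), c(0.97, 0.01, 0.01, 0.01))
  expect_equal(unname(rowSums(p$matrix)), rep(1, 4))
  expect_error(pwm(matrix(c(0.5, 0.5, 0.1, 0.1), 1, 4), "bad"),
               "sum to 1")
})

test_that("kmers_to_meme enforces the 50-kmer cap and ranks ends of the table", {
  w <- data.frame(kmer = c("AAAAAA", "AAAAAC", "AAAAAG", "AAAAAT"),
                  revcomp = c("TTTTTT", "GTTTTT", "CTTTTT", "ATTTTT"),
                  weight = c(3, 1, -1, -2))
  pw <- kmers_to_meme(w, n_top = 1, n_bottom = 2)
  expect_length(pw, 3)
  expect_identical(vapply(pw, `[[`, character(1), "name"),
                   c(AAAAAA = "AAAAAA", AAAAAT = "AAAAAT",
                     AAAAAG = "AAAAAG"))  # most negative first among bottom
  expect_error(kmers_to_meme(w, 30, 25), "at most 50")
  expect_error(kmers_to_meme(w[0, ], 1, 0))
})

test_that("MEME write -> read -> write is byte-identical", {
  w <- data.frame(kmer = c("AAGGTC", "CACGTG"), revcomp = c("GACCTT", "CACGTG"),
                  weight = c(2, -2))
  pw <- kmers_to_meme(w, n_top = 1, n_bottom = 1)
  f1 <- withr::local_tempfile(fileext = ".meme")
  f2 <- withr::local_tempfile(fileext = ".meme")
  write_meme(pw, f1)
  parsed <- read_meme(f1)
  expect_length(parsed, 2)
  expect_equal(parsed[["AAGGTC"]]$matrix, pw[["AAGGTC"]]$matrix,
               tolerance = 1e-9)
  expect_true(all(abs(rowSums(parsed[["AAGGTC"]]$matrix) - 1) < 1e-9))
  write_meme(parsed, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("max log-odds scoring: closed form, strands, N and short sequences", {
  p0 <- kmersvm:::kmer_pwm("ACGT", alpha = 0)
  expect_equal(pwm_max_logodds("TTACGTTT", p0), 4 * log2(4))   # 8 bits
  # revcomp occurrence scores identically (both strands scanned)
  expect_equal(pwm_max_logodds("TTACGTTT", p0),
               pwm_max_logodds(revcomp("TTACGTTT"), p0))
  set.seed(5)
  s <- random_dna(1, 50)
  pa <- delta_pwm("AAGGTC")
  expect_equal(pwm_max_logodds(s, pa), pwm_max_logodds(revcomp(s), pa))

  # uniform PWM scores 0 everywhere
  pu <- pwm(matrix(0.25, 5, 4), "uniform")
  expect_equal(pwm_max_logodds(s, pu), 0)

  # N contributes log2(1) = 0
  expect_equal(pwm_max_logodds("NNACGTNN", p0), 8)
  expect_warning(v <- pwm_max_logodds("AC", p0), "shorter than motif")
  expect_identical(v, -Inf)

  # a planted consensus attains the motif self-information (alpha = 0)
  expect_equal(pwm_max_logodds("ACACAAGGTCACAC", kmersvm:::kmer_pwm("AAGGTC", 0)),
               6 * log2(4))
})

test_that("identical PWMs hit each metric's maximum; similarity is symmetric", {
  p <- delta_pwm("AAGGTC")
  for (m in c("pearson", "euclidean", "sandelin_wasserman")) {
    hit <- pwm_similarity(p, p, metric = m)
    expect_equal(hit$best_offset, 0L)
    expect_identical(hit$orientation, "forward")
    expect_equal(hit$similarity,
                 c(pearson = 1, euclidean = 0, sandelin_wasserman = 2)[[m]])
  }
  q <- delta_pwm("AAGGCC")
  for (m in c("pearson", "euclidean", "sandelin_wasserman"))
    expect_equal(pwm_similarity(p, q, metric = m)$similarity,
                 pwm_similarity(q, p, metric = m)$similarity,
                 tolerance = 1e-12)
  expect_error(pwm_similarity(delta_pwm("ACG"), delta_pwm("AAGGTC"),
                              min_overlap = 4), "too short")
})

test_that("rank_matches finds self, strand and the right database entry", {
  q <- delta_pwm("AAGGTC")
  db <- list(delta_pwm("CCCCCC"), delta_pwm("AAGGTC"))
  db[[1]]$name <- "CCCCCC"; db[[2]]$name <- "AAGGTC"
  for (m in c("pearson", "euclidean", "sandelin_wasserman")) {
    r <- rank_matches(q, db, metric = m)
    expect_identical(r$target[1], "AAGGTC")
  }
  # the reverse complement matches at self level in revcomp orientation
  rc_only <- list(pwm_revcomp(q))
  hit <- rank_matches(q, rc_only, metric = "pearson")
  expect_identical(hit$orientation[1], "revcomp")
  expect_equal(hit$similarity[1], 1.0)
  # deterministic tie-break by target name
  twins <- list(delta_pwm("AAGGTC"), delta_pwm("AAGGTC"))
  twins[[1]]$name <- "zeta"; twins[[2]]$name <- "alpha"
  expect_identical(rank_matches(q, twins)$target, c("alpha", "zeta"))
})

test_that("PWM scores of planted-motif sets separate classes (links to ROC)", {
  cfg <- synth_config(n_pos = 100, seq_length = 60, fold_increase = 1,
                      motifs = list(list(consensus = "AAGGTC", p = 1,
                                         class = "positive")),
                      seed = 33)
  sets <- generate_labeled_sets(cfg)
  sc <- c(pwm_scan(sets$positives, delta_pwm("AAGGTC")),
          pwm_scan(sets$negatives, delta_pwm("AAGGTC")))
  labels <- c(rep(1, 100), rep(-1, 100))
  expect_gt(roc_curve(sc, labels)$area, 0.9)
})
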