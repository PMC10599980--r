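# AUROC / average precision oracles, the normalised L2 loss, bootstrap R and
# split-half cross-validation

test_that("AUROC matches the exhaustive pair-counting oracle, with ties", {
  dag <- grn_dag(c("a", "b", "c"),
                 data.frame(from = c("a", "a"), to = c("b", "c")))
  e <- micanet:::edge_universe(c("a", "b", "c"), c("a", "b", "c"))
  # perfect and inverted oracles
  e$score <- as.numeric(paste(e$tf, e$gene) %in% c("a b", "a c"))
  expect_identical(auroc(e, dag), 1)
  e$score <- 1 - e$score
  expect_identical(auroc(e, dag), 0)
  # 6-pair worked case including a tie across a positive and a negative
  e$score <- c(0.9, 0.5, 0.5, 0.2, 0.8, 0.1)
  lab <- paste(e$tf, e$gene) %in% c("a b", "a c")
  expect_equal(auroc(e, dag), auroc_bruteforce(e$score, lab), tolerance = 1e-12)
  # randomized cases against the oracle
  set.seed(23)
  for (i in 1:10) {
    e$score <- sample(c(runif(4), 0.3, 0.3))
    expect_equal(auroc(e, dag), auroc_bruteforce(e$score, lab),
                 tolerance = 1e-12)
  }
  expect_error(auroc(e, grn_dag(c("a", "b"), data.frame(from = character(),
                                                        to = character()))),
               "degenerate truth")
})

test_that("average precision equals the brute-force PR evaluation", {
  set.seed(24)
  # 20-pair universe with a single positive
  s <- runif(20)
  lab <- seq_along(s) == 7
  expect_equal(average_precision(s, lab), ap_bruteforce(s, lab),
               tolerance = 1e-12)
  expect_equal(average_precision(s, lab), 1 / rank(-s)[7], tolerance = 1e-12)
  for (i in 1:10) {
    s <- runif(20)
    lab <- runif(20) < 0.3
    if (!any(lab)) lab[1] <- TRUE
    expect_equal(average_precision(s, lab), ap_bruteforce(s, lab),
                 tolerance = 1e-12)
  }
  # self-agreement attains 1
  expect_identical(average_precision(s, rank(-s) <= 5), 1)
})

test_that("normalised L2 loss pins the printed formula", {
  same <- normalized_l2_loss(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$loss, 0)
  expect_equal(same$inverse, 1e8)
  ab <- normalized_l2_loss(c(1, 0), c(0, 1))
  expect_equal(ab$loss, sqrt(2), tolerance = 1e-12)
  # pinned algebra: the default statistic is scale-invariant (c cancels
  # between the distance and the product of root-norms); the squared
  # variant scales linearly with c
  a <- c(0.3, 1.4, 0); b <- c(1.1, 0.2, 0.5)
  l1 <- normalized_l2_loss(a, b)$loss
  l9 <- normalized_l2_loss(9 * a, 9 * b)$loss
  expect_equal(l9, l1, tolerance = 1e-12)
  s1 <- normalized_l2_loss(a, b, squared = TRUE)$loss
  s9 <- normalized_l2_loss(9 * a, 9 * b, squared = TRUE)$loss
  expect_equal(s9, 9 * s1, tolerance = 1e-12)
  expect_error(normalized_l2_loss(c(0, 0), c(0, 0)), "undefined normalizer")
  # squared variant on the worked pair
  expect_equal(normalized_l2_loss(c(1, 0), c(0, 1), squared = TRUE)$loss, 2,
               tolerance = 1e-12)
})

test_that("bootstrap R is 1 for always-selected edges and has B=2 support
           {0, 1/2, 1}", {
  x <- coupled_expr(n = 30, seed = 25)
  rep_all <- bootstrap_reproducibility(x, rownames(x), "spearman", B = 10,
                                       k = 20, seed = 1)
  expect_identical(nrow(rep_all$edges), 20L)
  expect_true(all(rep_all$edges$R == 1))  # k = universe size: always selected
  r2 <- bootstrap_reproducibility(x, rownames(x), "random", B = 2, k = 5,
                                  seed = 2)
  expect_true(all(r2$edges$R %in% c(0, 0.5, 1)))
})

test_that("random-predictor R matches the k/N binomial expectation", {
  set.seed(26)
  x <- named_matrix(rnorm(10 * 40), 10)
  N <- 10 * 9; k <- 18
  r <- bootstrap_reproducibility(x, rownames(x), "random", B = 100, k = k,
                                 seed = 3)
  p <- k / N
  se <- sqrt(p * (1 - p) / 100)
  expect_lt(abs(median(r$edges$R) - p), 3 * se)
})

test_that("delta metrics vanish exactly for a method against itself", {
  x <- coupled_expr(n = 24, seed = 27)
  a <- bootstrap_reproducibility(x, rownames(x), "spearman", B = 5, k = 10,
                                 seed = 7)
  b <- bootstrap_reproducibility(x, rownames(x), "spearman", B = 5, k = 10,
                                 seed = 7)
  expect_identical(delta_r(a, b), 0)
  cva <- split_half_cv(x, rownames(x), "spearman", repeats = 3, seed = 9)
  cvb <- split_half_cv(x, rownames(x), "spearman", repeats = 3, seed = 9)
  expect_identical(delta_auprc(cva, cvb), 0)
})

test_that("split-half AUPRC of the random predictor sits at the top-fraction
           prevalence", {
  set.seed(28)
  x <- named_matrix(rnorm(25 * 60), 25)
  cv <- split_half_cv(x, rownames(x), "random", repeats = 10,
                      top_frac = 0.05, seed = 5)
  # prevalence baseline: AP of a random ranking concentrates near top_frac
  expect_lt(abs(cv$median_auprc - 0.05), 0.05)
  expect_gt(cv$median_auprc, 0.015)
})
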