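# the five inference engines and the grn_fit surface

test_that("Spearman scores perfect, transformed and hand-worked pairs", {
  x <- rbind(g01 = 1:10, g02 = (1:10)^3, g03 = exp(1:10 / 3))
  colnames(x) <- sprintf("c%03d", 1:10)
  f <- infer_spearman(x, "g01")
  expect_equal(f$edges$score, c(1, 1), tolerance = 1e-12)  # rank invariance
  # one discordant rank at n = 5: rho = 1 - 6*2/(5*24) = 0.9
  y <- rbind(g01 = 1:5, g02 = c(1, 2, 3, 5, 4))
  colnames(y) <- sprintf("c%03d", 1:5)
  f2 <- infer_spearman(y, "g01")
  expect_equal(f2$edges$score[f2$edges$gene == "g02"], 0.9, tolerance = 1e-12)
  # zero-variance gene is flagged down to score 0, p = 1
  z <- rbind(g01 = 1:6, g02 = rep(2, 6))
  colnames(z) <- sprintf("c%03d", 1:6)
  f3 <- infer_spearman(z, "g01")
  expect_equal(f3$edges$score[f3$edges$gene == "g02"], 0)
  expect_equal(f3$edges$p[f3$edges$gene == "g02"], 1)
})

test_that("all methods emit the same edge universe before thresholding", {
  set.seed(12)
  x <- named_matrix(rnorm(8 * 30), 8)
  tfs <- rownames(x)[1:4]
  universes <- lapply(c("spearman", "mi", "genie3", "l0l2", "random"),
                      function(m) {
    args <- list(expr = x, regulators = tfs, method = m, seed = 1)
    if (m == "genie3") args$ntrees <- 20
    f <- do.call(grn_infer, args)
    sort(paste(f$edges$tf, f$edges$gene))
  })
  for (u in universes[-1]) expect_identical(u, universes[[1]])
  expect_length(universes[[1]], 4 * 8 - 4)
})

test_that("MI inference: planted dependence ranks first; TF-TF pairs are
           symmetric; empty FDR set stays empty", {
  set.seed(13)
  x <- named_matrix(rnorm(20 * 500), 20)
  x["g02", ] <- x["g01", ]^3 + 0.05 * rnorm(500)
  f <- infer_mi(x, rownames(x))
  expect_identical(unlist(f$edges[1, c("tf", "gene")], use.names = FALSE)[
    order(unlist(f$edges[1, c("tf", "gene")], use.names = FALSE))],
    c("g01", "g02"))
  # symmetric MI materialises both directed TF-TF edges with equal scores
  s12 <- f$edges$score[f$edges$tf == "g01" & f$edges$gene == "g02"]
  s21 <- f$edges$score[f$edges$tf == "g02" & f$edges$gene == "g01"]
  expect_identical(s12, s21)
  # independent data: nothing survives the FDR gate
  y <- named_matrix(rnorm(20 * 100), 20)
  expect_identical(sum(infer_mi(y, rownames(y))$edges$retained), 0L)
})

test_that("GENIE3 honours the pooled percentile rule, recovers a planted
           parent, and is seed-deterministic", {
  set.seed(14)
  noise <- named_matrix(rnorm(10 * 50), 10)
  f <- infer_genie3(noise, rownames(noise), ntrees = 30, seed = 3)
  frac <- mean(f$edges$retained)
  expect_gte(frac, 0.88)
  expect_lte(frac, 0.95)
  # planted dominant linear parent
  wins <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- named_matrix(rnorm(6 * 80), 6)
    x["g06", ] <- 2 * x["g01", ] + 0.01 * rnorm(80)
    g <- infer_genie3(x, rownames(x)[1:5], ntrees = 50, seed = s)
    e6 <- g$edges[g$edges$gene == "g06", ]
    e6$tf[which.max(e6$score)] == "g01"
  }, TRUE)
  expect_gte(sum(wins), 19)
  f2 <- infer_genie3(noise, rownames(noise), ntrees = 30, seed = 3)
  expect_identical(f$edges, f2$edges)
})

test_that("L0L2 finds an exact single-regulator fit with unit coefficient", {
  set.seed(15)
  x <- named_matrix(rnorm(5 * 100), 5)
  x["g05", ] <- x["g02", ]
  f <- infer_l0l2(x, rownames(x)[1:4], seed = 1)
  e5 <- f$edges[f$edges$gene == "g05", ]
  expect_true(e5$retained[e5$tf == "g02"])
  expect_equal(e5$score[e5$tf == "g02"], 1, tolerance = 1e-4)
  expect_true(all(e5$score[e5$tf != "g02"] == 0))
})

test_that("L0L2 prefers the empty or near-empty support on null data", {
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    x <- named_matrix(rnorm(8 * 200), 8)
    f <- infer_l0l2(x, rownames(x)[1:7], seed = s)
    e <- f$edges[f$edges$gene == "g08", ]
    sum(e$retained) <= 1
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("L0L2 matches the closed-form best subset on an orthonormal design", {
  set.seed(16)
  n <- 64
  q <- qr.Q(qr(matrix(rnorm(n * 2), n)))  # orthonormal columns
  y <- 3 * q[, 1] + 0.01 * rnorm(n)
  x <- rbind(g01 = q[, 1], g02 = q[, 2], g03 = y)
  colnames(x) <- sprintf("c%03d", 1:n)
  f <- infer_l0l2(x, c("g01", "g02"), seed = 2)
  e <- f$edges[f$edges$gene == "g03", ]
  expect_true(e$retained[e$tf == "g01"])
  expect_false(e$retained[e$tf == "g02"])
  expect_lt(abs(e$score[e$tf == "g01"] - 3) / 3, 0.1)
})

test_that("L0L2 with a prior never selects outside it", {
  set.seed(17)
  dag <- random_dag(10, 0.15, seed = 31)
  x <- simulate(sem_grn(dag, seed = 32), n = 150, seed = 33)
  pr <- synth_prior(dag, 0.7, 0.1, seed = 34)
  f <- infer_l0l2(x, rownames(x), prior = pr, seed = 35)
  sel <- f$edges[f$edges$retained, ]
  expect_true(all(paste(sel$tf, sel$gene) %in% paste(pr$tf, pr$gene)))
  expect_identical(f$method, "l0l2+CA")
})

test_that("random predictor: deterministic, tie-free, uniform over seeds", {
  x <- named_matrix(rnorm(3 * 6), 3)
  f1 <- infer_random(x, rownames(x), seed = 4)
  expect_identical(f1$edges, infer_random(x, rownames(x), seed = 4)$edges)
  expect_identical(anyDuplicated(f1$edges$score), 0L)
  expect_true(all(diff(f1$edges$score) < 0))
  ranks <- sapply(1:400, function(s) {
    e <- infer_random(x, rownames(x), seed = s)$edges
    rank(-e$score)[order(e$tf, e$gene)] / nrow(e)
  })
  mean_rank <- rowMeans(ranks)
  se <- sqrt(1 / 12) / sqrt(400) # sd of uniform ranks
  expect_true(all(abs(mean_rank - (1 + 1 / 6) / 2) < 4 * se))
})

test_that("grn_fit methods print, summarise, and expose coefficients", {
  set.seed(18)
  x <- named_matrix(rnorm(5 * 30), 5)
  f <- grn_infer(x, rownames(x)[1:3], method = "spearman")
  expect_output(print(f), "spearman")
  s <- summary(f)
  expect_s3_class(s, "summary.grn_fit")
  expect_output(print(s), "top edges")
  cf <- coef(f)
  expect_named(cf)
  expect_length(cf, nrow(f$edges))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
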