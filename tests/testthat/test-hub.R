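# hub-centred subnetworks, correlation classes and exports

hub_fixture_network <- function(n_targets, seed = 1) {
  set.seed(seed)
  e <- data.frame(tf = "HUB", gene = sprintf("T%02d", seq_len(n_targets)),
                  score = runif(n_targets), retained = TRUE)
  e <- rbind(e, data.frame(tf = "T01", gene = "HUB", score = 0.5,
                           retained = TRUE))
  structure(list(edges = e, method = "mi", normalization = "external",
                 celltype = NA_character_, refined = FALSE, k = nrow(e)),
            class = "grn_network")
}

hub_fixture_expr <- function(genes, n = 30, seed = 2) {
  set.seed(seed)
  matrix(rnorm(length(genes) * n), length(genes), n,
         dimnames = list(genes, sprintf("c%03d", 1:n)))
}

test_that("hub networks keep all partners when few, top-25 when many", {
  net3 <- hub_fixture_network(3)
  x <- hub_fixture_expr(unique(c(net3$edges$tf, net3$edges$gene)))
  h3 <- build_hub_network(net3, x, "HUB", "targets")
  expect_identical(nrow(h3$edges), 3L)
  net40 <- hub_fixture_network(40)
  x40 <- hub_fixture_expr(unique(c(net40$edges$tf, net40$edges$gene)))
  h25 <- build_hub_network(net40, x40, "HUB", "targets")
  expect_identical(nrow(h25$edges), 25L)
  expect_lte(nrow(h25$nodes), 26L)
  # the 25 best by score
  best <- head(net40$edges[net40$edges$tf == "HUB", ][
    order(-net40$edges$score[net40$edges$tf == "HUB"]), "gene"], 25)
  expect_setequal(h25$edges$gene, best)
  # a root node has no regulators
  root_net <- structure(list(edges = data.frame(
    tf = "A", gene = c("B", "C"), score = c(1, 2), retained = TRUE),
    method = "mi", normalization = "external", celltype = NA_character_,
    refined = FALSE, k = 2L), class = "grn_network")
  xr <- hub_fixture_expr(c("A", "B", "C"))
  expect_warning(hr <- build_hub_network(root_net, xr, "A", "regulators"),
                 "no partners")
  expect_identical(nrow(hr$edges), 0L)
  expect_error(build_hub_network(net40, x40, "ABSENT", "targets"), "absent")
})

test_that("node weights are mean expression on the inference matrix", {
  net <- hub_fixture_network(3)
  x <- hub_fixture_expr(unique(c(net$edges$tf, net$edges$gene)))
  h <- build_hub_network(net, x, "HUB", "targets")
  expect_equal(h$nodes$mean_expression,
               unname(rowMeans(x)[h$nodes$gene]), tolerance = 1e-12)
})

test_that("correlation classes follow the printed alpha = 0.1 rule", {
  x <- rbind(up = 1:10, down = 10:1, noise = c(5, 2, 8, 1, 9, 3, 7, 4, 6, 10))
  colnames(x) <- sprintf("c%03d", 1:10)
  expect_identical(classify_edge_correlation(x, "up", "up")$class, "correlated")
  expect_identical(classify_edge_correlation(x, "up", "down")$class,
                   "anti-correlated")
  const <- rbind(x, flat = rep(1, 10))
  expect_identical(classify_edge_correlation(const, "up", "flat")$class,
                   "uncorrelated")
  # every edge gets exactly one class
  cls <- c("correlated", "anti-correlated", "uncorrelated")
  for (g in rownames(x))
    expect_true(classify_edge_correlation(x, "up", g)$class %in% cls)
})

test_that("the uncorrelated call has roughly nominal type-I rate under
           shuffling", {
  set.seed(29)
  n <- 30
  base <- rnorm(n)
  x <- matrix(0, 2, n, dimnames = list(c("a", "b"), sprintf("c%03d", 1:n)))
  x["a", ] <- base
  calls <- vapply(1:1000, function(i) {
    x["b", ] <- sample(base)
    classify_edge_correlation(x, "a", "b", alpha = 0.1)$class
  }, "")
  frac_uncor <- mean(calls == "uncorrelated")
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(frac_uncor - 0.9), 4 * se)
})

test_that("hub networks export to TSV and GraphML and parse back", {
  net <- hub_fixture_network(3)
  x <- hub_fixture_expr(unique(c(net$edges$tf, net$edges$gene)))
  h <- build_hub_network(net, x, "HUB", "targets")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(h, tsv, "tsv")
  back <- read_hub_network(tsv)
  expect_identical(back$hub, "HUB")
  expect_equal(back$edges$score, h$edges$score, tolerance = 1e-9)
  expect_identical(back$edges$class, h$edges$class)
  # a full network exports to GraphML too
  gnet <- random_network(paste0("T", 1:3), paste0("g", 1:4), k = 5, seed = 30)
  gfull <- withr::local_tempfile(fileext = ".graphml")
  export_network(gnet, gfull, "graphml")
  gg <- igraph::read_graph(gfull, format = "graphml")
  expect_equal(igraph::ecount(gg), 5)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(h, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(c("score", "class") %in%
                    igraph::edge_attr_names(g)))
  expect_true("mean_expression" %in% igraph::vertex_attr_names(g))
})
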