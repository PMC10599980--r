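# Hub-centred TF subnetworks with correlation-class annotation.

#' Classify the co-expression of a gene pair
#'
#' Spearman rank correlation between the two genes across the matrix's
#' samples: `"correlated"` for positive rho with two-sided p < alpha,
#' `"anti-correlated"` for negative rho with p < alpha, `"uncorrelated"`
#' otherwise (including p exactly equal to alpha and constant genes).
#'
#' @param expr genes x samples expression matrix.
#' @param source,target gene labels present in `expr`.
#' @param alpha significance level (default 0.1).
#' @return List with `class`, `rho` and `p`.
#' @export
classify_edge_correlation <- function(expr, source, target, alpha = 0.1) {
  if (!all(c(source, target) %in% rownames(expr)))
    stop("source or target absent from the matrix", call. = FALSE)
  if (ncol(expr) < 3L) stop("need >= 3 samples", call. = FALSE)
  x <- expr[source, ]; y <- expr[target, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(class = "uncorrelated", rho = 0, p = 1, flagged = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  p <- spearman_pvalue(rho, length(x))
  cls <- if (p < alpha && rho > 0) "correlated"
    else if (p < alpha && rho < 0) "anti-correlated"
    else "uncorrelated"
  list(class = cls, rho = rho, p = p, flagged = FALSE)
}

#' Build a hub-centred target or regulator subnetwork
#'
#' Extracts, from a final network, the top `max_nodes` partners of a hub TF in
#' the requested direction (its best-scored targets, or its best-scored
#' regulators), restricted to TFs by default as in hub TF-TF network figures.
#' Node weight is the partner's mean expression across the matrix's samples;
#' each edge carries its network score and a correlation class from
#' [classify_edge_correlation()].
#'
#' @param network a `grn_network` or `grn_fit`.
#' @param expr expression matrix of the same cell type (used for node means
#'   and correlation classes).
#' @param hub hub gene label.
#' @param direction `"targets"` or `"regulators"`.
#' @param max_nodes maximum number of non-hub members (default 25).
#' @param tf_list TF labels used to restrict partners; `NULL` admits any
#'   partner.
#' @param alpha significance level for correlation classes.
#' @return Object of class `hub_network`: `hub`, `direction`, `nodes`
#'   (label + mean expression), `edges` (tf, gene, score, class, rho, p).
#' @export
build_hub_network <- function(network, expr, hub,
                              direction = c("targets", "regulators"),
                              max_nodes = 25, tf_list = NULL, alpha = 0.1) {
  direction <- match.arg(direction)
  e <- edges_of(network)
  vocab <- unique(c(e$tf, e$gene))
  if (!hub %in% vocab) stop("hub absent from the network", call. = FALSE)
  sub <- if (direction == "targets") e[e$tf == hub, , drop = FALSE]
         else e[e$gene == hub, , drop = FALSE]
  partner_col <- if (direction == "targets") "gene" else "tf"
  if (!is.null(tf_list)) sub <- sub[sub[[partner_col]] %in% tf_list, , drop = FALSE]
  sub <- utils::head(order_edges(sub), max_nodes)
  if (nrow(sub) == 0L) warning("hub has no partners in this direction")
  members <- unique(sub[[partner_col]])
  nodes <- data.frame(gene = c(hub, members), stringsAsFactors = FALSE)
  nodes$mean_expression <- vapply(nodes$gene, function(g) {
    if (g %in% rownames(expr)) mean(expr[g, ]) else NA_real_
  }, 0)
  cls <- lapply(seq_len(nrow(sub)), function(i) {
    if (all(c(sub$tf[i], sub$gene[i]) %in% rownames(expr))) {
      classify_edge_correlation(expr, sub$tf[i], sub$gene[i], alpha = alpha)
    } else list(class = "uncorrelated", rho = NA_real_, p = NA_real_)
  })
  sub$class <- vapply(cls, `[[`, "", "class")
  sub$rho <- vapply(cls, `[[`, 0, "rho")
  sub$p_spearman <- vapply(cls, `[[`, 0, "p")
  rownames(sub) <- NULL
  structure(list(hub = hub, direction = direction, nodes = nodes,
                 edges = sub[, c("tf", "gene", "score", "class", "rho",
                                 "p_spearman")]),
            class = "hub_network")
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf("Hub network: %s (%s), %d members, %d edges\n", x$hub,
              x$direction, nrow(x$nodes) - 1L, nrow(x$edges)))
  if (nrow(x$edges)) print(table(x$edges$class))
  invisible(x)
}

#' Export a network for viewers
#'
#' For a `hub_network`, TSV keeps the node and edge tables (node mean
#' expression maps to node size, edge score to line thickness downstream);
#' GraphML carries the same attributes through igraph and loads in standard
#' network viewers. A `grn_network` exports its edge list as metadata TSV
#' (see [write_network()]) or as score-attributed GraphML.
#'
#' @param hub_net a `hub_network` or `grn_network`.
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(hub_net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (inherits(hub_net, "grn_network")) {
    if (format == "tsv") return(write_network(hub_net, path))
    g <- igraph::graph_from_data_frame(
      hub_net$edges[, c("tf", "gene", "score")], directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#hub\t%s\t%s", hub_net$hub, hub_net$direction), con)
    writeLines("#nodes", con)
    utils::write.table(hub_net$nodes, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines("#edges", con)
    utils::write.table(hub_net$edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      hub_net$edges[, c("tf", "gene", "score", "class")],
      directed = TRUE, vertices = hub_net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a hub network exported as TSV
#' @param path file written by [export_network()] with `format = "tsv"`.
#' @return A `hub_network`.
#' @export
read_hub_network <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  iedges <- which(lines == "#edges")
  nodes <- utils::read.table(text = lines[3:(iedges - 1L)], header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  edges <- utils::read.table(text = lines[(iedges + 1L):length(lines)],
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  structure(list(hub = hdr[2], direction = hdr[3], nodes = nodes,
                 edges = edges), class = "hub_network")
}
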