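# Biological evaluation: lineage set algebra, marker out-degree activity,
# hypergeometric gene-set enrichment and the V-statistic.

#' Gene-set collections (GMT semantics)
#'
#' @param sets named list of character vectors (set members).
#' @param universe optional background gene universe; set members must be
#'   drawn from it when given.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named", call. = FALSE)
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  if (!is.null(universe)) {
    bad <- !unlist(sets, use.names = FALSE) %in% universe
    if (any(bad)) stop("set members outside the declared universe", call. = FALSE)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets (sizes %s)%s\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-",
              if (is.null(x$universe)) "" else
                sprintf(", universe of %d genes", length(x$universe))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path GMT file.
#' @param universe optional background universe to attach on read.
#' @return A `gene_set_collection` / `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, universe = universe)
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Lineage-specific and common interaction sets
#'
#' Computes, on (tf, gene) edge identity, the printed set algebra over the
#' three blastocyst lineage networks:
#' EPI-specific = (EPI \ PE) \ TE, PE-specific = (PE \ EPI) \ TE,
#' TE-specific = (TE \ EPI) \ PE, Common = EPI intersect PE intersect TE.
#'
#' @param epi,pe,te `grn_network` objects sharing method and normalization
#'   tags.
#' @return Object of class `lineage_networks`: the four derived edge
#'   data.frames plus the originals.
#' @export
lineage_specific_sets <- function(epi, pe, te) {
  nets <- list(EPI = epi, PE = pe, TE = te)
  meth <- unique(vapply(nets, function(x) x$method, ""))
  norm <- unique(vapply(nets, function(x) as.character(x$normalization %||% NA), ""))
  if (length(meth) != 1L || length(norm) != 1L)
    stop("method/normalization tag mismatch between lineage networks",
         call. = FALSE)
  keys <- lapply(nets, function(x) unique(edge_key(x$edges$tf, x$edges$gene)))
  pick <- function(net, k) {
    e <- net$edges[edge_key(net$edges$tf, net$edges$gene) %in% k, , drop = FALSE]
    rownames(e) <- NULL
    e
  }
  structure(list(
    EPI_specific = pick(epi, setdiff(setdiff(keys$EPI, keys$PE), keys$TE)),
    PE_specific = pick(pe, setdiff(setdiff(keys$PE, keys$EPI), keys$TE)),
    TE_specific = pick(te, setdiff(setdiff(keys$TE, keys$EPI), keys$PE)),
    common = pick(epi, intersect(intersect(keys$EPI, keys$PE), keys$TE)),
    networks = nets, method = meth, normalization = norm),
    class = "lineage_networks")
}

#' @export
print.lineage_networks <- function(x, ...) {
  cat(sprintf("Lineage networks (%s): EPI-specific %d, PE-specific %d, TE-specific %d, common %d edges\n",
              x$method, nrow(x$EPI_specific), nrow(x$PE_specific),
              nrow(x$TE_specific), nrow(x$common)))
  invisible(x)
}

#' Marker-TF activity by normalised out-degree
#'
#' For each marker TF and each of the four derived networks (the three
#' lineage-specific sets and the common set), activity is proxied by the
#' marker's out-degree divided by the number of distinct genes in that
#' network. A marker is flagged active when its normalised out-degree is at
#' least the median over the pooled comparison cells: all (marker x network)
#' cells of the run by default, or per marker with `pool = "marker"`.
#' Markers absent from a network have out-degree 0 and are never active (a
#' zero out-degree means no detectable network for that marker, even when the
#' pooled median is itself 0).
#'
#' @param networks a `lineage_networks` object.
#' @param markers character vector of marker TFs (e.g. the EPI/PE/TE markers
#'   NANOG, GATA4, CDX2).
#' @param pool `"run"` (default) or `"marker"` median pooling.
#' @return data.frame with `marker`, `network`, `out_degree`,
#'   `norm_out_degree`, `active`.
#' @export
marker_activity <- function(networks, markers, pool = c("run", "marker")) {
  pool <- match.arg(pool)
  stopifnot(inherits(networks, "lineage_networks"))
  nets <- list(EPI_specific = networks$EPI_specific,
               PE_specific = networks$PE_specific,
               TE_specific = networks$TE_specific,
               common = networks$common)
  if (all(vapply(nets, nrow, 0L) == 0L))
    stop("all derived networks are empty", call. = FALSE)
  rows <- expand.grid(marker = markers, network = names(nets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$out_degree <- mapply(function(m, nn) {
    e <- unique(nets[[nn]][, c("tf", "gene")])
    sum(e$tf == m)
  }, rows$marker, rows$network)
  rows$norm_out_degree <- mapply(function(m, nn) {
    e <- nets[[nn]]
    n_genes <- length(unique(c(e$tf, e$gene)))
    if (n_genes == 0L) 0 else
      sum(unique(e[, c("tf", "gene")])$tf == m) / n_genes
  }, rows$marker, rows$network)
  med <- if (pool == "run") stats::median(rows$norm_out_degree)
         else tapply(rows$norm_out_degree, rows$marker,
                     stats::median)[rows$marker]
  # a marker with no outgoing edges has no detectable network: never active,
  # even when the pooled median is itself 0
  rows$active <- rows$norm_out_degree >= med & rows$out_degree > 0
  rows
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric tail p-value per set: the probability of drawing
#' at least the observed overlap when `length(genes)` genes are drawn from
#' the universe without replacement.
#'
#' @param genes query gene set (must lie inside `universe`).
#' @param collection a `gene_set_collection`.
#' @param universe background universe (defaults to the collection's own).
#' @return data.frame with `set`, `set_size`, `overlap`, `p`.
#' @export
gene_set_enrichment <- function(genes, collection, universe = NULL) {
  universe <- universe %||% collection$universe
  if (is.null(universe) || length(universe) == 0L)
    stop("empty universe", call. = FALSE)
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("query genes outside the universe", call. = FALSE)
  N <- length(universe); n <- length(genes)
  res <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(genes, s))
    p <- if (length(s) == 0L) 1 else
      stats::phyper(k - 1, length(s), N - length(s), n, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' V-statistic: enriched gene sets among top hub regulations
#'
#' Selects the `top_tfs` most-connected TFs of the network (highest
#' out-degree; ties broken by summed edge score then label), keeps the
#' `top_edges` best-scoring edges among those TFs' regulations, forms the
#' query as the union of sources and targets of the kept edges (targets only
#' with `include = "targets"`), and counts the gene sets enriched at
#' `p < alpha` by [gene_set_enrichment()]. No multiplicity correction is
#' applied: the raw count at a permissive alpha is the aggregate statistic.
#'
#' @param network a `grn_network`.
#' @param collection a `gene_set_collection`.
#' @param universe background universe for the enrichment test.
#' @param top_edges,top_tfs,alpha selection parameters (defaults 500, 25,
#'   0.1).
#' @param include `"union"` or `"targets"` query construction.
#' @return Object of class `v_result`: list with `V`, per-set `enrichment`
#'   table, and the `query` genes.
#' @export
v_statistic <- function(network, collection, universe = NULL, top_edges = 500,
                        top_tfs = 25, alpha = 0.1,
                        include = c("union", "targets")) {
  include <- match.arg(include)
  e <- unique(edges_of(network)[, c("tf", "gene", "score")])
  if (nrow(e) == 0L) stop("empty network", call. = FALSE)
  deg <- tapply(e$gene, e$tf, length)
  sc <- tapply(e$score, e$tf, sum)
  tf_order <- names(deg)[order(-deg, -sc[names(deg)], names(deg))]
  if (length(tf_order) < top_tfs)
    warning("fewer than ", top_tfs, " TFs in the network; using all")
  hubs <- utils::head(tf_order, top_tfs)
  eh <- order_edges(e[e$tf %in% hubs, , drop = FALSE])
  eh <- utils::head(eh, top_edges)
  query <- if (include == "union") unique(c(eh$tf, eh$gene)) else unique(eh$gene)
  universe <- universe %||% collection$universe
  query <- intersect(query, universe)
  enr <- gene_set_enrichment(query, collection, universe)
  structure(list(V = sum(enr$p < alpha), enrichment = enr, query = query,
                 alpha = alpha, top_edges = top_edges, top_tfs = top_tfs),
            class = "v_result")
}

#' @export
print.v_result <- function(x, ...) {
  cat(sprintf("V-statistic: %d of %d gene sets enriched at p < %g (query of %d genes)\n",
              x$V, nrow(x$enrichment), x$alpha, length(x$query)))
  invisible(x)
}

#' Normalise V-statistics across a method panel
#'
#' @param v named numeric vector of raw V values for one cell type.
#' @return `v / max(v)` (all zero stays all zero).
#' @export
normalize_v <- function(v) {
  m <- max(v)
  if (m == 0) return(v)
  v / m
}
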