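# Chromatin-accessibility refinement and top-K selection of final networks.

#' Refine a scored edge list with a chromatin-accessibility prior
#'
#' Exact set intersection on (tf, gene): edges absent from the prior are
#' dropped, scores are untouched. Appends `"+CA"` to the method tag.
#'
#' @param fit a `grn_fit` or `grn_network`.
#' @param prior a `regulatory_prior`.
#' @return The input object with intersected edges.
#' @export
refine_with_prior <- function(fit, prior) {
  stopifnot(inherits(fit, "grn_fit") || inherits(fit, "grn_network"))
  keep <- edge_key(fit$edges$tf, fit$edges$gene) %in%
    edge_key(prior$tf, prior$gene)
  if (!any(keep)) warning("refinement produced an empty edge list")
  fit$edges <- fit$edges[keep, , drop = FALSE]
  rownames(fit$edges) <- NULL
  if (!grepl("\\+CA$", fit$method)) fit$method <- paste0(fit$method, "+CA")
  fit$refined <- TRUE
  fit
}

#' Select the top-K edges of a fitted network
#'
#' Keeps the `k` highest-scoring edges (all, if fewer), with the deterministic
#' tie-break score desc, then tf, then gene, so that edges tied at the k-th
#' score are resolved lexicographically and reruns are identical. The
#' benchmark convention for real-data networks is k = 100,000.
#'
#' @param fit a `grn_fit` (or `grn_network`).
#' @param k maximum edge count (default 100000).
#' @param retained_only restrict to edges carrying the method's own retained
#'   flag (e.g. MI FDR pass, GENIE3 percentile pass) before ranking.
#' @param celltype optional cell-type tag carried into the result.
#' @return Object of class `grn_network`: list with `edges`, `method`,
#'   `normalization`, `celltype`, `refined`, `k`.
#' @export
select_top_edges <- function(fit, k = 100000, retained_only = FALSE,
                             celltype = NULL) {
  stopifnot_scalar_int(k, "k", min = 1L)
  e <- fit$edges
  if (retained_only) e <- e[e$retained, , drop = FALSE]
  e <- order_edges(e)
  e <- utils::head(e, k)
  rownames(e) <- NULL
  structure(list(edges = e, method = fit$method,
                 normalization = fit$normalization,
                 celltype = celltype %||% fit$celltype %||% NA_character_,
                 refined = isTRUE(fit$refined), k = k),
            class = "grn_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("GRN (%s%s): %d edges (k = %d)%s\n", x$method,
              if (isTRUE(x$refined)) ", CA-refined" else "",
              nrow(x$edges), x$k,
              if (is.na(x$celltype)) "" else paste0(", cell type ", x$celltype)))
  invisible(x)
}

#' Write a final network as TSV with metadata header lines
#'
#' @param network a `grn_network`.
#' @param path output file; `#method`, `#normalization`, `#celltype`,
#'   `#refined` comment lines precede the edge table.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#method\t", network$method),
               paste0("#normalization\t", network$normalization %||% "NA"),
               paste0("#celltype\t", network$celltype),
               paste0("#refined\t", network$refined)), con)
  utils::write.table(network$edges[, c("tf", "gene", "score")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network TSV written by [write_network()]
#' @param path input file.
#' @return A `grn_network`.
#' @export
read_network <- function(path) {
  hdr <- readLines(path, n = 4)
  meta <- strsplit(hdr, "\t")
  edges <- utils::read.table(path, header = TRUE, sep = "\t", skip = 4,
                             stringsAsFactors = FALSE)
  edges$retained <- TRUE
  structure(list(edges = order_edges(edges),
                 method = meta[[1]][2], normalization = meta[[2]][2],
                 celltype = meta[[3]][2],
                 refined = as.logical(meta[[4]][2]), k = nrow(edges)),
            class = "grn_network")
}
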