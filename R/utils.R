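# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random number stream. With `seed = NULL` the code runs
#' on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# deterministic ordering for edge tables: score desc, then tf, then gene
order_edges <- function(edges) {
  edges[order(-edges$score, edges$tf, edges$gene), , drop = FALSE]
}

# all ordered (tf, gene) pairs with tf drawn from `regulators`, no self-pairs
edge_universe <- function(regulators, genes) {
  u <- expand.grid(tf = regulators, gene = genes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- u[u$tf != u$gene, , drop = FALSE]
  rownames(u) <- NULL
  u
}

edge_key <- function(tf, gene) paste(tf, gene, sep = "\r")

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
}
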