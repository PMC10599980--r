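# Ground-truth DAGs and the linear structural-equation expression simulator.

#' Generate a random ground-truth regulatory DAG
#'
#' Draws a directed acyclic graph over `num_nodes` gene labels by fixing a
#' uniformly random topological order and including each order-respecting
#' ordered pair independently. Because only half of all ordered pairs respect
#' a given order, the per-pair inclusion probability is `2 * density`, so that
#' the expected edge density measured over *all* ordered non-self pairs equals
#' `density` (attainable for `density <= 0.5`).
#'
#' @param num_nodes number of genes (>= 2).
#' @param density target edge density over all ordered non-self pairs,
#'   in (0, 0.5]. The human-blastocyst accessibility data motivate the
#'   benchmark default of 0.07.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param labels optional character vector of gene labels
#'   (default `g001, g002, ...`).
#' @return An object of class `grn_dag`: list with `nodes` (character),
#'   `edges` (data.frame with columns `from`, `to`) and `topological_order`.
#' @examples
#' dag <- random_dag(20, 0.07, seed = 1)
#' dag
#' @export
random_dag <- function(num_nodes, density, seed = NULL, labels = NULL) {
  stopifnot_scalar_int(num_nodes, "num_nodes", min = 2L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0 || density >= 1)
    stop("'density' must be a single real in (0, 1)", call. = FALSE)
  max_edges <- num_nodes * (num_nodes - 1)
  if (density * max_edges < 1)
    stop("degenerate density: expected edge count below 1", call. = FALSE)
  if (is.null(labels)) {
    labels <- sprintf("g%0*d", max(3L, nchar(num_nodes)), seq_len(num_nodes))
  } else if (length(labels) != num_nodes || anyDuplicated(labels)) {
    stop("'labels' must be ", num_nodes, " unique labels", call. = FALSE)
  }
  p_incl <- min(1, 2 * density)
  with_seed(seed, {
    topo <- sample(labels)
    n_resp <- max_edges / 2L
    keep <- stats::runif(n_resp) < p_incl
    # enumerate order-respecting pairs (i earlier than j in topo)
    from_idx <- rep(seq_len(num_nodes - 1L), times = (num_nodes - 1L):1L)
    to_idx <- unlist(lapply(seq_len(num_nodes - 1L),
                            function(i) (i + 1L):num_nodes), use.names = FALSE)
    edges <- data.frame(from = topo[from_idx[keep]], to = topo[to_idx[keep]],
                        stringsAsFactors = FALSE)
    structure(list(nodes = labels, edges = edges, topological_order = topo),
              class = "grn_dag")
  })
}

#' Construct a ground-truth DAG from an explicit edge list
#'
#' @param nodes character vector of gene labels.
#' @param edges data.frame with character columns `from`, `to` (may have zero
#'   rows); must be acyclic over `nodes`.
#' @return A `grn_dag`; the topological order is derived.
#' @export
grn_dag <- function(nodes, edges) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes),
            is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to), stringsAsFactors = FALSE)
  if (!all(c(edges$from, edges$to) %in% nodes))
    stop("edge endpoints outside 'nodes'", call. = FALSE)
  if (any(edges$from == edges$to)) stop("self-edges are not allowed", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) stop("edge list contains a cycle", call. = FALSE)
  topo <- igraph::V(g)$name[igraph::topo_sort(g, mode = "out")]
  structure(list(nodes = nodes, edges = edges, topological_order = topo),
            class = "grn_dag")
}

#' @export
print.grn_dag <- function(x, ...) {
  p <- length(x$nodes)
  cat(sprintf("Ground-truth regulatory DAG: %d genes, %d edges (density %.3f)\n",
              p, nrow(x$edges), nrow(x$edges) / (p * (p - 1))))
  invisible(x)
}

#' Realized ordered-pair edge density of a DAG
#'
#' @param dag a `grn_dag`.
#' @return Edge count divided by the number of ordered non-self pairs.
#' @export
dag_density <- function(dag) {
  p <- length(dag$nodes)
  nrow(dag$edges) / (p * (p - 1))
}

#' Attach linear-SEM weights to a ground-truth DAG
#'
#' Every edge receives a weight `b` with `|b|` uniform on `weight_range` and a
#' random sign; node intercepts and the Gaussian noise standard deviation are
#' shared. The defaults give unit-scale, sign-balanced signal against N(0, 1)
#' noise.
#'
#' @param dag a `grn_dag`.
#' @param weight_range length-2 numeric, magnitude range for edge weights.
#' @param noise_sd standard deviation of the additive Gaussian error.
#' @param intercept per-node intercept (recycled).
#' @param seed optional integer seed.
#' @return An object of class `sem_grn`: the DAG plus a `weights` data.frame
#'   (`from`, `to`, `b`), `intercepts` and `noise_sd`.
#' @examples
#' g <- sem_grn(random_dag(10, 0.2, seed = 1), seed = 2)
#' x <- simulate(g, n = 50, seed = 3)
#' dim(x)
#' @export
sem_grn <- function(dag, weight_range = c(0.5, 1.5), noise_sd = 1,
                    intercept = 0, seed = NULL) {
  stopifnot(inherits(dag, "grn_dag"))
  if (length(weight_range) != 2L || weight_range[1] > weight_range[2] ||
      any(weight_range < 0))
    stop("'weight_range' must be 0 <= low <= high", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  m <- nrow(dag$edges)
  with_seed(seed, {
    mag <- stats::runif(m, weight_range[1], weight_range[2])
    sgn <- sample(c(-1, 1), m, replace = TRUE)
    weights <- cbind(dag$edges, b = mag * sgn)
    intercepts <- stats::setNames(rep_len(intercept, length(dag$nodes)), dag$nodes)
    structure(list(dag = dag, weights = weights, intercepts = intercepts,
                   noise_sd = noise_sd),
              class = "sem_grn")
  })
}

#' @export
print.sem_grn <- function(x, ...) {
  cat(sprintf("Linear-SEM ground truth: %d genes, %d weighted edges, noise sd %.3g\n",
              length(x$dag$nodes), nrow(x$weights), x$noise_sd))
  invisible(x)
}

#' Simulate expression from a linear-SEM ground truth
#'
#' Generates genes-by-samples matrices in topological order: each gene is its
#' intercept plus the weighted sum of its parents plus Gaussian noise
#' (x_j = sum_parents b * x_parent + e). Matrices carry the normalization tag
#' `"sem-raw"`.
#'
#' @param object a `sem_grn`.
#' @param nsim number of matrices to simulate.
#' @param seed optional integer seed.
#' @param n number of samples (columns) per matrix, >= 2.
#' @param ... unused.
#' @return A genes x samples matrix for `nsim = 1`, otherwise a list of them.
#' @export
simulate.sem_grn <- function(object, nsim = 1, seed = NULL, n = 100, ...) {
  stopifnot_scalar_int(n, "n", min = 2L)
  stopifnot_scalar_int(nsim, "nsim", min = 1L)
  dag <- object$dag
  parents <- split(seq_len(nrow(object$weights)),
                   factor(object$weights$to, levels = dag$nodes))
  out <- with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      x <- matrix(0, nrow = length(dag$nodes), ncol = n,
                  dimnames = list(dag$nodes, sprintf("s%04d", seq_len(n))))
      for (g in dag$topological_order) {
        val <- rep(object$intercepts[[g]], n)
        pid <- parents[[g]]
        if (length(pid)) {
          w <- object$weights$b[pid]
          val <- val + drop(w %*% x[object$weights$from[pid], , drop = FALSE])
        }
        x[g, ] <- val + stats::rnorm(n, sd = object$noise_sd)
      }
      expression_matrix(x, "sem-raw")
    })
  })
  if (nsim == 1L) out[[1]] else out
}

#' Synthetic chromatin-accessibility prior for a known DAG
#'
#' Emulates the accessibility-supported possible-regulation network: each true
#' edge enters the prior with probability `sensitivity`, each ordered non-edge
#' with probability `false_edge_rate`.
#'
#' @param dag a `grn_dag`.
#' @param sensitivity probability a true edge is in the prior.
#' @param false_edge_rate probability a non-edge is in the prior.
#' @param seed optional integer seed.
#' @return A `regulatory_prior` (data.frame of `tf`, `gene` pairs).
#' @export
synth_prior <- function(dag, sensitivity = 1, false_edge_rate = 0, seed = NULL) {
  stopifnot(inherits(dag, "grn_dag"))
  if (sensitivity < 0 || sensitivity > 1 || false_edge_rate < 0 || false_edge_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  u <- edge_universe(dag$nodes, dag$nodes)
  truth <- edge_key(u$tf, u$gene) %in% edge_key(dag$edges$from, dag$edges$to)
  with_seed(seed, {
    keep <- ifelse(truth,
                   stats::runif(nrow(u)) < sensitivity,
                   stats::runif(nrow(u)) < false_edge_rate)
    regulatory_prior(u[keep, , drop = FALSE])
  })
}

#' Synthetic gene-set collection for enrichment fixtures
#'
#' A stated fraction of sets is built from high-out-degree neighbourhoods of
#' the DAG (hub plus its targets, padded at random), so that they are
#' enrichable by construction; the remainder are uniform draws from the node
#' universe.
#'
#' @param dag a `grn_dag`.
#' @param n_sets number of sets.
#' @param set_size_range length-2 integer range of set sizes.
#' @param enriched_fraction fraction of sets anchored on hub neighbourhoods.
#' @param seed optional integer seed.
#' @return A `gene_set_collection` with the DAG nodes as universe.
#' @export
synth_genesets <- function(dag, n_sets, set_size_range = c(5L, 15L),
                           enriched_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(dag, "grn_dag"))
  stopifnot_scalar_int(n_sets, "n_sets", min = 0L)
  if (max(set_size_range) > length(dag$nodes))
    stop("set sizes exceed the number of nodes", call. = FALSE)
  if (n_sets == 0L)
    return(gene_set_collection(list(), universe = dag$nodes))
  outdeg <- table(factor(dag$edges$from, levels = dag$nodes))
  hubs <- names(sort(outdeg, decreasing = TRUE))
  n_enriched <- round(enriched_fraction * n_sets)
  with_seed(seed, {
    sizes <- seq(set_size_range[1], set_size_range[2])
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      if (i <= n_enriched) {
        hub <- hubs[1L + (i - 1L) %% length(hubs)]
        members <- unique(c(hub, dag$edges$to[dag$edges$from == hub]))
        if (length(members) >= size) {
          members[seq_len(size)]
        } else {
          c(members, sample(setdiff(dag$nodes, members), size - length(members)))
        }
      } else {
        sample(dag$nodes, size)
      }
    })
    names(sets) <- sprintf("%s%03d", c(rep("enriched_set", n_enriched),
                                       rep("random_set", n_sets - n_enriched)),
                           seq_len(n_sets))
    gene_set_collection(sets, universe = dag$nodes)
  })
}
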