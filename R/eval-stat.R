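# Statistical robustness metrics: AUROC, average precision, bootstrap edge
# reproducibility, split-half cross-validation and the normalised L2 loss.

edges_of <- function(x) {
  if (is.data.frame(x)) x else x$edges
}

#' Area under the ROC curve for a scored edge list
#'
#' Mann-Whitney rank formulation with tie correction, computed over the edge
#' universe carried by `fit` (all ordered non-self pairs for an unthresholded
#' fit). Positives are the ground-truth edges; with `undirected = TRUE` an
#' edge in either orientation counts as positive.
#'
#' @param fit a `grn_fit`, `grn_network` or edge data.frame with `tf`,
#'   `gene`, `score`.
#' @param truth a `grn_dag` or data.frame with `from`, `to`.
#' @param undirected give credit for reversed edges (off by default so that
#'   correlation-type and regression methods share one denominator).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(fit, truth, undirected = FALSE) {
  e <- edges_of(fit)
  te <- if (inherits(truth, "grn_dag")) truth$edges else truth
  pos_keys <- edge_key(te$from, te$to)
  if (undirected) pos_keys <- c(pos_keys, edge_key(te$to, te$from))
  lab <- edge_key(e$tf, e$gene) %in% pos_keys
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate truth: need >= 1 positive and >= 1 negative pair",
         call. = FALSE)
  r <- rank(e$score, ties.method = "average")
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (AUPRC) of a score vector against binary labels
#'
#' Step-wise average precision: scores are sorted in decreasing order (stable,
#' so any pre-sorting of the inputs acts as the tie-break) and precision is
#' averaged over the positions of the positives.
#'
#' @param scores numeric predictions.
#' @param labels logical (or 0/1) ground truth, same length.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels)) stop("no positive labels", call. = FALSE)
  ord <- order(-scores)
  lab <- labels[ord]
  hits <- cumsum(lab)
  prec <- hits / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Normalised L2 loss between two network-score vectors
#'
#' `loss = ||a - b||_2 / (sqrt(||a||_2) * sqrt(||b||_2))`: the Euclidean
#' distance between the score vectors divided by the product of the square
#' roots of their L2 norms. `squared = TRUE` uses `||a - b||_2^2` in the
#' numerator instead (reading ambiguity retained as a flag; the default is
#' the unsquared norm). With the default numerator the statistic is
#' scale-invariant: scaling both vectors by c > 0 leaves it unchanged
#' (c cancels between numerator and the product of root-norms); the squared
#' variant instead scales by c.
#'
#' @param a,b numeric vectors over a common edge universe (absent edges
#'   score 0).
#' @param squared use the squared distance in the numerator.
#' @param eps floor for the loss when inverting.
#' @return List with `loss` and `inverse` (`1 / max(loss, eps)`).
#' @export
normalized_l2_loss <- function(a, b, squared = FALSE, eps = 1e-8) {
  if (length(a) != length(b)) stop("score vectors differ in length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) stop("undefined normalizer: both vectors all-zero",
                               call. = FALSE)
  d <- sqrt(sum((a - b)^2))
  loss <- (if (squared) d^2 else d) / (sqrt(na) * sqrt(nb))
  list(loss = loss, inverse = 1 / max(loss, eps))
}

#' Bootstrap edge reproducibility
#'
#' Operationalises the reproducibility score R — the bootstrap estimate of the
#' posterior probability of observing an edge given the dataset — as the
#' selection frequency of each edge across `B` cell-resampled runs of the full
#' pipeline (inference, optional chromatin-accessibility refinement, top-`k`
#' selection). R is reported for the top-`k` edges of the full-data network.
#'
#' @param expr genes x samples expression matrix.
#' @param regulators TF labels.
#' @param method inference method name (see [grn_infer()]).
#' @param prior optional `regulatory_prior`.
#' @param B bootstrap resamples (>= 2).
#' @param k network size for every run.
#' @param seed integer seed.
#' @param infer_args extra arguments for the method engine.
#' @return Object of class `grn_reproducibility`: `edges` (top-k full-data
#'   edges with their R), `median_R`, `B_used`, `failures`, `k`,
#'   `n_universe`.
#' @export
bootstrap_reproducibility <- function(expr, regulators, method, prior = NULL,
                                      B = 100, k = 1000, seed = NULL,
                                      infer_args = list()) {
  stopifnot_scalar_int(B, "B", min = 2L)
  n <- ncol(expr)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  run_once <- function(x) {
    fit <- do.call(grn_infer, c(list(expr = x, regulators = regulators,
                                     method = method, prior = prior),
                                infer_args))
    select_top_edges(fit, k = k)
  }
  with_seed(seed, {
    full <- run_once(expr)
    counts <- stats::setNames(numeric(nrow(full$edges)),
                              edge_key(full$edges$tf, full$edges$gene))
    failures <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- expr[, idx, drop = FALSE]
      colnames(xb) <- sprintf("bs%05d", seq_len(n))
      if (!is.null(normalization_tag(expr)))
        attr(xb, "normalization") <- normalization_tag(expr)
      net <- tryCatch(run_once(xb), error = function(e) NULL)
      if (is.null(net)) { failures <- failures + 1L; next }
      hit <- names(counts) %in% edge_key(net$edges$tf, net$edges$gene)
      counts[hit] <- counts[hit] + 1
    }
    B_used <- B - failures
    if (B_used < B / 2)
      stop("more than half of the bootstrap resamples failed", call. = FALSE)
    edges <- full$edges[, c("tf", "gene", "score")]
    edges$R <- unname(counts) / B_used
    structure(list(edges = edges, median_R = stats::median(edges$R),
                   B_used = B_used, failures = failures, k = k,
                   n_universe = length(regulators) * (nrow(expr) - 1L),
                   method = full$method),
              class = "grn_reproducibility")
  })
}

#' @export
print.grn_reproducibility <- function(x, ...) {
  cat(sprintf("Edge reproducibility (%s): median R = %.3f over %d edges (B = %d, %d failures)\n",
              x$method, x$median_R, nrow(x$edges), x$B_used, x$failures))
  invisible(x)
}

#' Difference of median reproducibility (or AUPRC) against a baseline
#'
#' @param method_result,random_result two `grn_reproducibility` objects (for
#'   delta R) or two `grn_cv` objects (for delta AUPRC), computed on the same
#'   data and selection size.
#' @return `median(method) - median(baseline)`.
#' @export
delta_r <- function(method_result, random_result) {
  stopifnot(inherits(method_result, "grn_reproducibility"),
            inherits(random_result, "grn_reproducibility"))
  method_result$median_R - random_result$median_R
}

#' @rdname delta_r
#' @export
delta_auprc <- function(method_result, random_result) {
  stopifnot(inherits(method_result, "grn_cv"), inherits(random_result, "grn_cv"))
  method_result$median_auprc - random_result$median_auprc
}

#' Repeated split-half cross-validation of network inference
#'
#' Each repeat splits the cells into two random disjoint halves (sizes differ
#' by at most one), infers a network on each, takes the top `top_frac` of all
#' possible regulatory interactions from one half as the reference set, and
#' scores the other half's predictions over the same pair universe with
#' average precision; both fold orders are computed and averaged. The
#' normalised L2 loss between the two folds' full score vectors is recorded
#' per repeat as well.
#'
#' @inheritParams bootstrap_reproducibility
#' @param repeats number of random splits (default 10).
#' @param top_frac reference-set fraction of the universe (default 0.01).
#' @param eps,squared controls for [normalized_l2_loss()].
#' @return Object of class `grn_cv`: `results` (per-repeat `auprc`, `l2_loss`,
#'   `inv_l2`), `median_auprc`, `median_inv_l2`, `top_frac`, `failures`.
#' @export
split_half_cv <- function(expr, regulators, method, prior = NULL,
                          repeats = 10, top_frac = 0.01, seed = NULL,
                          infer_args = list(), eps = 1e-8, squared = FALSE) {
  n <- ncol(expr)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  universe <- edge_universe(regulators, rownames(expr))
  keys <- edge_key(universe$tf, universe$gene)
  n_ref <- max(1L, ceiling(top_frac * length(keys)))
  score_vec <- function(fit) {
    e <- edges_of(fit)
    s <- stats::setNames(numeric(length(keys)), keys)
    s[edge_key(e$tf, e$gene)] <- e$score
    s
  }
  top_keys <- function(fit) {
    e <- order_edges(edges_of(fit))
    edge_key(e$tf, e$gene)[seq_len(min(n_ref, nrow(e)))]
  }
  half_expr <- function(idx) {
    x <- expr[, idx, drop = FALSE]
    if (!is.null(normalization_tag(expr)))
      attr(x, "normalization") <- normalization_tag(expr)
    x
  }
  with_seed(seed, {
    rows <- list(); failures <- 0L
    for (r in seq_len(repeats)) {
      perm <- sample.int(n)
      ia <- perm[seq_len(floor(n / 2))]
      ib <- perm[(floor(n / 2) + 1L):n]
      res <- tryCatch({
        fa <- do.call(grn_infer, c(list(expr = half_expr(ia),
                                        regulators = regulators,
                                        method = method, prior = prior),
                                   infer_args))
        fb <- do.call(grn_infer, c(list(expr = half_expr(ib),
                                        regulators = regulators,
                                        method = method, prior = prior),
                                   infer_args))
        sa <- score_vec(fa); sb <- score_vec(fb)
        ap_ab <- average_precision(sa, keys %in% top_keys(fb))
        ap_ba <- average_precision(sb, keys %in% top_keys(fa))
        l2 <- normalized_l2_loss(sa, sb, squared = squared, eps = eps)
        data.frame(repeat_ = r, auprc = (ap_ab + ap_ba) / 2,
                   l2_loss = l2$loss, inv_l2 = l2$inverse)
      }, error = function(e) NULL)
      if (is.null(res)) failures <- failures + 1L else rows[[length(rows) + 1L]] <- res
    }
    if (length(rows) == 0L) stop("all cross-validation repeats failed", call. = FALSE)
    results <- do.call(rbind, rows)
    structure(list(results = results,
                   median_auprc = stats::median(results$auprc),
                   median_inv_l2 = stats::median(results$inv_l2),
                   top_frac = top_frac, failures = failures, method = method),
              class = "grn_cv")
  })
}

#' @export
print.grn_cv <- function(x, ...) {
  cat(sprintf("Split-half CV (%s): median AUPRC = %.4f, median 1/L2 = %.3f over %d repeats (%d failed)\n",
              x$method, x$median_auprc, x$median_inv_l2, nrow(x$results),
              x$failures))
  invisible(x)
}
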