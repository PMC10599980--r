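# The inference engines and the common fitted-network object.

new_grn_fit <- function(edges, method, score_type, normalization,
                        regulators, genes, extra = list(), call = NULL) {
  stopifnot(all(c("tf", "gene", "score") %in% names(edges)))
  if (is.null(edges$retained)) edges$retained <- TRUE
  edges <- order_edges(edges)
  rownames(edges) <- NULL
  structure(list(edges = edges, method = method, score_type = score_type,
                 normalization = normalization, regulators = regulators,
                 genes = genes, extra = extra, call = call),
            class = "grn_fit")
}

#' Infer a gene regulatory network
#'
#' The single fitting entry point: applies one of the five inference engines
#' to a genes x samples expression matrix and returns a scored edge list over
#' the full TF-to-gene universe (every ordered pair with the source in
#' `regulators`, self-pairs excluded). All methods emit this same universe
#' before any thresholding, so their outputs support set operations and a
#' common evaluation denominator.
#'
#' Methods and their network-score conventions:
#' \describe{
#'   \item{mi}{plug-in mutual information with empirical-CDF null
#'     (see [mi_edge_stats()]); score = -log10 p, edges at BH q < `fdr`
#'     flagged as retained. The MICA method is `method = "mi"` with a
#'     chromatin-accessibility `prior`.}
#'   \item{spearman}{absolute Spearman rank correlation, two-sided p by the
#'     t approximation.}
#'   \item{genie3}{random-forest total variance reduction per regulator,
#'     thresholded at the 10th percentile of the pooled importance
#'     distribution.}
#'   \item{l0l2}{per-target best-subset regression with an L0 + ridge penalty;
#'     score = |coefficient| of the CV-selected support
#'     (see [infer_l0l2()]).}
#'   \item{random}{a uniformly random strict ranking of all pairs.}
#' }
#'
#' When a `prior` is supplied, correlation-type methods (mi, spearman, genie3,
#' random) are refined by intersecting their edges with the prior after
#' fitting ("+CA"); l0l2 instead restricts each target's candidate regulators
#' to the prior before fitting.
#'
#' @param expr genes x samples numeric matrix (see [expression_matrix()]).
#' @param regulators character vector of TF labels (must be rows of `expr`).
#' @param method one of `"mi"`, `"spearman"`, `"genie3"`, `"l0l2"`,
#'   `"random"`.
#' @param prior optional `regulatory_prior` for chromatin-accessibility
#'   refinement.
#' @param seed optional integer seed for the stochastic methods.
#' @param ... passed to the method-specific engine.
#' @return An object of class `grn_fit` with elements `edges` (data.frame
#'   `tf`, `gene`, `score`, optionally `p`, `q`, and logical `retained`),
#'   `method`, `score_type`, `normalization`, `regulators`, `genes`.
#' @seealso [select_top_edges()], [refine_with_prior()], [auroc()]
#' @examples
#' g <- sem_grn(random_dag(15, 0.1, seed = 1), seed = 1)
#' x <- simulate(g, n = 60, seed = 2)
#' fit <- grn_infer(x, regulators = rownames(x), method = "spearman")
#' fit
#' head(coef(fit))
#' @export
grn_infer <- function(expr, regulators,
                      method = c("mi", "spearman", "genie3", "l0l2", "random"),
                      prior = NULL, seed = NULL, ...) {
  method <- match.arg(method)
  cl <- match.call()
  check_expr_regulators(expr, regulators)
  fit <- switch(method,
    mi = infer_mi(expr, regulators, ...),
    spearman = infer_spearman(expr, regulators, ...),
    genie3 = infer_genie3(expr, regulators, seed = seed, ...),
    l0l2 = infer_l0l2(expr, regulators, prior = prior, seed = seed, ...),
    random = infer_random(expr, regulators, seed = seed, ...))
  if (!is.null(prior) && method != "l0l2") {
    fit <- refine_with_prior(fit, prior)
  }
  fit$call <- cl
  fit
}

check_expr_regulators <- function(expr, regulators) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("'expr' must be a matrix with gene labels", call. = FALSE)
  if (!all(regulators %in% rownames(expr)))
    stop("regulators absent from the expression matrix", call. = FALSE)
  if (length(regulators) == 0L) stop("empty regulator list", call. = FALSE)
  invisible(TRUE)
}

# two-sided p for a Spearman rho via the t approximation
spearman_pvalue <- function(rho, n) {
  rho <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spearman co-expression inference
#'
#' Score = |Spearman rho| between each TF and each gene; two-sided p-values by
#' the t approximation. Zero-variance genes yield score 0, p = 1.
#'
#' @inheritParams grn_infer
#' @return A `grn_fit` (all edges retained; Spearman has no intrinsic
#'   threshold).
#' @export
infer_spearman <- function(expr, regulators) {
  check_expr_regulators(expr, regulators)
  n <- ncol(expr)
  if (n < 3L) stop("Spearman inference requires >= 3 samples", call. = FALSE)
  R <- suppressWarnings(stats::cor(t(expr[regulators, , drop = FALSE]),
                                   t(expr), method = "spearman"))
  flat <- edge_universe(regulators, rownames(expr))
  rho <- R[cbind(match(flat$tf, regulators), match(flat$gene, rownames(expr)))]
  bad <- is.na(rho)
  flat$score <- abs(ifelse(bad, 0, rho))
  flat$p <- ifelse(bad, 1, spearman_pvalue(rho, n))
  new_grn_fit(flat, "spearman", "abs_spearman_rho",
              normalization_tag(expr), regulators, rownames(expr))
}

#' Mutual-information inference with empirical-CDF null (MI / MICA core)
#'
#' Composes [mi_matrix()] and [mi_edge_stats()] over all genes in the matrix,
#' then materialises directed TF-to-gene edges (both directions when both
#' members are TFs; MI itself is symmetric). Score = -log10 p; pairs at BH
#' q < `fdr` are flagged retained.
#'
#' @inheritParams grn_infer
#' @param n_bins equal-frequency bin count (default `ceiling(sqrt(n))`).
#' @param fdr false-discovery-rate threshold for the retained flag.
#' @param null null model for p-values, see [mi_edge_stats()].
#' @return A `grn_fit` with `p`, `q` columns; `extra$stats` holds the
#'   `mi_edge_stats` object.
#' @export
infer_mi <- function(expr, regulators, n_bins = NULL, fdr = 0.05,
                     null = "chisq2") {
  check_expr_regulators(expr, regulators)
  M <- mi_matrix(expr, n_bins = n_bins)
  st <- mi_edge_stats(M, null = null)
  flat <- edge_universe(regulators, rownames(expr))
  i <- cbind(match(flat$tf, rownames(M)), match(flat$gene, rownames(M)))
  flat$p <- st$p[i]
  flat$q <- st$q[i]
  flat$score <- -log10(flat$p)
  flat$retained <- flat$q < fdr
  new_grn_fit(flat, "mi", "neg_log10_p", normalization_tag(expr),
              regulators, rownames(expr),
              extra = list(stats = st, mi = M, fdr = fdr))
}

#' Random-forest importance inference (GENIE3-style)
#'
#' For each target gene, a random-forest regression of the target on all
#' other TFs; a regulator's score is the forest-averaged total variance
#' reduction contributed by splits on it (response scaled to unit variance,
#' importance divided by the sample count). The pooled genome-wide importance
#' distribution is thresholded at its `percentile`-th percentile: scores
#' below it lose the retained flag.
#'
#' @inheritParams grn_infer
#' @param ntrees trees per target forest.
#' @param mtry candidate regulators per split
#'   (default `ceiling(sqrt(p_candidates))`).
#' @param min_split minimum node size eligible for splitting.
#' @param percentile pooled importance threshold percentile (default 10).
#' @return A `grn_fit`; `extra$threshold` is the pooled cutoff.
#' @export
infer_genie3 <- function(expr, regulators, ntrees = 1000, mtry = NULL,
                         min_split = 5, percentile = 10, seed = NULL) {
  check_expr_regulators(expr, regulators)
  n <- ncol(expr)
  if (n < 2L) stop("GENIE3 inference requires >= 2 samples", call. = FALSE)
  if (length(regulators) < 2L)
    stop("need >= 2 regulators (self is excluded per target)", call. = FALSE)
  genes <- rownames(expr)
  flat <- edge_universe(regulators, genes)
  score <- stats::setNames(numeric(nrow(flat)), edge_key(flat$tf, flat$gene))
  with_seed(seed, {
    for (g in genes) {
      cand <- setdiff(regulators, g)
      if (length(cand) == 0L) next
      y <- expr[g, ]
      sdy <- stats::sd(y)
      if (sdy == 0) next
      X <- t(expr[cand, , drop = FALSE])
      m <- if (is.null(mtry)) ceiling(sqrt(length(cand))) else min(mtry, length(cand))
      imp <- rf_importance_cpp(X, y / sdy, as.integer(ntrees), as.integer(m),
                               as.integer(min_split), TRUE) / n
      score[edge_key(cand, g)] <- imp
    }
  })
  flat$score <- unname(score)
  thr <- stats::quantile(flat$score, percentile / 100, names = FALSE)
  flat$retained <- flat$score >= thr
  new_grn_fit(flat, "genie3", "rf_importance", normalization_tag(expr),
              regulators, genes, extra = list(threshold = thr))
}

#' L0L2 best-subset regression inference
#'
#' Per target gene, minimises
#' `0.5 * ||y - a - X b||^2 + gamma * sum(I(|b_j| > 0)) + lambda * sum(b_j^2)`
#' over the candidate TFs (restricted to the chromatin-accessibility prior
#' when one is given) by coordinate descent with hard thresholding, selecting
#' `(gamma, lambda)` by internal K-fold cross-validation on mean squared
#' error. The gamma path runs geometrically down from just above the value at
#' which the first coefficient enters, so the empty model is always on the
#' path; ties in CV error prefer the sparser, more ridge-penalised model.
#' Score = |b| of the selected coefficients; unselected candidates keep score
#' 0 and are not retained. Targets whose final fit fails to converge are
#' skipped and reported; the run fails only if every target is skipped.
#'
#' @inheritParams grn_infer
#' @param lambda_grid ridge penalties to cross-validate over.
#' @param n_gamma number of L0 penalties on the path per lambda.
#' @param nfolds cross-validation folds.
#' @param max_iter,tol coordinate-descent sweep cap and relative
#'   objective-decrease stopping tolerance.
#' @return A `grn_fit`; `extra$skipped` lists non-converged targets and
#'   `extra$selection` the chosen `(gamma, lambda)` per target.
#' @export
infer_l0l2 <- function(expr, regulators, prior = NULL,
                       lambda_grid = c(1e-4, 1e-2, 1), n_gamma = 8,
                       nfolds = 5, max_iter = 100, tol = 1e-8, seed = NULL) {
  check_expr_regulators(expr, regulators)
  n <- ncol(expr)
  if (n < 4L) stop("L0L2 inference requires >= 4 samples", call. = FALSE)
  genes <- rownames(expr)
  flat <- edge_universe(regulators, genes)
  score <- stats::setNames(numeric(nrow(flat)), edge_key(flat$tf, flat$gene))
  retained <- stats::setNames(logical(nrow(flat)), edge_key(flat$tf, flat$gene))
  skipped <- character(0)
  selection <- list()
  prior_keys <- if (!is.null(prior)) edge_key(prior$tf, prior$gene)
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(nfolds), n))
    for (g in genes) {
      cand <- setdiff(regulators, g)
      if (!is.null(prior)) cand <- cand[edge_key(cand, g) %in% prior_keys]
      if (length(cand) == 0L) next
      y <- expr[g, ]
      X <- t(expr[cand, , drop = FALSE])
      res <- l0l2_fit_target(X, y, folds, lambda_grid, n_gamma, max_iter, tol)
      if (is.null(res)) { skipped <- c(skipped, g); next }
      sel <- res$b != 0
      if (any(sel)) {
        k <- edge_key(cand[sel], g)
        score[k] <- abs(res$b[sel])
        retained[k] <- TRUE
      }
      selection[[g]] <- res[c("gamma", "lambda")]
    }
  })
  if (length(skipped) == length(genes))
    stop("L0L2 did not converge for any target", call. = FALSE)
  flat$score <- unname(score)
  flat$retained <- unname(retained)
  method <- if (is.null(prior)) "l0l2" else "l0l2+CA"
  new_grn_fit(flat, method, "abs_regression_coefficient",
              normalization_tag(expr), regulators, genes,
              extra = list(skipped = skipped, selection = selection))
}

# CV over (lambda, gamma path) for one target; returns final full-data fit
l0l2_fit_target <- function(X, y, folds, lambda_grid, n_gamma, max_iter, tol) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  gamma_path_for <- function(Xm, ym, lambda) {
    s <- colSums(Xm^2)
    c0 <- abs(drop(crossprod(Xm, ym)))
    gmax <- max(c0^2 / (2 * (s + 2 * lambda)), na.rm = TRUE)
    if (!is.finite(gmax) || gmax <= 0) gmax <- 1
    c(gmax * 1.01, gmax * 10^seq(-0.5, -3, length.out = n_gamma - 1L))
  }
  nfolds <- max(folds)
  grid <- expand.grid(lambda = lambda_grid, gi = seq_len(n_gamma))
  cv_mse <- matrix(0, nrow(grid), nfolds)
  ok <- TRUE
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    Xtr <- scale(X[tr, , drop = FALSE], center = TRUE, scale = FALSE)
    ytr <- y[tr] - mean(y[tr])
    Xte <- sweep(X[!tr, , drop = FALSE], 2, attr(Xtr, "scaled:center"))
    yte <- y[!tr] - mean(y[tr])
    for (lam in lambda_grid) {
      path <- gamma_path_for(Xtr, ytr, lam)
      b <- numeric(ncol(X))
      for (gi in seq_along(path)) {
        fit <- l0l2_cd_cpp(Xtr, ytr, path[gi], lam, b, max_iter, tol)
        b <- fit$b
        row <- which(grid$lambda == lam & grid$gi == gi)
        cv_mse[row, f] <- mean((yte - drop(Xte %*% b))^2)
      }
    }
  }
  mse <- rowMeans(cv_mse)
  # prefer sparser (smaller gi) then larger lambda on ties
  ord <- order(mse, grid$gi, -grid$lambda)
  best <- grid[ord[1], ]
  path <- gamma_path_for(Xc, yc, best$lambda)
  gamma <- path[best$gi]
  b <- numeric(ncol(X))
  for (gi in seq_len(best$gi)) {   # warm-started path down to the selection
    fit <- l0l2_cd_cpp(Xc, yc, path[gi], best$lambda, b, max_iter, tol)
    b <- fit$b
  }
  if (!fit$converged) return(NULL)
  list(b = drop(b), gamma = gamma, lambda = best$lambda)
}

#' Random-ranking baseline
#'
#' Emits the full TF-to-gene universe with a uniformly random permutation
#' encoded as strictly decreasing scores (no ties).
#'
#' @inheritParams grn_infer
#' @return A `grn_fit`.
#' @export
infer_random <- function(expr, regulators, seed = NULL) {
  check_expr_regulators(expr, regulators)
  flat <- edge_universe(regulators, rownames(expr))
  N <- nrow(flat)
  with_seed(seed, {
    flat$score <- sample(N) / N
  })
  new_grn_fit(flat, "random", "random_rank", normalization_tag(expr),
              regulators, rownames(expr))
}

# ---- grn_fit methods -------------------------------------------------------

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("GRN fit (%s): %d TFs x %d genes, %d scored edges, %d retained\n",
              x$method, length(x$regulators), length(x$genes),
              nrow(x$edges), sum(x$edges$retained)))
  if (!is.null(x$normalization))
    cat("  expression units:", x$normalization, "\n")
  invisible(x)
}

#' @export
summary.grn_fit <- function(object, n_top = 10, ...) {
  e <- object$edges
  out <- list(method = object$method, score_type = object$score_type,
              n_edges = nrow(e), n_retained = sum(e$retained),
              score_summary = summary(e$score),
              top = utils::head(e, n_top),
              out_degree = sort(table(e$tf[e$retained]), decreasing = TRUE))
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  cat(sprintf("GRN fit summary (%s, score = %s)\n", x$method, x$score_type))
  cat(sprintf("  %d edges in universe, %d retained\n", x$n_edges, x$n_retained))
  cat("  score distribution:\n")
  print(x$score_summary)
  cat("  top edges:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.grn_fit <- function(object, ...) {
  stats::setNames(object$edges$score,
                  paste(object$edges$tf, object$edges$gene, sep = "->"))
}

#' Plot the score distribution of a fitted network
#'
#' Histogram of edge scores with the retention boundary (smallest retained
#' score) marked.
#'
#' @param x a `grn_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.grn_fit <- function(x, ...) {
  graphics::hist(x$edges$score, breaks = 50,
                 main = sprintf("%s edge scores", x$method),
                 xlab = x$score_type, ...)
  if (any(x$edges$retained) && !all(x$edges$retained))
    graphics::abline(v = min(x$edges$score[x$edges$retained]),
                     col = "firebrick", lty = 2)
  invisible(x)
}
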