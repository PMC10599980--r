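# The scaled simulation study: ground-truth recovery (AUROC) as a function of
# sample size and network size, per inference method.

#' Run the DAG / linear-SEM simulation study
#'
#' For every combination of network size `p` and replicate, a fresh
#' ground-truth DAG (edge density `density`) with fresh SEM weights is drawn
#' and one expression matrix of `max(sample_sizes)` cells is simulated from
#' it; each sample size `n` uses the first `n` cells of that matrix (nested
#' subsamples, so the sample-size comparison is paired within replicate and
#' the Monte-Carlo variance of across-`n` contrasts is strongly reduced).
#' Every requested inference method is scored against the ground truth with
#' AUROC over all ordered non-self pairs. The benchmark world is density
#' 0.07, n in {10, 100, 1000}, 100 replicates; replicate counts are routinely
#' scaled down for desk-time runs.
#'
#' @param num_nodes integer vector of network sizes `p`.
#' @param sample_sizes integer vector of sample sizes `n`.
#' @param methods subset of `c("spearman", "mi", "genie3", "l0l2", "random")`.
#' @param density ordered-pair edge density of the ground truths.
#' @param num_replicates replicates per grid cell.
#' @param weight_range,noise_sd SEM weight magnitude range and noise sd.
#' @param seed integer seed; the whole grid is reproducible end-to-end.
#' @param method_args named list of per-method argument lists, e.g.
#'   `list(genie3 = list(ntrees = 100))`.
#' @return Object of class `grn_sim_study`: `results` (long data.frame with
#'   `method`, `n`, `p`, `replicate`, `auroc`; `NA` for failed fits) and
#'   `summary` (per-cell mean and standard error).
#' @examples
#' \donttest{
#' st <- run_simulation_study(num_nodes = 10, sample_sizes = c(10, 100),
#'                            methods = c("spearman", "random"),
#'                            num_replicates = 3, seed = 1)
#' st$summary
#' }
#' @export
run_simulation_study <- function(num_nodes = c(10, 50),
                                 sample_sizes = c(10, 100, 1000),
                                 methods = c("spearman", "mi", "genie3",
                                             "l0l2", "random"),
                                 density = 0.07, num_replicates = 100,
                                 weight_range = c(0.5, 1.5), noise_sd = 1,
                                 seed = NULL, method_args = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(sample_sizes >= 2))
  rows <- list()
  with_seed(seed, {
    for (p in num_nodes) {
      for (rep_i in seq_len(num_replicates)) {
        dag <- random_dag(p, density)
        g <- sem_grn(dag, weight_range = weight_range, noise_sd = noise_sd)
        x_full <- simulate(g, n = max(sample_sizes))
        for (n in sample_sizes) {
          x <- x_full[, seq_len(n), drop = FALSE]
          attr(x, "normalization") <- "sem-raw"
          for (m in methods) {
            a <- tryCatch({
              fit <- do.call(grn_infer,
                             c(list(expr = x, regulators = rownames(x),
                                    method = m), method_args[[m]]))
              auroc(fit, dag)
            }, error = function(e) NA_real_)
            rows[[length(rows) + 1L]] <-
              data.frame(method = m, n = n, p = p, replicate = rep_i,
                         auroc = a, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(auroc ~ method + n + p, data = results,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              se = stats::sd(v, na.rm = TRUE) /
                                                sqrt(sum(!is.na(v))),
                                              n_ok = sum(!is.na(v))))
  summary_df <- cbind(agg[c("method", "n", "p")], as.data.frame(agg$auroc))
  structure(list(results = results, summary = summary_df,
                 density = density, num_replicates = num_replicates),
            class = "grn_sim_study")
}

#' @export
print.grn_sim_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates, density %.3f\n",
              x$num_replicates, x$density))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot mean AUROC against sample size per method
#'
#' One panel per network size `p`; error bars are standard errors of the mean.
#'
#' @param x a `grn_sim_study`.
#' @param ... unused.
#' @export
plot.grn_sim_study <- function(x, ...) {
  s <- x$summary
  ps <- sort(unique(s$p))
  methods <- sort(unique(s$method))
  cols <- stats::setNames(grDevices::hcl.colors(length(methods), "Dark 3"),
                          methods)
  old <- graphics::par(mfrow = c(1, length(ps)))
  on.exit(graphics::par(old))
  for (p in ps) {
    sp <- s[s$p == p, ]
    graphics::plot(NA, xlim = range(sp$n), ylim = c(0.4, 1), log = "x",
                   xlab = "samples (n)", ylab = "mean AUROC",
                   main = sprintf("p = %d", p))
    graphics::abline(h = 0.5, lty = 3, col = "grey50")
    for (m in methods) {
      sm <- sp[sp$method == m, ]
      sm <- sm[order(sm$n), ]
      graphics::lines(sm$n, sm$mean, type = "b", col = cols[[m]], pch = 16)
      graphics::arrows(sm$n, sm$mean - sm$se, sm$n, sm$mean + sm$se,
                       angle = 90, code = 3, length = 0.03, col = cols[[m]])
    }
    graphics::legend("bottomright", legend = methods, col = cols, lty = 1,
                     pch = 16, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Export study results as long-format TSV
#' @param study a `grn_sim_study`.
#' @param path output file with columns method, n, p, replicate, auroc.
#' @return `path`, invisibly.
#' @export
write_sim_study <- function(study, path) {
  utils::write.table(study$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
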