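# Configuration-driven orchestration: load -> normalize -> restrict -> infer
# -> refine -> select -> evaluate, with a provenance manifest.

#' Validate a pipeline configuration
#'
#' A configuration is an R list (or a path to a JSON file with the same
#' structure). Recognised fields: `expression` (TSV path or matrix),
#' `format` ("tsv"/"mtx"), `row_names`/`col_names` (for mtx),
#' `normalization` ("tpm", "fpkm", "logcounts" or "none"), `gene_lengths`
#' (2-column TSV gene/length, for tpm/fpkm), `tf_list` (path with one symbol
#' per line, or character vector), `prior` (2-column TSV or
#' `regulatory_prior`), `refine` (logical), `method`, `k`, `celltype`,
#' `seed`, `out_dir`, `infer_args` (list), and an optional `evaluate` block
#' with `bootstrap_B`, `cv_repeats`, `top_frac`.
#'
#' @param config list or JSON path.
#' @return The normalised config list; errors describe the offending field.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(format = "tsv", normalization = "none", refine = FALSE,
                   method = "mi", k = 100000, seed = 1L, celltype = NA,
                   infer_args = list(), out_dir = NULL, evaluate = NULL)
  config <- utils::modifyList(defaults, config)
  for (f in c("expression", "tf_list", "prior", "gene_lengths",
              "row_names", "col_names")) {
    v <- config[[f]]
    if (is.character(v) && length(v) == 1L && !file.exists(v))
      stop("config field '", f, "': file not found: ", v, call. = FALSE)
  }
  if (is.null(config$expression)) stop("config field 'expression' is required",
                                       call. = FALSE)
  config$method <- match.arg(config$method,
                             c("mi", "spearman", "genie3", "l0l2", "random"))
  if (isTRUE(config$refine) && is.null(config$prior))
    stop("refinement requested but no prior configured", call. = FALSE)
  if (config$normalization %in% c("tpm", "fpkm") && is.null(config$gene_lengths))
    stop("normalization '", config$normalization,
         "' requires gene_lengths", call. = FALSE)
  config
}

#' Run the full inference pipeline from a configuration
#'
#' Executes load, normalize, universe restriction, inference, optional
#' chromatin-accessibility refinement, top-K selection, and (when configured)
#' bootstrap-reproducibility and split-half evaluation. Every stage failure
#' aborts with the stage name; outputs written before the failure are kept.
#'
#' @param config list or JSON path, see [validate_config()].
#' @return The run manifest (list): seeds, stage log, input descriptions and
#'   every output file. Written as `manifest.json` when `out_dir` is set.
#' @examples
#' \donttest{
#' g <- sem_grn(random_dag(20, 0.1, seed = 1), seed = 1)
#' x <- simulate(g, n = 50, seed = 2)
#' man <- run_pipeline(list(expression = x, tf_list = rownames(x),
#'                          method = "spearman", k = 100))
#' man$stages
#' }
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  manifest <- list(package_version = as.character(utils::packageVersion("micanet")),
                   seed = config$seed, config = config[setdiff(names(config),
                                                               "expression")],
                   stages = character(0), inputs = list(), outputs = character(0))
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  out <- function(path) manifest$outputs <<- c(manifest$outputs, path)

  expr <- stage("load", {
    if (is.matrix(config$expression)) config$expression
    else {
      # the stage expression evaluates in this function's frame, so plain
      # assignment updates the manifest directly
      manifest$inputs$expression <- unname(tools::md5sum(config$expression))
      read_expression(config$expression, format = config$format,
                      row_names = config$row_names,
                      col_names = config$col_names)
    }
  })
  tf_list <- stage("load", {
    if (length(config$tf_list) > 1L || !is.character(config$tf_list))
      config$tf_list
    else readLines(config$tf_list)
  })
  prior <- stage("load", {
    if (is.null(config$prior)) NULL
    else if (inherits(config$prior, "regulatory_prior")) config$prior
    else read_prior(config$prior)
  })
  expr <- stage("normalize", {
    if (config$normalization == "none") {
      if (is.null(normalization_tag(expr))) expression_matrix(expr, "external")
      else expr
    } else {
      lens <- config$gene_lengths
      if (is.character(lens)) {
        tab <- utils::read.table(lens, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        lens <- stats::setNames(tab[[2]], tab[[1]])
      }
      normalize_expression(expr, method = config$normalization,
                           gene_lengths = lens)
    }
  })
  restricted <- stage("restrict", restrict_universe(expr, prior, tf_list))
  expr <- restricted$expr
  tf_list <- restricted$tf_list
  fit <- stage("infer", {
    use_prior <- if (isTRUE(config$refine) ||
                     (config$method == "l0l2" && !is.null(prior))) prior
    do.call(grn_infer, c(list(expr = expr, regulators = tf_list,
                              method = config$method, prior = use_prior,
                              seed = config$seed),
                         config$infer_args))
  })
  network <- stage("select", select_top_edges(fit, k = config$k,
                                              celltype = config$celltype))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(config$out_dir, "network.tsv")
    write_network(network, p); out(p)
  }
  if (!is.null(config$evaluate)) {
    ev <- config$evaluate
    metrics <- stage("evaluate", {
      rows <- list()
      if (!is.null(ev$bootstrap_B)) {
        rep_m <- bootstrap_reproducibility(expr, tf_list, config$method,
                                           prior = if (isTRUE(config$refine)) prior,
                                           B = ev$bootstrap_B, k = config$k,
                                           seed = config$seed,
                                           infer_args = config$infer_args)
        rows$reproducibility <- data.frame(metric = "median_R",
                                           value = rep_m$median_R)
      }
      if (!is.null(ev$cv_repeats)) {
        cv <- split_half_cv(expr, tf_list, config$method,
                            prior = if (isTRUE(config$refine)) prior,
                            repeats = ev$cv_repeats,
                            top_frac = ev$top_frac %||% 0.01,
                            seed = config$seed,
                            infer_args = config$infer_args)
        rows$cv <- data.frame(metric = c("median_auprc", "median_inv_l2"),
                              value = c(cv$median_auprc, cv$median_inv_l2))
      }
      do.call(rbind, rows)
    })
    if (!is.null(config$out_dir) && !is.null(metrics)) {
      p <- file.path(config$out_dir, "metrics.tsv")
      utils::write.table(metrics, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out(p)
    }
    manifest$metrics <- metrics
  }
  manifest$network <- network
  if (!is.null(config$out_dir)) {
    p <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest[c("package_version", "seed", "stages",
                                    "inputs", "outputs")],
                         p, auto_unbox = TRUE, pretty = TRUE)
    out(p)
  }
  invisible(manifest)
}
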