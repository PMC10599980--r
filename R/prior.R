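# Chromatin-accessibility prior: nearest-TSS assignment of accessible motif
# hits, the signed strand-aware distance window, and prior summaries.

#' Construct a regulatory prior from (tf, gene) pairs
#'
#' @param pairs data.frame with character columns `tf` and `gene`;
#'   duplicates are collapsed.
#' @param details optional per-pair supporting-region table.
#' @return Object of class `regulatory_prior` (a data.frame).
#' @export
regulatory_prior <- function(pairs, details = NULL) {
  stopifnot(is.data.frame(pairs), all(c("tf", "gene") %in% names(pairs)))
  pairs <- unique(data.frame(tf = as.character(pairs$tf),
                             gene = as.character(pairs$gene),
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$tf, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, details = details,
            class = c("regulatory_prior", "data.frame"))
}

#' @export
print.regulatory_prior <- function(x, ...) {
  cat(sprintf("Regulatory prior: %d TF-gene pairs (%d TFs, %d genes)\n",
              nrow(x), length(unique(x$tf)), length(unique(x$gene))))
  invisible(x)
}

#' Read a motif-hit table (BED6-derived)
#'
#' Six tab-separated columns without header: chrom, start (0-based),
#' end (exclusive), TF name, score, strand.
#'
#' @param path input file.
#' @return data.frame with those columns.
#' @export
read_motif_hits <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "tf",
                                        "score", "strand"))
  if (any(df$start >= df$end)) stop("motif hit with start >= end", call. = FALSE)
  df
}

#' Read a TSS annotation table
#'
#' Four tab-separated columns without header: gene, chrom, TSS position
#' (0-based), strand (+/-).
#'
#' @param path input file.
#' @return data.frame with those columns.
#' @export
read_tss <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("gene", "chrom", "tss", "strand"))
  if (anyDuplicated(df$gene)) stop("duplicate gene labels in TSS table", call. = FALSE)
  df
}

#' Build the possible-regulation network from accessible motif hits
#'
#' Each motif hit is represented by its interval midpoint and assigned to the
#' gene with the nearest TSS on the same chromosome (ties in absolute distance
#' broken by lexicographic gene label). The signed TSS-relative distance is
#' strand-aware: negative means upstream of the TSS in the gene's reading
#' direction. A (TF, gene) pair is retained iff that distance lies within
#' `[-window_upstream_bp, +window_downstream_bp]`; the default window reflects
#' the promoter-proximal band observed in blastocyst accessibility data.
#' Hits on chromosomes absent from the TSS table are skipped and counted.
#'
#' @param hits motif-hit data.frame (see [read_motif_hits()]).
#' @param tss TSS data.frame (see [read_tss()]).
#' @param window_upstream_bp,window_downstream_bp window bounds in bp.
#' @return A `regulatory_prior`; per-pair supporting regions with signed
#'   distances are in `attr(, "details")`, the skipped-hit count in
#'   `attr(, "skipped")`.
#' @export
build_prior <- function(hits, tss, window_upstream_bp = 5000,
                        window_downstream_bp = 10000) {
  if (nrow(hits) == 0L || nrow(tss) == 0L)
    stop("empty motif-hit or TSS table", call. = FALSE)
  mid <- (hits$start + hits$end) / 2
  dist_signed <- rep(NA_real_, nrow(hits))
  gene_hit <- rep(NA_character_, nrow(hits))
  for (chr in unique(hits$chrom)) {
    hi <- which(hits$chrom == chr)
    ti <- which(tss$chrom == chr)
    if (length(ti) == 0L) next
    sub <- tss[ti, , drop = FALSE]
    sub <- sub[order(sub$gene), , drop = FALSE]   # lexicographic tie-break
    for (h in hi) {
      d_abs <- abs(mid[h] - sub$tss)
      j <- which.min(d_abs)                       # first = smallest label on ties
      d <- mid[h] - sub$tss[j]
      if (sub$strand[j] == "-") d <- -d
      dist_signed[h] <- d
      gene_hit[h] <- sub$gene[j]
    }
  }
  assigned <- !is.na(gene_hit)
  skipped <- sum(!assigned)
  in_window <- assigned & dist_signed >= -window_upstream_bp &
    dist_signed <= window_downstream_bp
  details <- data.frame(tf = hits$tf[in_window], gene = gene_hit[in_window],
                        chrom = hits$chrom[in_window],
                        start = hits$start[in_window], end = hits$end[in_window],
                        distance = dist_signed[in_window],
                        stringsAsFactors = FALSE)
  prior <- regulatory_prior(details[, c("tf", "gene")], details = details)
  attr(prior, "skipped") <- skipped
  prior
}

#' Summarise a regulatory prior
#'
#' @param prior a `regulatory_prior`.
#' @return List with `tfs_per_gene` (named counts of distinct TFs per gene),
#'   `median_tfs_per_gene`, and `targets_per_tf`.
#' @export
prior_summary <- function(prior) {
  tpg <- tapply(prior$tf, prior$gene, function(x) length(unique(x)))
  tpt <- tapply(prior$gene, prior$tf, function(x) length(unique(x)))
  list(tfs_per_gene = c(tpg),
       median_tfs_per_gene = stats::median(as.numeric(tpg)),
       targets_per_tf = c(tpt))
}

#' Write / read a prior as 2-column TSV
#' @param prior a `regulatory_prior`.
#' @param path output/input file.
#' @return `path` invisibly / a `regulatory_prior`.
#' @export
write_prior <- function(prior, path) {
  utils::write.table(as.data.frame(prior)[, c("tf", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  regulatory_prior(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
}
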