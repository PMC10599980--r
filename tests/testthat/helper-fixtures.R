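# fixtures built in code: tiny DAGs, expression matrices and genomic tables

named_matrix <- function(data, nrow, gene_prefix = "g", sample_prefix = "c") {
  m <- matrix(data, nrow = nrow)
  dimnames(m) <- list(sprintf("%s%02d", gene_prefix, seq_len(nrow)),
                      sprintf("%s%03d", sample_prefix, seq_len(ncol(m))))
  m
}

# three-gene chain a -> b -> c with fixed weights
chain_dag <- function() {
  grn_dag(c("a", "b", "c"),
          data.frame(from = c("a", "b"), to = c("b", "c")))
}

chain_sem <- function(b_ab = 2, b_bc = -1.5, noise_sd = 1) {
  dag <- chain_dag()
  w <- data.frame(from = c("a", "b"), to = c("b", "c"), b = c(b_ab, b_bc))
  structure(list(dag = dag, weights = w,
                 intercepts = c(a = 0, b = 0, c = 0), noise_sd = noise_sd),
            class = "sem_grn")
}

# strongly coupled 5-gene matrix: every gene a monotone function of a latent
coupled_expr <- function(n = 40, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  m <- rbind(z, 2 * z + 0.01 * rnorm(n), exp(z), z^3, -z)
  dimnames(m) <- list(paste0("g0", 1:5), sprintf("c%03d", seq_len(n)))
  m + 0  # drop deparse-level names
}

# small motif-hit / TSS fixture tables
fixture_tss <- function() {
  data.frame(gene = c("geneA", "geneB", "geneC"),
             chrom = c("chr1", "chr1", "chr2"),
             tss = c(10000L, 50000L, 20000L),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

fixture_hits <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
             start = c(11950L, 3900L, 51950L, 19500L, 100L),
             end = c(12050L, 4100L, 52050L, 19600L, 200L),
             tf = c("TF1", "TF2", "TF3", "TF1", "TF4"),
             score = c(5, 4, 3, 2, 1),
             strand = c("+", "+", "-", "+", "+"),
             stringsAsFactors = FALSE)
}

random_network <- function(tfs, genes, k, seed) {
  set.seed(seed)
  u <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  u <- u[u$tf != u$gene, ]
  u <- u[sample(nrow(u), k), ]
  u$score <- runif(k)
  u$retained <- TRUE
  structure(list(edges = u[order(-u$score, u$tf, u$gene), ],
                 method = "fixture", normalization = "external",
                 celltype = NA_character_, refined = FALSE, k = k),
            class = "grn_network")
}
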