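# independent brute-force oracles shared across test files

# direct sum p * log2(p / (p1 p2)) over a joint count table
mi_bruteforce <- function(tab) {
  p <- tab / sum(tab)
  p1 <- rowSums(p); p2 <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (p1[i] * p2[j]))
  as.numeric(s)
}

# exhaustive AUROC: fraction of positive-negative comparisons won, ties 1/2
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive average precision from the sorted PR curve
ap_bruteforce <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  hits <- 0; s <- 0
  for (i in seq_along(lab)) {
    if (lab[i]) { hits <- hits + 1; s <- s + hits / i }
  }
  s / sum(lab)
}
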