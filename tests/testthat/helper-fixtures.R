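## Small fixtures built in code; no files are shipped.

tinyManifest <- function() {
  data.frame(
    probe_id = c("cg000001", "cg000002", "cg000003"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 250L, 500L),
    strand = c("+", "-", "*"),
    gene = c("TCF7", "TCF7", ""),
    region_category = c("TSS200", "Body", "Intergenic"),
    island_relation = c("Island", "Shore", "OpenSea"),
    stringsAsFactors = FALSE)
}

## manifest with n single-probe rows spread over two chromosomes
randomManifest <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    probe_id = sprintf("cg%06d", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    strand = sample(c("+", "-", "*"), n, replace = TRUE),
    gene = ifelse(runif(n) < 0.2, "", sprintf("G%03d", sample(50, n, TRUE))),
    region_category = "Body",
    island_relation = sample(c("Island", "Shore", "Shelf", "OpenSea"), n,
                             replace = TRUE),
    stringsAsFactors = FALSE)
}

## brute-force Benjamini-Hochberg for the oracle tests
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## exact Fisher p by hypergeometric enumeration (two-sided, as fisher.test:
## sum of table probabilities <= observed probability)
bruteFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
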