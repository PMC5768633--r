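# Shared fixture builders; everything is generated in code at test time.

# Tiny annotation table with explicit coordinates and biotypes.
make_annotation <- function(tx = c("t1", "t2", "t3", "t4"),
                            gene = c("g1", "g1", "g2", "g3"),
                            chrom = c("chr1", "chr1", "chr1", "chr2"),
                            start = c(100, 150, 5000, 100),
                            end = c(200, 400, 6000, 900),
                            biotype = c("protein_coding", "protein_coding",
                                        "lincRNA", "antisense")) {
  data.frame(transcript_id = tx, gene_id = gene, chromosome = chrom,
             start = start, end = end,
             strand = rep("+", length(tx)), biotype = biotype,
             stringsAsFactors = FALSE)
}

# Small four-group design.
make_design <- function(n_per_group = 4) {
  groups <- c("LH", "NLH", "Ctrl", "HC")
  data.frame(sample_id = paste0(rep(groups, each = n_per_group), "_",
                                seq_len(n_per_group)),
             group = rep(groups, each = n_per_group),
             stringsAsFactors = FALSE)
}

# Brute-force best 2-means partition by enumerating all 2-colourings.
brute_force_kmeans2 <- function(x) {
  n <- nrow(x)
  best <- NULL
  best_ss <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (length(unique(lab)) < 2) next
    ss <- sum(vapply(unique(lab), function(l) {
      g <- x[lab == l, , drop = FALSE]
      sum(scale(g, scale = FALSE)^2)
    }, 0))
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- lab }
  }
  list(labels = best, inertia = best_ss)
}

# Hand-computed pooled-variance two-sample t statistic.
pooled_t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Pearson r from the raw covariance/variance sums.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Hypergeometric upper tail P(X >= k) by direct enumeration.
hyper_tail_oracle <- function(k, K, n, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
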