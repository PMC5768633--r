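make_gene_mat <- function(rows) {
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  attr(mat, "level") <- "gene"
  mat
}

test_that("Pearson r matches the covariance-formula oracle", {
  gm <- make_gene_mat(list(l1 = c(1, 2, 3, 4), m1 = c(2, 4, 6, 8),
                           m2 = c(1, 2, 3, 5)))
  cand <- correlate_pairs(gm, "l1", c("m1", "m2"))
  r_perfect <- cand$r[cand$mrna_gene == "m1"]
  expect_equal(r_perfect, 1)
  r_near <- cand$r[cand$mrna_gene == "m2"]
  expect_equal(r_near, pearson_oracle(c(1, 2, 3, 4), c(1, 2, 3, 5)))
  expect_equal(round(r_near, 4), 0.9827)
  expect_equal(round(r_near^2, 4), 0.9657)
  expect_equal(cand$p, vapply(seq_len(nrow(cand)), function(i)
    cor.test(gm["l1", ], gm[cand$mrna_gene[i], ])$p.value, 0),
    tolerance = 1e-10)
})

test_that("constant genes are skipped with a warning, never NaN edges", {
  gm <- make_gene_mat(list(l1 = c(1, 2, 3, 4), m1 = c(5, 5, 5, 5)))
  expect_warning(cand <- correlate_pairs(gm, "l1", "m1"), "zero-variance")
  expect_equal(nrow(cand), 0)
  expect_error(correlate_pairs(gm, "l1", "l1"), "overlap")
  expect_error(correlate_pairs(gm, "l1", "m1", samples = c("s1", "s2")),
               ">= 3")
})

test_that("edge filter thresholds are inclusive on r2, strict on p", {
  n <- 8
  r_vals <- c(-0.96, sqrt(0.89), sqrt(0.9), 0.99)
  r2_vals <- c(0.9216, 0.89, 0.9, 0.9801)   # r^2 = 0.9 exactly on the bound
  p_vals <- 2 * pt(-abs(r_vals * sqrt((n - 2) / (1 - r2_vals))), n - 2)
  cand <- data.frame(lnc_gene = paste0("l", 1:4),
                     mrna_gene = paste0("m", 1:4),
                     r = r_vals, r_squared = r2_vals, p = p_vals)
  kept <- filter_edges(cand)
  expect_setequal(kept$lnc_gene, c("l1", "l3", "l4"))
  expect_equal(kept$sign[kept$lnc_gene == "l1"], "negative")
  # the worked example: r = -0.96 at n = 8 has p ~ 1.6e-4 < 0.01
  expect_lt(p_vals[1], 0.01)
})

test_that("at n = 8 the r2 threshold alone implies the p threshold", {
  set.seed(12)
  n <- 8
  r <- runif(10000, -1, 1)
  p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  cand <- data.frame(lnc_gene = paste0("l", 1:10000),
                     mrna_gene = paste0("m", 1:10000),
                     r = r, r_squared = r^2, p = p)
  both <- filter_edges(cand, r2_min = 0.9, p_max = 0.01)
  r2_only <- filter_edges(cand, r2_min = 0.9, p_max = 1)
  expect_equal(both$lnc_gene, r2_only$lnc_gene)
})

test_that("cis/trans classification follows the 1000-kb boundary rule", {
  ann <- make_annotation(
    tx = paste0("t", 1:5), gene = paste0("g", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(1000000, 1900000, 2005001, 500, 2005000),
    end = c(1005000, 1950000, 2100000, 900, 2100000),
    biotype = c("lincRNA", rep("protein_coding", 4)))
  edges <- data.frame(lnc_gene = rep("g1", 4),
                      mrna_gene = c("g2", "g4", "g3", "g5"),
                      r = 0.99, r_squared = 0.98, p = 1e-5)
  out <- classify_cis_trans(edges, ann)
  expect_equal(out$distance_bp[1], 895000)      # worked boundary-gap example
  expect_equal(out$locality[1], "cis")
  expect_equal(out$locality[2], "trans")        # different chromosome
  expect_true(is.na(out$distance_bp[2]))
  expect_equal(out$distance_bp[3], 1000001)     # 1 bp beyond the window
  expect_equal(out$locality[3], "trans")
  expect_equal(out$distance_bp[4], 1000000)     # exactly 1000 kb: inclusive
  expect_equal(out$locality[4], "cis")
  expect_error(classify_cis_trans(
    data.frame(lnc_gene = "g1", mrna_gene = "gX"), ann), "missing")
})

test_that("network is deduplicated, bipartite, and summarised", {
  edges <- data.frame(lnc_gene = c("l1", "l1", "l2"),
                      mrna_gene = c("m1", "m1", "m2"),
                      r = 0.99, r_squared = 0.98, p = 1e-5)
  net <- build_network(edges, n_lncrna_universe = 10)
  expect_equal(net$summary$n_edges, 2)
  expect_equal(net$summary$frac_lncrna_connected, 0.2)
  expect_true(all(net$edges$lnc_gene %in%
                    net$nodes$gene_id[net$nodes$role == "lncRNA"]))
  bad <- data.frame(lnc_gene = c("l1", "m1"), mrna_gene = c("m1", "x"),
                    r = 1, r_squared = 1, p = 0)
  expect_error(build_network(bad), "both")
  empty <- build_network(edges[0, ])
  expect_equal(empty$summary$n_edges, 0)
  expect_equal(empty$summary$frac_lncrna_connected, 0)
})

test_that("bipartiteness holds for random edge tables", {
  set.seed(3)
  for (i in 1:20) {
    edges <- data.frame(
      lnc_gene = sample(paste0("l", 1:6), 12, replace = TRUE),
      mrna_gene = sample(paste0("m", 1:6), 12, replace = TRUE),
      r = runif(12, -1, 1))
    edges$r_squared <- edges$r^2
    edges$p <- runif(12)
    net <- build_network(edges)
    expect_false(anyDuplicated(net$edges[, c("lnc_gene", "mrna_gene")]) > 0)
    expect_length(intersect(net$edges$lnc_gene, net$edges$mrna_gene), 0)
    g <- igraph::graph_from_data_frame(
      net$edges[, c("lnc_gene", "mrna_gene")], directed = FALSE)
    expect_true(igraph::bipartite_mapping(g)$res)
  }
})

test_that("planted pairs are recovered at the Monte-Carlo oracle rate", {
  # oracle: per-pair recovery probability for the latent-factor model at
  # rho = 0.98, n = 8, threshold r^2 >= 0.9, by direct simulation
  set.seed(555)
  a <- sqrt(0.98 / 0.02)
  oracle_sens <- mean(replicate(20000, {
    f <- rnorm(8)
    cor(a * f + rnorm(8), a * f + rnorm(8))^2 >= 0.9
  }))

  n_pairs <- 150
  cfg <- sim_config(n_per_group = 2, n_transcripts = 400, n_de = 0,
                    n_pairs = n_pairs, pair_r = 0.98, noise_sd = 0.5,
                    seed = 14)
  sim <- simulate_expression(cfg)  # 8 samples
  truth <- sim$truth
  gm <- gene_level_average(sim$matrix, sim$annotation)
  lnc_genes_p <- truth$gene_id[seq_len(n_pairs)]
  mrna_pool <- setdiff(unique(truth$gene_id[-seq_len(n_pairs)]),
                       lnc_genes_p)
  cand <- suppressWarnings(correlate_pairs(gm, lnc_genes_p, mrna_pool))
  edges <- filter_edges(cand)
  net <- build_network(edges, n_lncrna_universe = n_pairs)
  planted_key <- paste(truth$gene_id[seq_len(n_pairs)],
                       truth$partner_gene[seq_len(n_pairs)])
  got_key <- paste(net$edges$lnc_gene, net$edges$mrna_gene)
  sens <- mean(planted_key %in% got_key)
  expect_lt(abs(sens - oracle_sens),
            3 * sqrt(oracle_sens * (1 - oracle_sens) / n_pairs))
  # false edges across the null lnc x mrna combinations stay rare
  n_null <- length(lnc_genes_p) * length(mrna_pool) - n_pairs
  n_false <- sum(!(got_key %in% planted_key))
  expect_lt(n_false / n_null, 0.01)
  expect_equal(net$summary$frac_lncrna_connected,
               length(unique(net$edges$lnc_gene)) / n_pairs)
})

test_that("edge recovery is monotone in the planted correlation", {
  sens <- vapply(c(0.8, 0.95, 0.995), function(rho) {
    cfg <- sim_config(n_per_group = 2, n_transcripts = 120, n_de = 0,
                      n_pairs = 50, pair_r = rho, noise_sd = 0.5,
                      seed = 100)
    sim <- simulate_expression(cfg)
    truth <- sim$truth
    r2 <- vapply(1:50, function(k) {
      cor(sim$matrix[k, ], sim$matrix[50 + k, ])^2
    }, 0)
    mean(r2 >= 0.9)
  }, 0)
  expect_true(all(diff(sens) >= 0))
})

test_that("network exports round-trip and GraphML is well-formed", {
  edges <- data.frame(lnc_gene = c("l1", "l2"), mrna_gene = c("m1", "m2"),
                      r = c(0.99, -0.97), r_squared = c(0.9801, 0.9409),
                      p = c(1e-5, 2e-5),
                      sign = c("positive", "negative"),
                      locality = c("cis", "trans"),
                      distance_bp = c(5000, NA))
  net <- build_network(edges)
  d <- withr::local_tempdir()
  files <- export_network(net, d)
  expect_equal(length(readLines(files["sif"])), 2)
  expect_match(readLines(files["sif"])[1], "^l1 coexp m1$")
  back <- import_network(files["nodes_tsv"], files["edges_tsv"])
  expect_equal(back$edges[order(back$edges$lnc_gene), ],
               net$edges[order(net$edges$lnc_gene), ])
  g <- igraph::read_graph(files["graphml"], format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_setequal(igraph::vertex_attr(g, "role"),
                  c("lncRNA", "lncRNA", "mRNA", "mRNA"))
  expect_error(export_network(net, d, formats = "dot"), "unknown format")
})

test_that("single-edge network writes a single SIF line", {
  net <- build_network(data.frame(lnc_gene = "l1", mrna_gene = "m1",
                                  r = 1, r_squared = 1, p = 0))
  d <- withr::local_tempdir()
  f <- export_network(net, d, formats = "sif")
  expect_equal(readLines(f), "l1 coexp m1")
})
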