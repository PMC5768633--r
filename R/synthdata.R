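#' Simulation configuration for synthetic expression data
#'
#' Collects the knobs of the synthetic FPKM generator: the four-group design
#' size, transcriptome size and lncRNA fraction, the planted differential
#' expression effect, the measurement noise, and the target population
#' correlation of planted lncRNA--mRNA pairs.
#'
#' @param n_per_group samples per group (LH, NLH, Ctrl, HC). Default 4,
#'   matching a four-mice-per-group RNA-seq design.
#' @param n_transcripts total number of transcripts simulated.
#' @param frac_lncrna proportion of genes assigned a lncRNA biotype, in (0,1).
#' @param n_de number of transcripts with a planted LH expression shift.
#' @param n_pairs number of planted lncRNA--mRNA co-expressed gene pairs.
#' @param de_effect planted mean shift on the log2 scale; DE transcripts are
#'   multiplied by \code{2^de_effect} (up) or \code{2^-de_effect} (down) in LH.
#' @param noise_sd additive measurement noise standard deviation on the FPKM
#'   scale.
#' @param pair_r target population Pearson correlation for planted pairs,
#'   in (-1,1).
#' @param seed integer seed; every generator is a pure function of its
#'   configuration and seed.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_per_group = 4L, n_transcripts = 400L,
                       frac_lncrna = 0.2, n_de = 40L, n_pairs = 10L,
                       de_effect = 3, noise_sd = 0.5, pair_r = 0.98,
                       seed = 1L) {
  stopifnot(n_per_group >= 2, n_transcripts > 0, n_de >= 0, n_pairs >= 0)
  if (frac_lncrna <= 0 || frac_lncrna >= 1)
    stop("frac_lncrna must lie in (0, 1)")
  if (abs(pair_r) >= 1) stop("pair_r must lie in (-1, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_transcripts = as.integer(n_transcripts),
                 frac_lncrna = frac_lncrna, n_de = as.integer(n_de),
                 n_pairs = as.integer(n_pairs), de_effect = de_effect,
                 noise_sd = noise_sd, pair_r = pair_r,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate shuttle-box escape behavior for two phenotype clusters
#'
#' Draws per-mouse escape-failure counts and mean escape latencies from two
#' bivariate Gaussian clusters (diagonal covariance) representing helpless
#' (LH) and non-helpless (NLH) mice, plus an optional control group drawn
#' from the NLH cluster. Failures are rounded to integers and clipped to the
#' 30-trial protocol range [0, 30]; latencies are clipped to the 10-s
#' foot-shock cap [0, 10].
#'
#' @param n_lh,n_nlh,n_ctrl group sizes (default 14/17/10).
#' @param cluster_means list of two numeric length-2 vectors
#'   \code{c(failures, latency)} for the LH and NLH clusters.
#' @param cluster_sds list of two numeric length-2 vectors of standard
#'   deviations (>= 0) in the same order.
#' @param seed integer seed.
#'
#' @return A list with \code{behavior}, a data.frame with columns
#'   \code{mouse_id}, \code{group}, \code{failures}, \code{latency_s}, and
#'   \code{truth}, a data.frame with \code{mouse_id}, \code{true_class}.
#'   Control mice have group \code{"Ctrl"} and no truth row.
#' @export
simulate_behavior <- function(n_lh = 14L, n_nlh = 17L, n_ctrl = 10L,
                              cluster_means = list(LH = c(25, 8),
                                                   NLH = c(5, 3)),
                              cluster_sds = list(LH = c(3, 1),
                                                 NLH = c(3, 1)),
                              seed = 1L) {
  stopifnot(n_lh >= 0, n_nlh >= 0, n_ctrl >= 0)
  means <- lapply(cluster_means, as.numeric)
  sds <- lapply(cluster_sds, as.numeric)
  if (any(!is.finite(unlist(means))) || any(!is.finite(unlist(sds))))
    stop("cluster means and sds must be finite")
  if (any(unlist(sds) < 0)) stop("cluster sds must be non-negative")

  withr::with_seed(seed, {
    draw <- function(n, mu, sd) {
      cbind(stats::rnorm(n, mu[1], sd[1]), stats::rnorm(n, mu[2], sd[2]))
    }
    lh <- draw(n_lh, means[[1]], sds[[1]])
    nlh <- draw(n_nlh, means[[2]], sds[[2]])
    ctrl <- draw(n_ctrl, means[[2]], sds[[2]])
    pts <- rbind(lh, nlh, ctrl)
    grp <- rep(c("LH", "NLH", "Ctrl"), c(n_lh, n_nlh, n_ctrl))
    behavior <- data.frame(
      mouse_id = sprintf("m%02d", seq_len(nrow(pts))),
      group = grp,
      failures = pmin(30L, pmax(0L, as.integer(round(pts[, 1])))),
      latency_s = pmin(10, pmax(0, pts[, 2])),
      stringsAsFactors = FALSE)
    truth <- behavior[behavior$group != "Ctrl", c("mouse_id", "group")]
    names(truth)[2] <- "true_class"
    rownames(truth) <- NULL
    list(behavior = behavior, truth = truth)
  })
}

# lncRNA subclasses counted together as "lncRNA" in summaries
LNCRNA_BIOTYPES <- c("lincRNA", "antisense", "sense_intronic",
                     "sense_overlapping", "bidirectional_promoter_lncRNA",
                     "processed_transcript")

BIOTYPE_VOCAB <- c(LNCRNA_BIOTYPES, "protein_coding", "novel", "pseudogene",
                   "TEC", "miscRNA", "snoRNA", "scaRNA")

#' Simulate a four-group FPKM expression matrix with planted truth
#'
#' Generates a transcript-by-sample FPKM matrix for the groups LH, NLH, Ctrl
#' and HC with three kinds of planted structure: (i) differentially expressed
#' transcripts whose LH samples are shifted multiplicatively by
#' \code{2^de_effect} (half up, half down); (ii) lncRNA--mRNA gene pairs
#' coupled through a shared per-sample latent factor so that their population
#' Pearson correlation equals \code{pair_r}; and (iii) a mixed-biotype
#' annotation in which planted pairs are placed at controlled genomic
#' distances -- half within 1 Mb on one chromosome (cis in truth) and half on
#' different chromosomes (trans in truth).
#'
#' Baseline abundances are log-normal (meanlog 1, sdlog 1.5), a heavy-tailed
#' positive distribution resembling FPKM. Additive Gaussian noise with
#' standard deviation \code{noise_sd} is applied and values are clipped at 0
#' (FPKM is non-negative). With \code{noise_sd = 0} a planted pair is an
#' exact affine function of the latent factor, so its sample correlation is
#' exactly 1.
#'
#' The latent-factor coupling is \eqn{x = \mu_x + a f + \epsilon_x},
#' \eqn{y = \mu_y + b f + \epsilon_y} with \eqn{f \sim N(0,1)} per sample and
#' loadings \eqn{a = \sigma \sqrt{|r| / (1 - |r|)}}, \eqn{b = \mathrm{sign}(r)
#' \, a}, which gives population correlation
#' \eqn{\mathrm{sign}(r) \, a^2 / (a^2 + \sigma^2) = r} exactly when the
#' noise sd is \eqn{\sigma}. Planted features (DE transcripts and pair
#' members) draw their baselines from a narrower log-normal centred on
#' clearly expressed values (meanlog 2, sdlog 0.5), emulating validation on
#' robustly expressed transcripts and keeping the planted signal away from
#' the zero-clipping floor.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list with \code{matrix} (transcript-level FPKM matrix, samples
#'   in columns), \code{annotation} (see \code{\link{read_annotation}} for
#'   the column contract), \code{design} (data.frame sample_id, group) and
#'   \code{truth} (data.frame with transcript_id, gene_id, de_direction,
#'   partner_gene, population_r, pair_locality).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_planted <- cfg$n_de + 2L * cfg$n_pairs
  if (cfg$n_transcripts < n_planted)
    stop("n_transcripts (", cfg$n_transcripts,
         ") is smaller than the number of planted features (", n_planted, ")")

  groups <- c("LH", "NLH", "Ctrl", "HC")
  n_s <- cfg$n_per_group * 4L
  sample_id <- paste0(rep(groups, each = cfg$n_per_group), "_",
                      rep(seq_len(cfg$n_per_group), times = 4L))
  design <- data.frame(sample_id = sample_id,
                       group = rep(groups, each = cfg$n_per_group),
                       stringsAsFactors = FALSE)

  withr::with_seed(cfg$seed, {
    nt <- cfg$n_transcripts
    tx_id <- sprintf("TX%05d", seq_len(nt))

    # transcript -> gene map: ~15% of genes carry two transcripts so that
    # gene-level averaging is exercised; planted features stay 1:1
    gene_of <- sprintf("G%05d", seq_len(nt))
    n_free <- nt - n_planted
    if (n_free >= 4) {
      idx_free <- (n_planted + 1L):nt
      n_merge <- floor(length(idx_free) * 0.15)
      if (n_merge >= 2) {
        merged <- sample(idx_free, 2L * floor(n_merge / 2))
        half <- length(merged) / 2
        gene_of[merged[seq_len(half) + half]] <- gene_of[merged[seq_len(half)]]
      }
    }

    base <- stats::rlnorm(nt, meanlog = 1, sdlog = 1.5)
    if (cfg$n_de > 0)
      base[seq_len(cfg$n_de)] <- stats::rlnorm(cfg$n_de, meanlog = 2,
                                               sdlog = 0.5)
    if (cfg$n_pairs > 0) {
      # pair members sit well above the zero-clipping floor so the
      # latent-factor population-correlation contract holds
      pr <- cfg$n_de + seq_len(2L * cfg$n_pairs)
      base[pr] <- stats::rlnorm(length(pr), meanlog = 3, sdlog = 0.3)
    }
    mat <- matrix(rep(base, n_s), nrow = nt, ncol = n_s,
                  dimnames = list(tx_id, sample_id))

    # planted DE: first n_de transcripts, alternating up/down in LH
    de_dir <- rep("null", nt)
    if (cfg$n_de > 0) {
      de_idx <- seq_len(cfg$n_de)
      de_dir[de_idx] <- rep(c("up", "down"), length.out = cfg$n_de)
      lh_cols <- design$group == "LH"
      shift <- ifelse(de_dir[de_idx] == "up", 2^cfg$de_effect,
                      2^(-cfg$de_effect))
      mat[de_idx, lh_cols] <- mat[de_idx, lh_cols] * shift
    }

    # planted lncRNA-mRNA pairs via one shared latent factor per sample
    partner <- rep(NA_character_, nt)
    pop_r <- rep(NA_real_, nt)
    pair_rows <- integer(0)
    if (cfg$n_pairs > 0) {
      pair_rows <- cfg$n_de + seq_len(2L * cfg$n_pairs)
      lnc_rows <- pair_rows[seq_len(cfg$n_pairs)]
      mrna_rows <- pair_rows[cfg$n_pairs + seq_len(cfg$n_pairs)]
      sigma <- cfg$noise_sd
      rr <- cfg$pair_r
      a <- if (sigma > 0) sigma * sqrt(abs(rr) / (1 - abs(rr))) else 1
      b <- sign(rr) * a
      if (rr == 0) b <- a * 0
      for (k in seq_len(cfg$n_pairs)) {
        f <- stats::rnorm(n_s)
        mat[lnc_rows[k], ] <- base[lnc_rows[k]] + a * f
        mat[mrna_rows[k], ] <- base[mrna_rows[k]] + b * f
      }
      partner[lnc_rows] <- gene_of[mrna_rows]
      partner[mrna_rows] <- gene_of[lnc_rows]
      pop_r[pair_rows] <- cfg$pair_r
    }

    if (cfg$noise_sd > 0) {
      mat <- mat + matrix(stats::rnorm(nt * n_s, 0, cfg$noise_sd), nrow = nt)
    }
    mat[mat < 0] <- 0

    ann <- .simulate_annotation(tx_id, gene_of, cfg)
    truth <- data.frame(transcript_id = tx_id, gene_id = gene_of,
                        de_direction = de_dir, partner_gene = partner,
                        population_r = pop_r,
                        pair_locality = NA_character_,
                        stringsAsFactors = FALSE)
    if (cfg$n_pairs > 0) {
      gs <- gene_spans(ann)
      for (i in which(!is.na(partner))) {
        g1 <- gs[gs$gene_id == gene_of[i], ]
        g2 <- gs[gs$gene_id == partner[i], ]
        truth$pair_locality[i] <-
          if (g1$chromosome == g2$chromosome &&
              .span_gap(g1$start, g1$end, g2$start, g2$end) <= 1e6)
            "cis" else "trans"
      }
    }
    list(matrix = mat, annotation = ann, design = design, truth = truth)
  })
}

# Assigns chromosomes, spans, strands and biotypes. Planted pairs are placed
# alternately cis (same chromosome, gap << 1 Mb) and trans (different
# chromosomes) so both labels occur in truth.
.simulate_annotation <- function(tx_id, gene_of, cfg) {
  nt <- length(tx_id)
  chroms <- paste0("chr", 1:19)
  chrom <- sample(chroms, nt, replace = TRUE)
  start <- sample.int(1e8, nt, replace = TRUE)
  width <- sample(500:50000, nt, replace = TRUE)
  strand <- sample(c("+", "-"), nt, replace = TRUE)

  n_pairs <- cfg$n_pairs
  if (n_pairs > 0) {
    lnc_rows <- cfg$n_de + seq_len(n_pairs)
    mrna_rows <- cfg$n_de + n_pairs + seq_len(n_pairs)
    for (k in seq_len(n_pairs)) {
      i <- lnc_rows[k]; j <- mrna_rows[k]
      if (k %% 2 == 1) {            # cis: same chromosome, ~100-500 kb apart
        chrom[j] <- chrom[i]
        start[j] <- start[i] + width[i] + sample(1e5:5e5, 1)
      } else {                      # trans: force different chromosome
        chrom[j] <- chroms[(match(chrom[i], chroms) %% length(chroms)) + 1L]
      }
    }
  }

  # biotypes assigned per gene; planted lncRNA partners get lncRNA classes,
  # planted mRNA partners protein_coding, the rest a realistic mixture
  genes <- unique(gene_of)
  n_lnc <- max(1L, round(cfg$frac_lncrna * length(genes)))
  lnc_genes <- character(0)
  if (n_pairs > 0)
    lnc_genes <- unique(gene_of[cfg$n_de + seq_len(n_pairs)])
  pool <- setdiff(genes, if (n_pairs > 0)
    unique(gene_of[cfg$n_de + seq_len(2L * n_pairs)]) else character(0))
  extra <- max(0L, n_lnc - length(lnc_genes))
  lnc_genes <- c(lnc_genes, sample(pool, min(extra, length(pool))))
  gene_bt <- stats::setNames(
    sample(c("protein_coding", "novel", "pseudogene", "TEC"),
           length(genes), replace = TRUE,
           prob = c(0.7, 0.2, 0.06, 0.04)), genes)
  gene_bt[lnc_genes] <- sample(LNCRNA_BIOTYPES, length(lnc_genes),
                               replace = TRUE)
  if (n_pairs > 0) {
    mrna_genes <- unique(gene_of[cfg$n_de + n_pairs + seq_len(n_pairs)])
    gene_bt[mrna_genes] <- "protein_coding"
  }

  # shared-gene transcripts must sit on the gene's chromosome
  first_of_gene <- match(gene_of, gene_of)
  chrom <- chrom[first_of_gene]
  data.frame(transcript_id = tx_id, gene_id = gene_of, chromosome = chrom,
             start = start, end = start + width, strand = strand,
             biotype = unname(gene_bt[gene_of]), stringsAsFactors = FALSE)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Emits triplicate Ct values per sample and gene for a two-group design
#' (target group \code{"LH"}, control group \code{"Ctrl"}), plus a reference
#' gene (\code{"Gapdh"}, fold 1). A planted fold change \eqn{\phi} lowers the
#' target-group Ct by \eqn{\log_2 \phi} cycles, so noiseless generation
#' inverts exactly under \code{\link{ddct}}.
#'
#' @param true_fold named numeric vector, gene -> fold change (> 0).
#' @param n_per_group samples per group (>= 2).
#' @param ct_noise_sd per-replicate Ct noise in cycles (>= 0).
#' @param seed integer seed.
#' @param reference_gene name of the reference gene appended with fold 1.
#' @return data.frame with columns sample, group, gene, ct1, ct2, ct3.
#' @export
simulate_qpcr <- function(true_fold, n_per_group = 10L, ct_noise_sd = 0.1,
                          seed = 1L, reference_gene = "Gapdh") {
  if (any(true_fold <= 0)) stop("fold changes must be positive")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  stopifnot(ct_noise_sd >= 0, !is.null(names(true_fold)))
  folds <- c(true_fold, stats::setNames(1, reference_gene))
  genes <- names(folds)
  withr::with_seed(seed, {
    base_ct <- stats::setNames(stats::runif(length(genes), 20, 28), genes)
    grid <- expand.grid(rep = seq_len(n_per_group),
                        group = c("Ctrl", "LH"), gene = genes,
                        stringsAsFactors = FALSE)
    ct0 <- base_ct[grid$gene] -
      ifelse(grid$group == "LH", log2(folds[grid$gene]), 0)
    reps <- matrix(stats::rnorm(3L * nrow(grid), 0, ct_noise_sd), ncol = 3)
    data.frame(sample = paste0(grid$group, "_", grid$rep),
               group = grid$group, gene = grid$gene,
               ct1 = ct0 + reps[, 1], ct2 = ct0 + reps[, 2],
               ct3 = ct0 + reps[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a gene-set collection enriched for planted DE genes
#'
#' Builds a flat gene-set collection (GMT-style) over the annotated gene
#' universe. The first \code{enriched_terms} terms draw most of their members
#' from planted differentially expressed genes, so the enrichment stage has
#' guaranteed positives; the remaining terms are random draws from the
#' universe.
#'
#' @param annotation annotation table (provides the gene universe).
#' @param truth truth table from \code{\link{simulate_expression}}.
#' @param n_terms total number of terms.
#' @param enriched_terms number of DE-enriched terms (<= n_terms).
#' @param term_size members per term.
#' @param seed integer seed.
#' @return named list of character vectors (term -> gene ids); term names
#'   carry an \code{ENR} prefix when DE-enriched.
#' @export
simulate_gene_sets <- function(annotation, truth, n_terms = 20L,
                               enriched_terms = 3L, term_size = 10L,
                               seed = 1L) {
  if (nrow(annotation) == 0) stop("annotation is empty")
  if (n_terms < enriched_terms)
    stop("n_terms must be >= enriched_terms")
  universe <- unique(annotation$gene_id)
  de_genes <- unique(truth$gene_id[truth$de_direction != "null"])
  withr::with_seed(seed, {
    sets <- vector("list", n_terms)
    names(sets) <- c(sprintf("ENR_TERM_%02d", seq_len(enriched_terms)),
                     sprintf("RAND_TERM_%02d",
                             seq_len(n_terms - enriched_terms)))
    for (i in seq_len(n_terms)) {
      if (i <= enriched_terms && length(de_genes) > 0) {
        n_de_mem <- min(length(de_genes), ceiling(0.8 * term_size))
        mem <- c(sample(de_genes, n_de_mem),
                 sample(setdiff(universe, de_genes),
                        max(0, term_size - n_de_mem)))
      } else {
        mem <- sample(universe, min(term_size, length(universe)))
      }
      sets[[i]] <- sort(unique(mem))
    }
    sets
  })
}
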