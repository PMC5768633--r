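#' Frozen reference counts from the original GSE102965 cohort
#'
#' The printed headline counts of the original four-group hippocampus
#' RNA-seq study (deposited as GEO GSE102965): per-comparison differentially
#' expressed transcript totals with their down/up split, the lncRNA and
#' protein-coding sub-tallies, and the regulatory-lncRNA fractions. These
#' are input data for \code{\link{consistency_checks}}; the package does not
#' re-derive them (the raw data are not bundled).
#'
#' One printed value is adjusted: the LH vs Ctrl up-regulated total is
#' printed as 1337, which is inconsistent with both the column sum of the
#' up-regulated biotype rows (30 + 823 + 484 + 16 + 23 + 1 = 1377) and the
#' printed grand total (2550 + 1377 = 3927). The internally consistent 1377
#' is used here, treating 1337 as a transposed-digit typo.
#'
#' @return named list of integer counts.
#' @export
reference_counts <- function() {
  list(
    de_lh_ctrl = 3927, de_lh_nlh = 2419, de_total = 6346,
    lh_ctrl_down = 2550, lh_ctrl_up = 1377,
    lh_nlh_down = 1663, lh_nlh_up = 756,
    pc_lh_ctrl = 2163, pc_lh_nlh = 1396, pc_total = 3559,
    lnc_lh_ctrl_down = 169, lnc_lh_ctrl_up = 30, lnc_lh_ctrl = 199,
    lnc_lh_nlh_down = 121, lnc_lh_nlh_up = 21, lnc_lh_nlh = 142,
    reg_lnc_lh_ctrl = 34, reg_lnc_pct_lh_ctrl = 17,
    reg_lnc_lh_nlh = 24,
    synapse_lnc = 33, reg_lnc_both = 58, synapse_pct = 57)
}

#' Arithmetic consistency checks over reported counts
#'
#' Verifies the internal sum and rounded-percentage identities of a set of
#' reported counts (see \code{\link{reference_counts}} for the field
#' names). Checks whose inputs are absent from \code{counts} are skipped;
#' a percentage with a zero denominator is reported as 0 and flagged
#' degenerate.
#'
#' @param counts named list of counts.
#' @return data.frame check, computed, expected, pass, degenerate.
#' @export
consistency_checks <- function(counts) {
  rows <- list()
  add <- function(label, computed, expected, degenerate = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = label, computed = computed, expected = expected,
      pass = isTRUE(computed == expected), degenerate = degenerate,
      stringsAsFactors = FALSE)
  }
  has <- function(...) all(c(...) %in% names(counts))
  g <- function(nm) counts[[nm]]
  pct <- function(num, den) {
    if (den == 0) return(list(v = 0, deg = TRUE))
    list(v = round(100 * num / den), deg = FALSE)
  }
  if (has("de_lh_ctrl", "de_lh_nlh", "de_total"))
    add("total DE transcripts", g("de_lh_ctrl") + g("de_lh_nlh"),
        g("de_total"))
  if (has("pc_lh_ctrl", "pc_lh_nlh", "pc_total"))
    add("total protein-coding mRNAs", g("pc_lh_ctrl") + g("pc_lh_nlh"),
        g("pc_total"))
  if (has("lh_ctrl_down", "lh_ctrl_up", "de_lh_ctrl"))
    add("LH vs Ctrl down + up", g("lh_ctrl_down") + g("lh_ctrl_up"),
        g("de_lh_ctrl"))
  if (has("lh_nlh_down", "lh_nlh_up", "de_lh_nlh"))
    add("LH vs NLH down + up", g("lh_nlh_down") + g("lh_nlh_up"),
        g("de_lh_nlh"))
  if (has("lnc_lh_ctrl_down", "lnc_lh_ctrl_up", "lnc_lh_ctrl"))
    add("LH vs Ctrl lncRNAs down + up",
        g("lnc_lh_ctrl_down") + g("lnc_lh_ctrl_up"), g("lnc_lh_ctrl"))
  if (has("lnc_lh_nlh_down", "lnc_lh_nlh_up", "lnc_lh_nlh"))
    add("LH vs NLH lncRNAs down + up",
        g("lnc_lh_nlh_down") + g("lnc_lh_nlh_up"), g("lnc_lh_nlh"))
  if (has("reg_lnc_lh_ctrl", "lnc_lh_ctrl", "reg_lnc_pct_lh_ctrl")) {
    r <- pct(g("reg_lnc_lh_ctrl"), g("lnc_lh_ctrl"))
    add("regulatory lncRNA percent (LH vs Ctrl)", r$v,
        g("reg_lnc_pct_lh_ctrl"), r$deg)
  }
  if (has("synapse_lnc", "reg_lnc_both", "synapse_pct")) {
    r <- pct(g("synapse_lnc"), g("reg_lnc_both"))
    add("synapse-linked lncRNA percent", r$v, g("synapse_pct"), r$deg)
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline from file inputs
#'
#' Orchestrates: expression/annotation/metadata input and QC; the four
#' Student's-t comparisons (LH vs Ctrl, LH vs NLH, Ctrl vs HC, Ctrl vs NLH)
#' with exclusion filtering and biotype tallies; gene-level averaging and
#' per-comparison lncRNA-mRNA co-expression networks with cis/trans labels;
#' Fisher GO enrichment, stringent pathway overlap and lncRNA-function
#' networks. Every stage's outputs are written to \code{out_dir} before the
#' next stage begins.
#'
#' @param expression_tsv transcript FPKM matrix (TSV).
#' @param annotation_path transcript annotation (GTF or TSV).
#' @param annotation_format "gtf" or "tsv".
#' @param metadata_tsv sample metadata TSV (sample_id, group).
#' @param gmt_path gene-set collection (GMT); NULL skips enrichment.
#' @param out_dir output directory.
#' @param alpha_de DE cutoff (default 0.05).
#' @param r2_min,p_max co-expression thresholds (defaults 0.9, 0.01).
#' @param window_bp cis window (default 1e6).
#' @param alpha_go,alpha_pathway enrichment cutoffs (defaults 0.05, 0.01).
#' @param min_fpkm,min_samples QC thresholds (defaults 0.1, 1).
#' @param correlation_scope "comparison" correlates over the comparison's
#'   samples (n = 8 by default); "all" uses every sample.
#' @param theme_terms optional term ids defining a theme (e.g.
#'   synapse-related bioprocesses) summarised over the pooled
#'   function-network lncRNAs.
#' @param log_transform run the t-tests on log2(FPKM + 1).
#' @return the run report, a nested list of per-stage counts (invisibly
#'   written to \code{out_dir/report.tsv} as flat key/value pairs).
#' @export
run_pipeline <- function(expression_tsv, annotation_path,
                         annotation_format = "tsv", metadata_tsv,
                         gmt_path = NULL, out_dir,
                         alpha_de = 0.05, r2_min = 0.9, p_max = 0.01,
                         window_bp = 1e6, alpha_go = 0.05,
                         alpha_pathway = 0.01, min_fpkm = 0.1,
                         min_samples = 1L,
                         correlation_scope = c("comparison", "all"),
                         theme_terms = NULL, log_transform = FALSE) {
  correlation_scope <- match.arg(correlation_scope)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- input + QC -----------------------------------------------------
  report <- list()
  dat <- stage("input", {
    mat <- read_expression(expression_tsv)
    ann <- read_annotation(annotation_path, format = annotation_format)
    design <- read_metadata(metadata_tsv)
    missing <- setdiff(colnames(mat), design$sample_id)
    if (length(missing) > 0)
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    list(mat = mat, ann = ann, design = design)
  })
  qc <- stage("qc", qc_filter(dat$mat, min_fpkm, min_samples))
  write_expression(qc$matrix, file.path(out_dir, "expression_qc.tsv"))
  report$qc <- as.list(qc$report)

  # --- differential expression ---------------------------------------
  comparisons <- list(LHvsCtrl = c("LH", "Ctrl"), LHvsNLH = c("LH", "NLH"),
                      CtrlvsHC = c("Ctrl", "HC"),
                      CtrlvsNLH = c("Ctrl", "NLH"))
  de <- stage("diffexpr", lapply(comparisons, function(cmp)
    run_comparison(qc$matrix, dat$design, cmp, alpha = alpha_de,
                   log_transform = log_transform)))
  for (nm in names(de))
    utils::write.table(de[[nm]], file.path(out_dir,
                                           paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- lapply(de, function(d) d$feature_id[d$significant])
  sets <- exclusion_filter(sig$LHvsCtrl, sig$LHvsNLH, sig$CtrlvsHC,
                           sig$CtrlvsNLH)
  report$de <- c(lapply(sets, length))
  vc <- venn_counts(sig)
  utils::write.table(vc, file.path(out_dir, "venn_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  specific <- list(LHvsCtrl = sets$LHvsCtrl_specific,
                   LHvsNLH = sets$LHvsNLH_specific)
  summaries <- stage("biotype", lapply(names(specific), function(nm) {
    ids <- specific[[nm]]
    dirs <- de[[nm]]$direction[match(ids, de[[nm]]$feature_id)]
    bs <- biotype_summary(ids, dirs, dat$ann)
    utils::write.table(bs, file.path(out_dir,
                                     paste0("biotype_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bs
  }))
  names(summaries) <- names(specific)
  report$biotype <- lapply(summaries, function(bs)
    stats::setNames(as.list(bs$n_total), bs$biotype))

  # --- co-expression networks ----------------------------------------
  gene_mat <- stage("gene_level", gene_level_average(qc$matrix, dat$ann))
  write_expression(gene_mat, file.path(out_dir, "expression_gene.tsv"))
  gs <- gene_spans(dat$ann)
  networks <- list()
  fnc_networks <- list()
  background <- rownames(gene_mat)
  collection <- if (!is.null(gmt_path)) read_gmt(gmt_path) else NULL

  for (nm in names(specific)) {
    net <- stage(paste0("coexnet_", nm), {
      ids <- specific[[nm]]
      genes <- unique(dat$ann$gene_id[match(ids, dat$ann$transcript_id)])
      roles <- gs$biotype[match(genes, gs$gene_id)]
      lnc <- genes[roles %in% LNCRNA_BIOTYPES]
      mrna <- genes[roles == "protein_coding"]
      if (length(lnc) == 0 || length(mrna) == 0) {
        build_network(data.frame(lnc_gene = character(0),
                                 mrna_gene = character(0),
                                 r = numeric(0), r_squared = numeric(0),
                                 p = numeric(0)), comparison = nm)
      } else {
        cols <- if (correlation_scope == "comparison")
          dat$design$sample_id[dat$design$group %in% comparisons[[nm]]]
          else dat$design$sample_id
        cand <- correlate_pairs(gene_mat, lnc, mrna, samples = cols)
        edges <- filter_edges(cand, r2_min = r2_min, p_max = p_max)
        if (nrow(edges) > 0)
          edges <- classify_cis_trans(edges, dat$ann,
                                      window_bp = window_bp)
        build_network(edges, comparison = nm,
                      n_lncrna_universe = length(lnc))
      }
    })
    export_network(net, out_dir)
    networks[[nm]] <- net
    report$coexnet[[nm]] <- c(net$summary,
      list(n_cis = sum(net$edges$locality == "cis"),
           n_trans = sum(net$edges$locality == "trans")))

    if (!is.null(collection)) {
      fnc <- stage(paste0("enrich_", nm), {
        dirs <- de[[nm]]$direction[match(specific[[nm]],
                                         de[[nm]]$feature_id)]
        gdir <- tapply(dirs,
                       dat$ann$gene_id[match(specific[[nm]],
                                             dat$ann$transcript_id)],
                       function(d) d[1])
        lncrna_function_network(net, collection, background,
                                alpha = alpha_go,
                                directions = gdir)
      })
      fnc_networks[[nm]] <- fnc
      utils::write.table(fnc$edges,
                         file.path(out_dir,
                                   paste0("function_network_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$function_network[[nm]] <-
        list(n_lncrna = nrow(fnc$lnc_nodes), n_edges = nrow(fnc$edges),
             n_terms = length(fnc$terms))
    }
  }

  # --- global enrichment + pathway overlap ---------------------------
  if (!is.null(collection)) {
    enr <- stage("enrichment", lapply(names(specific), function(nm) {
      ids <- specific[[nm]]
      genes <- intersect(
        unique(dat$ann$gene_id[match(ids, dat$ann$transcript_id)]),
        background)
      er <- fisher_enrichment(genes, background, collection,
                              alpha = alpha_go)
      utils::write.table(er, file.path(out_dir,
                                       paste0("enrichment_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      er
    }))
    names(enr) <- names(specific)
    ov <- pathway_overlap(enr$LHvsCtrl, enr$LHvsNLH,
                          alpha_strict = alpha_pathway)
    report$enrichment <- list(
      n_sig_LHvsCtrl = sum(enr$LHvsCtrl$significant),
      n_sig_LHvsNLH = sum(enr$LHvsNLH$significant),
      n_common_pathways = length(ov$common))
    if (!is.null(theme_terms) && length(fnc_networks) > 0) {
      pooled_edges <- do.call(rbind, lapply(fnc_networks, `[[`, "edges"))
      pooled_nodes <- unique(do.call(rbind, lapply(fnc_networks, `[[`,
                                                   "lnc_nodes")))
      pooled <- structure(list(edges = pooled_edges,
                               lnc_nodes = pooled_nodes,
                               terms = sort(unique(pooled_edges$term_id))),
                          class = "function_network")
      report$theme <- term_theme_summary(pooled, theme_terms)
    }
  }

  .write_report(report, file.path(out_dir, "report.tsv"))
  invisible(report)
}

# Flattens the nested report into key/value TSV lines.
.write_report <- function(report, path) {
  flat <- unlist(report)
  utils::write.table(data.frame(key = names(flat),
                                value = as.character(flat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
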