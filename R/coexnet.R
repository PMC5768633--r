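#' All-pairs Pearson correlation between lncRNA and mRNA genes
#'
#' For every (lncRNA gene, mRNA gene) pair, the Pearson correlation of
#' gene-level FPKM over the selected samples and the two-sided p-value from
#' the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2 degrees of
#' freedom. Genes with zero variance across the selected samples produce no
#' candidates and are reported with a warning.
#'
#' @param gene_mat gene-level expression matrix.
#' @param lnc_ids,mrna_ids disjoint gene-id sets present in the matrix.
#' @param samples sample ids to correlate over (>= 3).
#' @return data.frame lnc_gene, mrna_gene, r, r_squared, p.
#' @export
correlate_pairs <- function(gene_mat, lnc_ids, mrna_ids,
                            samples = colnames(gene_mat)) {
  if (length(intersect(lnc_ids, mrna_ids)) > 0)
    stop("lnc_ids and mrna_ids overlap: ",
         paste(utils::head(intersect(lnc_ids, mrna_ids), 5),
               collapse = ", "))
  if (length(samples) < 3) stop("need >= 3 samples for correlation")
  miss <- setdiff(c(lnc_ids, mrna_ids), rownames(gene_mat))
  if (length(miss) > 0)
    stop("genes absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- t(gene_mat[lnc_ids, samples, drop = FALSE])
  Y <- t(gene_mat[mrna_ids, samples, drop = FALSE])
  const_x <- apply(X, 2, stats::var) == 0
  const_y <- apply(Y, 2, stats::var) == 0
  if (any(const_x) || any(const_y))
    warning("skipping zero-variance gene(s): ",
            paste(utils::head(c(colnames(X)[const_x],
                                colnames(Y)[const_y]), 5), collapse = ", "))
  X <- X[, !const_x, drop = FALSE]
  Y <- Y[, !const_y, drop = FALSE]
  if (ncol(X) == 0 || ncol(Y) == 0)
    return(data.frame(lnc_gene = character(0), mrna_gene = character(0),
                      r = numeric(0), r_squared = numeric(0),
                      p = numeric(0)))
  r <- stats::cor(X, Y)
  n <- length(samples)
  r_cap <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  tstat <- r_cap * sqrt((n - 2) / (1 - r_cap^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  out <- data.frame(
    lnc_gene = rep(rownames(r), times = ncol(r)),
    mrna_gene = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), r_squared = as.vector(r)^2, p = as.vector(p),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Retain strongly correlated candidate pairs
#'
#' Keeps candidates with r^2 >= \code{r2_min} (inclusive) and
#' p < \code{p_max}; both positive and negative correlations are retained
#' and annotated with their sign.
#'
#' @param candidates output of \code{\link{correlate_pairs}}.
#' @param r2_min squared-correlation threshold (default 0.9, inclusive).
#' @param p_max p-value cutoff (default 0.01, exclusive).
#' @return the retained rows plus a \code{sign} column
#'   ("positive"/"negative").
#' @export
filter_edges <- function(candidates, r2_min = 0.9, p_max = 0.01) {
  stopifnot(r2_min >= 0, r2_min <= 1, p_max >= 0, p_max <= 1)
  keep <- candidates$r_squared >= r2_min & candidates$p < p_max
  out <- candidates[keep, , drop = FALSE]
  out$sign <- ifelse(out$r >= 0, "positive", "negative")
  rownames(out) <- NULL
  out
}

#' Classify edges as cis or trans by genomic distance
#'
#' An mRNA gene within \code{window_bp} (inclusive) of the lncRNA gene on
#' the same chromosome is a potential cis partner; partners on different
#' chromosomes or beyond the window are potential trans partners. Distance
#' is the gap between the closest gene-span boundaries (0 when the spans
#' overlap), with the window applied symmetrically regardless of strand.
#'
#' @param edges data.frame with lnc_gene, mrna_gene columns.
#' @param annotation transcript annotation table (gene spans are derived).
#' @param window_bp cis window in base pairs (default 1,000,000, inclusive).
#' @return \code{edges} plus columns \code{locality} ("cis"/"trans") and
#'   \code{distance_bp} (NA when chromosomes differ).
#' @export
classify_cis_trans <- function(edges, annotation, window_bp = 1e6) {
  gs <- gene_spans(annotation)
  miss <- setdiff(unique(c(edges$lnc_gene, edges$mrna_gene)), gs$gene_id)
  if (length(miss) > 0)
    stop("genes missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "))
  i <- match(edges$lnc_gene, gs$gene_id)
  j <- match(edges$mrna_gene, gs$gene_id)
  same_chr <- gs$chromosome[i] == gs$chromosome[j]
  dist <- rep(NA_real_, nrow(edges))
  dist[same_chr] <- mapply(.span_gap, gs$start[i[same_chr]],
                           gs$end[i[same_chr]], gs$start[j[same_chr]],
                           gs$end[j[same_chr]])
  edges$locality <- ifelse(same_chr & dist <= window_bp, "cis", "trans")
  edges$locality[!same_chr] <- "trans"
  edges$distance_bp <- dist
  edges
}

#' Assemble a bipartite lncRNA-mRNA co-expression network
#'
#' Deduplicates edges, derives the node table with roles, and computes
#' summary statistics. A gene appearing on both sides of the bipartition
#' is an error.
#'
#' @param edges filtered (and optionally cis/trans-classified) edge table.
#' @param comparison label for the comparison the network belongs to.
#' @param n_lncrna_universe optional denominator for the fraction-connected
#'   statistic (e.g. the number of DE lncRNA genes tested); defaults to the
#'   lncRNAs present in the edge table.
#' @return list of class \code{"coex_network"}: nodes (data.frame gene_id,
#'   role), edges, comparison, and summary (n_lncrna, n_mrna, n_edges,
#'   frac_lncrna_connected relative to the lncRNAs present in the edge
#'   table).
#' @export
build_network <- function(edges, comparison = "LHvsCtrl",
                          n_lncrna_universe = NULL) {
  edges <- edges[!duplicated(edges[, c("lnc_gene", "mrna_gene")]), ,
                 drop = FALSE]
  clash <- intersect(unique(edges$lnc_gene), unique(edges$mrna_gene))
  if (length(clash) > 0)
    stop("gene(s) appear as both lncRNA and mRNA endpoint: ",
         paste(utils::head(clash, 5), collapse = ", "))
  lnc <- unique(edges$lnc_gene)
  mrna <- unique(edges$mrna_gene)
  nodes <- data.frame(gene_id = c(lnc, mrna),
                      role = rep(c("lncRNA", "mRNA"),
                                 c(length(lnc), length(mrna))),
                      stringsAsFactors = FALSE)
  denom <- if (is.null(n_lncrna_universe)) length(lnc) else n_lncrna_universe
  structure(list(
    nodes = nodes, edges = edges, comparison = comparison,
    summary = list(n_lncrna = length(lnc), n_mrna = length(mrna),
                   n_edges = nrow(edges),
                   frac_lncrna_connected =
                     if (denom > 0) length(lnc) / denom else 0)),
    class = "coex_network")
}

#' Export a network as SIF, GraphML and node/edge TSVs
#'
#' SIF lines are \code{"lnc_gene coexp mrna_gene"}. GraphML (via igraph)
#' carries the node \code{role} attribute and the edge attributes r,
#' r_squared, p, sign and locality. The TSV pair round-trips through
#' \code{\link{import_network}}.
#'
#' @param network a \code{"coex_network"}.
#' @param dir output directory (created if needed).
#' @param formats subset of c("sif", "graphml", "tsv").
#' @param prefix file-name prefix (default the comparison label).
#' @return named character vector of the files written.
#' @export
export_network <- function(network, dir,
                           formats = c("sif", "graphml", "tsv"),
                           prefix = NULL) {
  stopifnot(inherits(network, "coex_network"))
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad) > 0)
    stop("unknown format(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(prefix)) prefix <- network$comparison
  out <- character(0)
  if ("sif" %in% formats) {
    f <- file.path(dir, paste0(prefix, ".sif"))
    writeLines(paste(network$edges$lnc_gene, "coexp",
                     network$edges$mrna_gene), f)
    out["sif"] <- f
  }
  if ("graphml" %in% formats) {
    f <- file.path(dir, paste0(prefix, ".graphml"))
    g <- .as_igraph(network)
    igraph::write_graph(g, f, format = "graphml")
    out["graphml"] <- f
  }
  if ("tsv" %in% formats) {
    fn <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    fe <- file.path(dir, paste0(prefix, "_edges.tsv"))
    utils::write.table(network$nodes, fn, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$edges, fe, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out["nodes_tsv"] <- fn
    out["edges_tsv"] <- fe
  }
  out
}

.as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("lnc_gene", "mrna_gene",
                      intersect(c("r", "r_squared", "p", "sign", "locality"),
                                names(network$edges)))],
    directed = FALSE, vertices = network$nodes)
  g
}

#' Re-import a network from its node/edge TSV export
#' @param nodes_tsv,edges_tsv paths written by \code{\link{export_network}}.
#' @param comparison comparison label.
#' @return a \code{"coex_network"} equal to the exported one.
#' @export
import_network <- function(nodes_tsv, edges_tsv, comparison = "LHvsCtrl") {
  edges <- utils::read.delim(edges_tsv, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(nodes_tsv, stringsAsFactors = FALSE)
  net <- build_network(edges, comparison = comparison)
  stopifnot(setequal(net$nodes$gene_id, nodes$gene_id))
  net
}
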