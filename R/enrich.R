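#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated. Gene ids are kept case-stable; empty terms are dropped.
#'
#' @param path GMT file.
#' @return named list of character vectors (term id -> members); the
#'   description field is kept in the \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 0L) < 3
  fields <- fields[!bad]
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2)
  sets[vapply(sets, length, 0L) > 0]
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher's exact test per term: with query size n,
#' term size K in a background of N genes and k query hits, the p-value is
#' the hypergeometric upper tail \eqn{P(X \ge k)}. Terms with fewer than
#' \code{min_term_size} background members are skipped. No multiple-testing
#' correction is applied.
#'
#' @param query gene set to test (must be a subset of \code{background}).
#' @param background the gene universe; the default expressed-universe
#'   background (all genes surviving QC) is supplied by the caller.
#' @param collection named list of term gene sets (e.g. from
#'   \code{\link{read_gmt}}); members outside the background are ignored.
#' @param alpha significance cutoff (default 0.05).
#' @param min_term_size minimum background term size (default 3).
#' @return data.frame term_id, k, n, K, N, odds_ratio, p, significant,
#'   ordered by p.
#' @export
fisher_enrichment <- function(query, background, collection, alpha = 0.05,
                              min_term_size = 3L) {
  query <- unique(query)
  background <- unique(background)
  if (length(background) < 2) stop("background needs >= 2 genes")
  stray <- setdiff(query, background)
  if (length(stray) > 0)
    stop("query genes outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) " ...")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], background)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    odds <- (k * (N - K - n + k)) / max(1e-300, (n - k) * (K - k))
    data.frame(term_id = term, k = k, n = n, K = K, N = N,
               odds_ratio = odds, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      significant = logical(0)))
  out$significant <- out$p < alpha
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Partition enriched terms between two comparisons
#'
#' Terms significant at the stringent pathway cutoff in both result tables
#' are "common"; otherwise they fall in the respective one-sided bucket.
#'
#' @param enrich_a,enrich_b enrichment tables over the same collection.
#' @param alpha_strict stringent cutoff (default 0.01).
#' @return list with common, a_only, b_only term-id vectors.
#' @export
pathway_overlap <- function(enrich_a, enrich_b, alpha_strict = 0.01) {
  if (!setequal(enrich_a$term_id, enrich_b$term_id))
    stop("enrichment tables cover different collections")
  sig_a <- enrich_a$term_id[enrich_a$p < alpha_strict]
  sig_b <- enrich_b$term_id[enrich_b$p < alpha_strict]
  list(common = intersect(sig_a, sig_b),
       a_only = setdiff(sig_a, sig_b),
       b_only = setdiff(sig_b, sig_a))
}

#' lncRNA-bioprocess bipartite network from a co-expression network
#'
#' For each lncRNA node, its co-expressed mRNA partner set is
#' enrichment-tested against the collection; an edge (lncRNA, term) is
#' created when the term is significant at \code{alpha} with at least
#' \code{min_support} supporting partner genes. lncRNAs with no partners
#' are omitted. The lncRNA regulation direction (from the DE stage) is
#' carried as a node attribute when supplied.
#'
#' @param network a \code{"coex_network"}.
#' @param collection named list of term gene sets.
#' @param background gene universe containing every mRNA node.
#' @param alpha per-term significance cutoff (default 0.05).
#' @param min_support minimum supporting partner genes per edge (default 2).
#' @param directions optional named vector gene_id -> "up"/"down" for the
#'   lncRNA nodes.
#' @return list of class \code{"function_network"}: edges (data.frame
#'   lnc_gene, term_id, support, p), lnc_nodes (data.frame gene_id,
#'   direction), terms (term ids with >= 1 edge).
#' @export
lncrna_function_network <- function(network, collection, background,
                                    alpha = 0.05, min_support = 2L,
                                    directions = NULL) {
  stopifnot(inherits(network, "coex_network"))
  lncs <- sort(unique(network$edges$lnc_gene))
  edge_rows <- lapply(lncs, function(lnc) {
    partners <- unique(network$edges$mrna_gene[
      network$edges$lnc_gene == lnc])
    if (length(partners) == 0) return(NULL)
    er <- fisher_enrichment(partners, background, collection, alpha = alpha)
    er <- er[er$significant & er$k >= min_support, , drop = FALSE]
    if (nrow(er) == 0) return(NULL)
    data.frame(lnc_gene = lnc, term_id = er$term_id, support = er$k,
               p = er$p, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_rows)
  if (is.null(edges))
    edges <- data.frame(lnc_gene = character(0), term_id = character(0),
                        support = integer(0), p = numeric(0))
  lnc_nodes <- data.frame(gene_id = lncs,
                          direction = if (is.null(directions))
                            NA_character_ else
                              unname(directions[lncs]),
                          stringsAsFactors = FALSE)
  structure(list(edges = edges, lnc_nodes = lnc_nodes,
                 terms = sort(unique(edges$term_id))),
            class = "function_network")
}

#' Fraction of lncRNAs linked to a theme
#'
#' Reports how many lncRNAs in a function network have at least one edge to
#' a term of the given theme (e.g. synapse-related bioprocesses), and how
#' many distinct theme terms are hit.
#'
#' @param fnet a \code{"function_network"}.
#' @param theme_terms character vector of term ids defining the theme.
#' @return list with n_linked, n_total, fraction, percent (rounded to the
#'   nearest integer), n_theme_terms_hit, degenerate (TRUE when the network
#'   has no lncRNAs).
#' @export
term_theme_summary <- function(fnet, theme_terms) {
  stopifnot(inherits(fnet, "function_network"))
  n_total <- nrow(fnet$lnc_nodes)
  if (n_total == 0)
    return(list(n_linked = 0L, n_total = 0L, fraction = 0, percent = 0,
                n_theme_terms_hit = 0L, degenerate = TRUE))
  hit <- fnet$edges[fnet$edges$term_id %in% theme_terms, , drop = FALSE]
  n_linked <- length(unique(hit$lnc_gene))
  frac <- n_linked / n_total
  list(n_linked = n_linked, n_total = n_total, fraction = frac,
       percent = round(100 * frac),
       n_theme_terms_hit = length(unique(hit$term_id)),
       degenerate = FALSE)
}
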