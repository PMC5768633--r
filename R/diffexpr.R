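#' Two-sample Student's t-test (pooled variance)
#'
#' Pooled-variance two-sample t with df = n_a + n_b - 2 and a two-sided p,
#' as used for the library differential expression. Degenerate inputs are
#' kept total: zero pooled variance with equal means gives t = 0, p = 1
#' (non-significant); zero pooled variance with unequal means gives p = 0
#' with a degenerate flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with t, p, direction ("up" when mean(a) > mean(b), "down"
#'   when smaller, NA when equal) and degenerate flag.
#' @export
de_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 values")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  md <- mean(a) - mean(b)
  dir <- if (md > 0) "up" else if (md < 0) "down" else NA_character_
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (md == 0) return(list(t = 0, p = 1, direction = dir,
                             degenerate = FALSE))
    return(list(t = sign(md) * Inf, p = 0, direction = dir,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, direction = dir,
       degenerate = FALSE)
}

#' Differential expression for one group comparison
#'
#' Applies \code{\link{de_t_test}} to every feature of the matrix for one
#' ordered (test, reference) group pair. Significance is called at
#' p < \code{alpha} with no multiple-testing correction and no fold-change
#' cutoff. By default the test runs on raw FPKM; \code{log_transform}
#' switches to log2(FPKM + 1).
#'
#' @param mat expression matrix (features x samples).
#' @param design data.frame sample_id, group covering the matrix columns.
#' @param comparison character length-2, c(test_group, reference_group).
#' @param alpha significance cutoff (default 0.05).
#' @param log_transform test on log2(FPKM + 1) instead of raw FPKM.
#' @return data.frame: feature_id, comparison, mean_test, mean_ref, t, p,
#'   direction, significant.
#' @export
run_comparison <- function(mat, design, comparison, alpha = 0.05,
                           log_transform = FALSE) {
  stopifnot(length(comparison) == 2)
  unknown <- setdiff(comparison, design$group)
  if (length(unknown) > 0)
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  cols_a <- design$sample_id[design$group == comparison[1]]
  cols_b <- design$sample_id[design$group == comparison[2]]
  if (length(cols_a) < 2 || length(cols_b) < 2)
    stop("both groups need >= 2 samples")
  A <- mat[, cols_a, drop = FALSE]
  B <- mat[, cols_b, drop = FALSE]
  if (log_transform) { A <- log2(A + 1); B <- log2(B + 1) }
  res <- lapply(seq_len(nrow(mat)), function(i) de_t_test(A[i, ], B[i, ]))
  out <- data.frame(
    feature_id = rownames(mat),
    comparison = paste0(comparison[1], "vs", comparison[2]),
    mean_test = rowMeans(A), mean_ref = rowMeans(B),
    t = vapply(res, `[[`, 0, "t"),
    p = vapply(res, `[[`, 0, "p"),
    direction = vapply(res, `[[`, "", "direction"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p < alpha
  out
}

#' Helplessness-specific transcript sets by exclusion filtering
#'
#' Transcripts differentially expressed in Ctrl vs HC may be driven by
#' handling and context exposure; those in Ctrl vs NLH by the resilience
#' phenotype. Both are removed from the LH comparisons:
#' \code{LHvsCtrl_specific = LHvsCtrl \\ (CtrlvsHC U CtrlvsNLH)}, and
#' likewise for LHvsNLH.
#'
#' @param lh_ctrl,lh_nlh,ctrl_hc,ctrl_nlh character vectors of significant
#'   feature ids per comparison.
#' @return list with raw sets and the two filtered
#'   \code{*_specific} sets.
#' @export
exclusion_filter <- function(lh_ctrl, lh_nlh, ctrl_hc, ctrl_nlh) {
  excl <- union(ctrl_hc, ctrl_nlh)
  list(LHvsCtrl = lh_ctrl, LHvsNLH = lh_nlh,
       CtrlvsHC = ctrl_hc, CtrlvsNLH = ctrl_nlh,
       LHvsCtrl_specific = setdiff(lh_ctrl, excl),
       LHvsNLH_specific = setdiff(lh_nlh, excl))
}

#' Tally a DE set by biotype and direction
#'
#' Counts features per biotype split by regulation direction, with the
#' lncRNA subclasses additionally aggregated into one combined
#' \code{"lncRNA"} row and a grand \code{"Total"} row.
#'
#' @param feature_ids character vector of features in the set.
#' @param directions character vector ("up"/"down") aligned to
#'   \code{feature_ids}.
#' @param annotation annotation table (transcript level).
#' @return data.frame biotype, n_down, n_up, n_total; first row Total,
#'   second row lncRNA (subclass aggregate), then individual biotypes.
#' @export
biotype_summary <- function(feature_ids, directions, annotation) {
  stopifnot(length(feature_ids) == length(directions))
  bt <- annotation$biotype[match(feature_ids, annotation$transcript_id)]
  if (anyNA(bt))
    stop("unannotated feature(s): ",
         paste(utils::head(feature_ids[is.na(bt)], 5), collapse = ", "))
  count_row <- function(sel, name) {
    data.frame(biotype = name,
               n_down = sum(directions[sel] == "down"),
               n_up = sum(directions[sel] == "up"),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    count_row(rep(TRUE, length(bt)), "Total"),
    count_row(bt %in% LNCRNA_BIOTYPES, "lncRNA"),
    do.call(rbind, lapply(sort(unique(bt)), function(b)
      count_row(bt == b, b))))
  if (length(feature_ids) == 0)
    rows <- rows[rows$biotype %in% c("Total", "lncRNA"), ]
  rows$n_total <- rows$n_down + rows$n_up
  rownames(rows) <- NULL
  rows
}

#' Counts for every region of a <= 4-set Venn partition
#'
#' Enumerates the inclusion--exclusion partition by membership pattern.
#' Region names are \code{"+-+-"}-style strings over the set order, one
#' character per set.
#'
#' @param sets named list of <= 4 character vectors.
#' @return data.frame region, count for every non-empty region.
#' @export
venn_counts <- function(sets) {
  if (length(sets) > 4) stop("venn_counts supports at most 4 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  if (length(universe) == 0)
    return(data.frame(region = character(0), count = integer(0)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  pattern <- apply(member, 1, function(m)
    paste(ifelse(m, "+", "-"), collapse = ""))
  tab <- table(pattern)
  data.frame(region = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
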