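#' Read a qPCR Ct table
#'
#' CSV with columns sample, group, gene and up to three replicate Ct
#' columns (ct1, ct2, ct3).
#' @param path CSV file.
#' @return data.frame as above.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct1")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("qPCR CSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample and gene: the mean Ct over replicates, then
#' dCt = Ct_target - Ct_reference, ddCt = dCt - mean(dCt over the
#' control-group samples), fold = 2^-ddCt and percent-of-control =
#' 100 * fold. The control baseline is the mean dCt of the control group
#' (not a single calibrator sample), matching percent-of-average-control
#' reporting. Amplification efficiency is fixed at 2 (the ddCt assumption).
#'
#' @param plate Ct table (see \code{\link{read_qpcr}}).
#' @param reference_gene housekeeping gene id (default "Gapdh"); must be
#'   measured in every sample.
#' @param control_group baseline group (default "Ctrl").
#' @return data.frame sample, group, gene, delta_ct, ddct, fold_change,
#'   percent_of_control for every non-reference gene.
#' @export
ddct <- function(plate, reference_gene = "Gapdh", control_group = "Ctrl") {
  ct_cols <- intersect(c("ct1", "ct2", "ct3"), names(plate))
  ct <- rowMeans(as.matrix(plate[, ct_cols, drop = FALSE]), na.rm = TRUE)
  if (any(!is.finite(ct) | ct <= 0))
    stop("Ct values must be positive and finite")
  if (!control_group %in% plate$group)
    stop("control group '", control_group, "' not present")
  ref <- plate$gene == reference_gene
  ref_ct <- stats::setNames(ct[ref], plate$sample[ref])
  samples <- unique(plate$sample)
  no_ref <- setdiff(samples, names(ref_ct))
  if (length(no_ref) > 0)
    stop("reference gene not measured for sample(s): ",
         paste(no_ref, collapse = ", "))
  tgt <- plate[!ref, c("sample", "group", "gene")]
  dct <- ct[!ref] - ref_ct[tgt$sample]
  out <- do.call(rbind, lapply(split(seq_len(nrow(tgt)), tgt$gene),
    function(idx) {
      ctrl_mean <- mean(dct[idx][tgt$group[idx] == control_group])
      dd <- dct[idx] - ctrl_mean
      data.frame(sample = tgt$sample[idx], group = tgt$group[idx],
                 gene = tgt$gene[idx], delta_ct = dct[idx], ddct = dd,
                 fold_change = 2^(-dd),
                 percent_of_control = 100 * 2^(-dd),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Two-tailed unpaired t-test on percent-of-control values
#'
#' Validates relative expression per gene between two groups with the same
#' pooled-variance Student's t-test used for the library differential
#' expression (df = n1 + n2 - 2).
#'
#' @param rel output of \code{\link{ddct}}.
#' @param group_pair character length-2, the two groups to compare.
#' @return data.frame gene, mean_1, mean_2, t, p, significant (at 0.05).
#' @export
qpcr_validate <- function(rel, group_pair = c("LH", "Ctrl")) {
  stopifnot(length(group_pair) == 2)
  absent <- setdiff(group_pair, rel$group)
  if (length(absent) > 0)
    stop("group(s) absent: ", paste(absent, collapse = ", "))
  out <- do.call(rbind, lapply(split(rel, rel$gene), function(g) {
    a <- g$percent_of_control[g$group == group_pair[1]]
    b <- g$percent_of_control[g$group == group_pair[2]]
    if (length(a) < 2 || length(b) < 2)
      stop("gene ", g$gene[1], ": need >= 2 samples per group")
    tt <- de_t_test(a, b)
    data.frame(gene = g$gene[1], mean_1 = mean(a), mean_2 = mean(b),
               t = tt$t, p = tt$p, significant = tt$p < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
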