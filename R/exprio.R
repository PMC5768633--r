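#' Read a transcript/gene expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and a first
#' column of feature ids; all remaining cells are non-negative FPKM values.
#'
#' @param path path to the TSV file.
#' @param level feature level of the matrix, \code{"transcript"} or
#'   \code{"gene"}.
#' @return numeric matrix (features x samples) with a \code{"level"}
#'   attribute.
#' @export
read_expression <- function(path, level = "transcript") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample ids in header")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric FPKM value at feature ", ids[bad[1, 1]],
         ", sample ", names(df)[-1][bad[1, 2]])
  }
  rownames(mat) <- ids
  .validate_expression(mat)
  attr(mat, "level") <- level
  mat
}

.validate_expression <- function(mat) {
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite FPKM at feature ",
         rownames(mat)[bad[1, 1]], ", sample ", colnames(mat)[bad[1, 2]])
  invisible(mat)
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{read_expression}}: first column
#' \code{feature_id}, one column per sample.
#' @param mat expression matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript annotation from GTF or flat TSV
#'
#' For GTF input, transcript features are parsed (via rtracklayer) with the
#' attributes \code{gene_id}, \code{transcript_id} and
#' \code{transcript_biotype}; GTF 1-based inclusive coordinates are kept
#' as-is. Biotypes outside the recognised vocabulary are mapped to
#' \code{"novel"} with a warning.
#'
#' @param path input file.
#' @param format \code{"gtf"} or \code{"tsv"}.
#' @return data.frame with columns transcript_id, gene_id, chromosome,
#'   start, end, strand, biotype.
#' @export
read_annotation <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "transcript"]
    m <- S4Vectors::mcols(gr)
    if (is.null(m$gene_id) || anyNA(m$gene_id))
      stop("GTF transcript feature(s) missing gene_id")
    bt <- if (!is.null(m$transcript_biotype)) as.character(m$transcript_biotype)
          else rep(NA_character_, length(gr))
    ann <- data.frame(
      transcript_id = as.character(m$transcript_id),
      gene_id = as.character(m$gene_id),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = bt, stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "chromosome", "start", "end",
              "strand", "biotype")
    miss <- setdiff(need, names(ann))
    if (length(miss) > 0)
      stop("annotation TSV missing columns: ", paste(miss, collapse = ", "))
    if (anyNA(ann$gene_id)) stop("transcript(s) missing gene_id")
    ann <- ann[, need]
  }
  unknown <- !(ann$biotype %in% BIOTYPE_VOCAB) | is.na(ann$biotype)
  if (any(unknown)) {
    warning(sum(unknown), " transcript(s) with unrecognised biotype mapped ",
            "to 'novel' (e.g. ",
            paste(utils::head(unique(ann$biotype[unknown]), 3),
                  collapse = ", "), ")")
    ann$biotype[unknown] <- "novel"
  }
  if (any(ann$start > ann$end)) stop("annotation has start > end")
  ann
}

#' Write annotation as a GTF file (Ensembl attribute dialect)
#'
#' Emits one \code{transcript} feature per row with gene_id, transcript_id
#' and transcript_biotype attributes; coordinates are written 1-based
#' inclusive as supplied.
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotation_gtf <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chromosome,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand,
    type = "transcript", source = "lhcoex",
    gene_id = ann$gene_id, transcript_id = ann$transcript_id,
    transcript_biotype = ann$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write annotation as flat TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, group)
#' @param path TSV with columns sample_id, group.
#' @return data.frame sample_id, group.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata TSV must have columns sample_id, group")
  df[, c("sample_id", "group")]
}

#' Filter low-expression features
#'
#' Keeps features with FPKM >= \code{min_fpkm} in at least
#' \code{min_samples} samples. The criteria behind the original
#' 190451-to-80137 transcript reduction are not published; this permissive
#' detection filter is the package's stand-in and both thresholds are
#' exposed.
#'
#' @param mat expression matrix.
#' @param min_fpkm detection threshold (>= 0).
#' @param min_samples minimum number of samples meeting the threshold.
#' @return list with \code{matrix} (filtered) and \code{report}
#'   (n_before, n_after, n_dropped).
#' @export
qc_filter <- function(mat, min_fpkm = 0.1, min_samples = 1L) {
  stopifnot(min_fpkm >= 0, min_samples >= 0)
  if (min_samples > ncol(mat))
    stop("min_samples (", min_samples, ") exceeds sample count (",
         ncol(mat), ")")
  keep <- rowSums(mat >= min_fpkm) >= min_samples
  out <- mat[keep, , drop = FALSE]
  attr(out, "level") <- attr(mat, "level")
  list(matrix = out,
       report = data.frame(n_before = nrow(mat), n_after = sum(keep),
                           n_dropped = sum(!keep)))
}

#' Collapse a transcript-level matrix to gene level by averaging
#'
#' Per gene and sample, the unweighted arithmetic mean of the FPKM of all
#' transcripts expressed from that gene.
#'
#' @param mat transcript-level expression matrix.
#' @param ann annotation table covering every transcript in \code{mat}.
#' @return gene-level expression matrix (level attribute \code{"gene"});
#'   sample columns preserved in order.
#' @export
gene_level_average <- function(mat, ann) {
  missing <- setdiff(rownames(mat), ann$transcript_id)
  if (length(missing) > 0)
    stop("transcripts missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  gene <- ann$gene_id[match(rownames(mat), ann$transcript_id)]
  sums <- rowsum(mat, group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  attr(out, "level") <- "gene"
  out
}

#' Per-gene genomic spans and modal biotype
#'
#' Gene span is the union [min start, max end] of its transcripts on one
#' chromosome. Gene biotype is the modal transcript biotype, ties broken
#' toward protein_coding.
#'
#' @param ann annotation table.
#' @return data.frame gene_id, chromosome, start, end, biotype.
#' @export
gene_spans <- function(ann) {
  sp <- split(ann, ann$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    if (length(unique(g$chromosome)) > 1)
      stop("gene ", g$gene_id[1], " spans multiple chromosomes")
    tab <- table(g$biotype)
    top <- names(tab)[tab == max(tab)]
    bt <- if (length(top) > 1 && "protein_coding" %in% top)
      "protein_coding" else top[1]
    data.frame(gene_id = g$gene_id[1], chromosome = g$chromosome[1],
               start = min(g$start), end = max(g$end), biotype = bt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Distance in bp between the closest boundaries of two 1-based inclusive
# spans on one chromosome; 0 when they overlap.
.span_gap <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2))
}

#' Identifiers of lncRNA-class genes
#'
#' A gene counts as lncRNA when its modal biotype is one of the lncRNA
#' subclasses (lincRNA, antisense, sense intronic/overlapping, processed
#' transcript, bidirectional promoter lncRNA).
#' @param ann annotation table.
#' @return character vector of gene ids.
#' @export
lncrna_genes <- function(ann) {
  gs <- gene_spans(ann)
  gs$gene_id[gs$biotype %in% LNCRNA_BIOTYPES]
}

#' @rdname lncrna_genes
#' @export
mrna_genes <- function(ann) {
  gs <- gene_spans(ann)
  gs$gene_id[gs$biotype == "protein_coding"]
}
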