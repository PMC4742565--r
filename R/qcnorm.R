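#' Quality-control thresholds
#'
#' @param min_reads Minimum paired read count; cells strictly below are
#'   excluded.
#' @param min_genes Minimum number of expressed genes; cells strictly
#'   below are excluded.
#' @param expression_cutoff TPM value above which (strictly) a gene counts
#'   as expressed.
#' @return A named list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_reads = 50000, min_genes = 1000,
                          expression_cutoff = 1) {
  stopifnot(min_reads > 0, min_genes > 0, expression_cutoff > 0)
  structure(list(min_reads = min_reads, min_genes = min_genes,
                 expression_cutoff = expression_cutoff),
            class = "qc_thresholds")
}

spikein_columns <- function(mat, spike_prefix = "ERCC-") {
  grepl(paste0("^", spike_prefix), colnames(mat))
}

check_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must carry cell (row) and gene (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) stop("duplicated cell identifiers", call. = FALSE)
  if (anyDuplicated(colnames(mat))) stop("duplicated gene identifiers", call. = FALSE)
  if (any(mat < 0)) stop("expression values must be non-negative", call. = FALSE)
  invisible(mat)
}

#' Number of expressed genes in one cell
#'
#' A gene counts as expressed when its value is strictly greater than the
#' cutoff.
#'
#' @param v Non-negative expression vector of one cell.
#' @param cutoff Expression cutoff (default 1 TPM).
#' @return Integer count.
#' @export
expressed_gene_count <- function(v, cutoff = 1) {
  if (any(v < 0)) stop("expression values must be non-negative", call. = FALSE)
  sum(v > cutoff)
}

#' Filter cells by read count and expressed-gene count
#'
#' Retains cells whose paired read count and expressed-gene count are both
#' at or above the thresholds ("less than" excludes, so equality passes).
#'
#' @param mat Cell-by-gene expression matrix.
#' @param metadata Data frame with columns `cell` and `reads` covering
#'   every row of `mat`.
#' @param thresholds A [qc_thresholds()] list.
#' @return A list with the filtered `matrix`, matching `metadata`, and a
#'   `report` data frame listing every cell with its metrics, retention
#'   flag and exclusion reason.
#' @export
filter_cells <- function(mat, metadata, thresholds = qc_thresholds()) {
  check_matrix(mat)
  if (!all(rownames(mat) %in% metadata$cell)) {
    stop("metadata must cover all cells in the matrix", call. = FALSE)
  }
  metadata <- metadata[match(rownames(mat), metadata$cell), , drop = FALSE]
  n_expr <- apply(mat, 1, expressed_gene_count,
                  cutoff = thresholds$expression_cutoff)
  ok_reads <- metadata$reads >= thresholds$min_reads
  ok_genes <- n_expr >= thresholds$min_genes
  keep <- ok_reads & ok_genes
  reason <- rep("", nrow(mat))
  reason[!ok_reads] <- "low_reads"
  reason[!ok_genes] <- paste0(reason[!ok_genes],
                              ifelse(reason[!ok_genes] == "", "", "+"),
                              "few_genes")
  report <- data.frame(cell = rownames(mat), reads = metadata$reads,
                       expressed_genes = n_expr, retained = keep,
                       reason = reason, stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("all cells excluded by QC thresholds", call. = FALSE)
  }
  list(matrix = mat[keep, , drop = FALSE],
       metadata = metadata[keep, , drop = FALSE],
       report = report)
}

#' Remove spike-in columns and rescale each cell to one million
#'
#' Drops spike-in transcripts (identified by prefix) and rescales each
#' cell's endogenous values so they sum to 1e6, restoring the TPM
#' interpretation as within-cell mRNA concentration.
#'
#' @param mat Cell-by-gene expression matrix including spike-in columns.
#' @param spike_prefix Identifier prefix flagging spike-in transcripts.
#' @return The endogenous-only matrix, each row summing to 1e6.
#' @export
strip_spikeins_and_rescale <- function(mat, spike_prefix = "ERCC-") {
  check_matrix(mat)
  spike <- spikein_columns(mat, spike_prefix)
  endo <- mat[, !spike, drop = FALSE]
  s <- rowSums(endo)
  if (any(s == 0)) {
    stop("cells with zero endogenous signal: ",
         paste(rownames(endo)[s == 0], collapse = ", "), call. = FALSE)
  }
  endo / s * 1e6
}

#' Filter genes by minimum expression prevalence
#'
#' Keeps genes whose value exceeds `min_tpm` (strictly) in at least
#' `min_cells` cells.
#'
#' @param mat Renormalized cell-by-gene matrix.
#' @param min_tpm Expression cutoff.
#' @param min_cells Minimum number of cells above the cutoff.
#' @return The matrix restricted to surviving genes.
#' @export
filter_genes <- function(mat, min_tpm = 1, min_cells = 3) {
  check_matrix(mat)
  keep <- colSums(mat > min_tpm) >= min_cells
  if (!any(keep)) warning("gene filter removed every gene")
  mat[, keep, drop = FALSE]
}

#' Per-cell endogenous mRNA-content proxy
#'
#' Spike-ins are added at fixed amounts per well, so the ratio of
#' endogenous to spike-in signal is proportional to the cell's mRNA
#' content. Computed on the matrix before spike-in stripping.
#'
#' @param mat Cell-by-gene matrix including spike-in columns.
#' @param spike_prefix Spike-in identifier prefix.
#' @return Named numeric vector (one value per cell).
#' @export
mrna_content_proxy <- function(mat, spike_prefix = "ERCC-") {
  check_matrix(mat)
  spike <- spikein_columns(mat, spike_prefix)
  if (!any(spike)) stop("no spike-in columns found", call. = FALSE)
  s <- rowSums(mat[, spike, drop = FALSE])
  if (any(s == 0)) {
    stop("cells with zero spike-in signal: ",
         paste(rownames(mat)[s == 0], collapse = ", "), call. = FALSE)
  }
  rowSums(mat[, !spike, drop = FALSE]) / s
}
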