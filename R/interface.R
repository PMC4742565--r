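#' Read a cell-by-gene expression matrix
#'
#' TSV format: cells in rows, genes in columns, first column holding cell
#' identifiers. MTX format: a MatrixMarket file with sidecar
#' `cells.tsv` / `genes.tsv` name files (one identifier per line) in the
#' same directory, rows = cells.
#'
#' @param path File path (for MTX, the `.mtx` file).
#' @param format `"tsv"` or `"mtx"` (guessed from the extension when
#'   missing).
#' @return Dense numeric matrix with cell row names and gene column
#'   names.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids)) {
      stop("duplicated cell identifiers: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    dir <- dirname(path)
    cells_file <- file.path(dir, "cells.tsv")
    genes_file <- file.path(dir, "genes.tsv")
    for (f in c(cells_file, genes_file)) {
      if (!file.exists(f)) stop("missing name file: ", f, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(cells_file)
    colnames(m) <- readLines(genes_file)
  }
  check_matrix(m)
  m
}

#' Write a cell-by-gene expression matrix
#'
#' @param mat Matrix with cell row names and gene column names.
#' @param path Output path (`.mtx` writes MatrixMarket plus `cells.tsv`
#'   and `genes.tsv` sidecars; anything else writes TSV).
#' @return The path, invisibly.
#' @export
write_matrix <- function(mat, path) {
  check_matrix(mat)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), file.path(dirname(path), "cells.tsv"))
    writeLines(colnames(mat), file.path(dirname(path), "genes.tsv"))
  } else {
    df <- data.frame(cell = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage's thresholds and seeds. Unknown keys are
#' rejected so typos cannot silently revert a setting to its default.
#'
#' @param qc [qc_thresholds()] for cell filtering.
#' @param min_tpm,min_cells Gene-filter settings.
#' @param spike_prefix Spike-in identifier prefix.
#' @param k,n_clusters,ica_seed ICA-composite ordering settings.
#' @param gplvm_top_genes,gplvm_restarts,gplvm_seed GPLVM settings.
#' @param marker_trees,marker_seed Marker-ranking settings.
#' @param dynamic_threshold,dynamic_restarts,dynamic_max_genes
#'   Dynamic-gene detection settings; `dynamic_max_genes` caps the fit to
#'   the most variable genes (`Inf` fits all).
#' @param trend_groups Number of trend groups.
#' @param ohnolog [ohnolog_thresholds()]; count thresholds are rescaled
#'   to the post-QC cell count when `ohnolog_autoscale` is `TRUE`.
#' @param ohnolog_autoscale See above.
#' @param alpha Two-group test significance level.
#' @param ... Rejected; guards against unknown keys.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            min_tpm = 1, min_cells = 3,
                            spike_prefix = "ERCC-",
                            k = 4, n_clusters = 6, ica_seed = 3984L,
                            gplvm_top_genes = 500, gplvm_restarts = 3,
                            gplvm_seed = 1L,
                            marker_trees = 1000, marker_seed = 1L,
                            dynamic_threshold = 8, dynamic_restarts = 3,
                            dynamic_max_genes = Inf,
                            trend_groups = 3,
                            ohnolog = ohnolog_thresholds(),
                            ohnolog_autoscale = TRUE,
                            alpha = 0.05, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$extra <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes QC, ICA-composite ordering, GPLVM cross-validation, marker
#' ranking, dynamic-gene detection with trend clustering, and (when a
#' pair list is given) ohnolog classification, and returns a
#' machine-readable report.
#'
#' @param mat Raw cell-by-gene TPM matrix including spike-ins.
#' @param metadata Per-cell metadata (`cell`, `fluorescence`, `reads`).
#' @param config A [pipeline_config()] list.
#' @param ohnolog_pairs Optional data frame with `gene_a`, `gene_b`.
#' @return A list of class `"pipeline_report"` with one element per
#'   stage plus a `summary` list of headline numbers.
#' @export
run_pipeline <- function(mat, metadata, config = pipeline_config(),
                         ohnolog_pairs = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  qc <- stage("qc", {
    f <- filter_cells(mat, metadata, config$qc)
    proxy <- mrna_content_proxy(f$matrix, config$spike_prefix)
    endo_all <- strip_spikeins_and_rescale(f$matrix, config$spike_prefix)
    endo <- filter_genes(endo_all, config$min_tpm, config$min_cells)
    list(matrix = endo, matrix_unfiltered = endo_all, metadata = f$metadata,
         report = f$report, mrna_proxy = proxy)
  })
  fluor <- stats::setNames(qc$metadata$fluorescence, qc$metadata$cell)
  ord <- stage("order", order_cells(qc$matrix, fluor, k = config$k,
                                    n_clusters = config$n_clusters,
                                    seed = config$ica_seed))
  gplvm <- stage("order-gplvm", {
    lp <- fit_gplvm_1d(qc$matrix, n_top_genes = config$gplvm_top_genes,
                       seed = config$gplvm_seed,
                       restarts = config$gplvm_restarts)
    lp <- align_orientation(lp, fluor)
    lp
  })
  agreement <- compare_orderings(
    ord$pseudotime$rank, gplvm$latent[names(ord$pseudotime$rank)])
  markers <- stage("markers", {
    stages <- setdiff(unique(ord$stages), "outlier")
    stats::setNames(lapply(stages, function(s)
      rank_markers(qc$matrix, ord$stages, s, n_trees = config$marker_trees,
                   seed = config$marker_seed)), stages)
  })
  dynamics <- stage("dynamics", {
    genes <- colnames(qc$matrix)
    if (is.finite(config$dynamic_max_genes) &&
        length(genes) > config$dynamic_max_genes) {
      v <- apply(log(qc$matrix + 1), 2, stats::var)
      genes <- names(sort(v, decreasing = TRUE))[seq_len(config$dynamic_max_genes)]
    }
    dg <- detect_dynamic_genes(qc$matrix, ord$pseudotime,
                               threshold = config$dynamic_threshold,
                               restarts = config$dynamic_restarts,
                               genes = genes)
    if (!is.null(dg$curves) && nrow(dg$curves) >= config$trend_groups) {
      dg <- cluster_trends(dg, config$trend_groups)
    }
    dg
  })
  ohnologs <- if (!is.null(ohnolog_pairs)) {
    stage("ohnologs", {
      thr <- config$ohnolog
      if (config$ohnolog_autoscale) {
        thr <- scale_ohnolog_thresholds(nrow(qc$matrix), thr)
      }
      # pairs expressed nowhere are a class of their own, so the
      # prevalence gene filter must not precede this stage
      classify_all(qc$matrix_unfiltered, ohnolog_pairs, thr)
    })
  } else NULL

  report <- list(
    qc = qc, order = ord, gplvm = gplvm, markers = markers,
    dynamics = dynamics, ohnologs = ohnologs, config = config,
    summary = list(
      cells_retained = nrow(qc$matrix),
      genes_retained = ncol(qc$matrix),
      ordering_agreement = agreement,
      n_dynamic_genes = sum(dynamics$results$dynamic, na.rm = TRUE),
      ohnolog_tally = if (!is.null(ohnologs)) as.list(ohnologs$tally) else NULL
    )
  )
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Pipeline report\n")
  cat("  cells retained:     ", s$cells_retained, "\n")
  cat("  genes retained:     ", s$genes_retained, "\n")
  cat("  ordering agreement: ", sprintf("%.3f", s$ordering_agreement),
      "(|Spearman|, ICA vs GPLVM)\n")
  cat("  dynamic genes:      ", s$n_dynamic_genes, "\n")
  if (!is.null(s$ohnolog_tally)) {
    cat("  ohnolog classes:    ",
        paste(names(s$ohnolog_tally), unlist(s$ohnolog_tally),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
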