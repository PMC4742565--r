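#' Rank marker genes for one cluster by Gini importance
#'
#' Trains a randomized-tree ensemble (one-vs-rest: member cells of the
#' target cluster against all other cells) on log(TPM+1) values and ranks
#' genes by impurity (Gini) feature importance, normalized to sum to 1.
#'
#' @param mat Cell-by-gene TPM matrix.
#' @param assignment Named per-cell cluster labels.
#' @param cluster Label of the target cluster.
#' @param n_trees Ensemble size (default 1000; larger values stabilize
#'   ranks further down the list).
#' @param seed Integer seed.
#' @return A list of class `"marker_ranking"`: `ranking` (data frame of
#'   gene and importance, sorted descending), `cluster`, `n_trees`,
#'   `seed`.
#' @export
rank_markers <- function(mat, assignment, cluster, n_trees = 1000,
                         seed = 1L) {
  check_matrix(mat)
  assignment <- assignment[rownames(mat)]
  if (anyNA(assignment)) stop("assignment missing for some cells", call. = FALSE)
  target <- factor(ifelse(assignment == cluster, "in", "rest"),
                   levels = c("in", "rest"))
  if (length(unique(target)) < 2) {
    stop("cluster must be nonempty and not contain all cells", call. = FALSE)
  }
  df <- as.data.frame(log(mat + 1))
  colnames(df) <- make.names(colnames(mat)) # ranger needs syntactic names
  fit <- ranger::ranger(
    x = df, y = target, num.trees = n_trees, importance = "impurity",
    seed = seed, classification = TRUE
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  structure(list(
    ranking = data.frame(gene = colnames(mat)[ord],
                         importance = unname(imp[ord]),
                         stringsAsFactors = FALSE),
    cluster = cluster, n_trees = n_trees, seed = seed
  ), class = "marker_ranking")
}

#' Fraction of cells expressing a gene, per cluster
#'
#' @param mat Cell-by-gene TPM matrix.
#' @param assignment Named per-cell cluster labels.
#' @param gene Gene identifier.
#' @param cutoff Expression cutoff; strictly greater counts as expressed.
#' @return Named numeric vector of fractions in `[0, 1]`, one per cluster.
#' @export
expression_fraction <- function(mat, assignment, gene, cutoff = 1) {
  check_matrix(mat)
  if (!gene %in% colnames(mat)) stop("unknown gene: ", gene, call. = FALSE)
  assignment <- assignment[rownames(mat)]
  expressed <- mat[, gene] > cutoff
  tapply(expressed, assignment, mean)
}
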