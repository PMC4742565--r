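#' Ohnolog classification thresholds
#'
#' Defaults are the decision-tree cutoffs used for a 363-cell dataset;
#' [scale_ohnolog_thresholds()] rescales them for other dataset sizes.
#'
#' @param not_expressed Pairs with more than this many cells expressing
#'   neither member are "NotExpressed".
#' @param xor `both_min_diff` values larger than this mark "XOR" pairs
#'   (mutually exclusive usage).
#' @param single Differences in per-member expressing-cell counts larger
#'   than this mark "Single" pairs (one member used).
#' @param cutoff TPM cutoff for binarization (strictly greater than).
#' @param not_expressed_rule `"cells"` (default): the NotExpressed test
#'   counts cells expressing neither member; `"per_gene"`: alternative
#'   reading requiring each member individually to be expressed in few
#'   cells (`n_cells - n_expr > not_expressed` for both members).
#' @return A named list of class `"ohnolog_thresholds"`.
#' @export
ohnolog_thresholds <- function(not_expressed = 300, xor = 15, single = 60,
                               cutoff = 1,
                               not_expressed_rule = c("cells", "per_gene")) {
  stopifnot(not_expressed > 0, xor > 0, single > 0, cutoff > 0)
  structure(list(not_expressed = not_expressed, xor = xor, single = single,
                 cutoff = cutoff,
                 not_expressed_rule = match.arg(not_expressed_rule)),
            class = "ohnolog_thresholds")
}

#' Rescale ohnolog thresholds to a dataset size
#'
#' Scales the count thresholds proportionally from their reference
#' dataset size (363 cells).
#'
#' @param n_cells Target dataset size.
#' @param thr Base thresholds.
#' @param reference Cell count the base thresholds refer to.
#' @return Rescaled `"ohnolog_thresholds"`.
#' @export
scale_ohnolog_thresholds <- function(n_cells, thr = ohnolog_thresholds(),
                                     reference = 363) {
  thr$not_expressed <- round(thr$not_expressed * n_cells / reference)
  thr$xor <- round(thr$xor * n_cells / reference)
  thr$single <- round(thr$single * n_cells / reference)
  thr
}

#' Binarize expression at a TPM cutoff
#'
#' @param mat Cell-by-gene TPM matrix.
#' @param cutoff Entries strictly greater than this are expressed.
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(mat, cutoff = 1) {
  check_matrix(mat)
  mat > cutoff
}

#' Co-expression counts for a gene pair
#'
#' @param bin Binarized (logical) cell-by-gene matrix.
#' @param gene_a,gene_b Gene identifiers.
#' @return Named integer vector `(n_onlyA, n_onlyB, n_both, n_none)`
#'   summing to the number of cells.
#' @export
count_pair <- function(bin, gene_a, gene_b) {
  missing <- setdiff(c(gene_a, gene_b), colnames(bin))
  if (length(missing)) stop("unknown gene(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  a <- bin[, gene_a]; b <- bin[, gene_b]
  c(n_onlyA = sum(a & !b), n_onlyB = sum(!a & b),
    n_both = sum(a & b), n_none = sum(!a & !b))
}

#' Classify one ohnolog pair
#'
#' Decision tree, evaluated in order:
#' \enumerate{
#'   \item NotExpressed — neither member expressed in more than
#'     `not_expressed` cells (`n_none > not_expressed`);
#'   \item XOR — `both_min_diff = min(n_onlyA, n_onlyB) - n_both` larger
#'     than `xor` (mutually exclusive usage);
#'   \item Single — difference between the members' expressing-cell
#'     counts (`|n_exprA - n_exprB|`, co-expressing cells included)
#'     larger than `single`;
#'   \item Mixed — everything else.
#' }
#'
#' @param counts Vector from [count_pair()].
#' @param n_cells Total cell count (consistency check).
#' @param thr An [ohnolog_thresholds()] list.
#' @return Class string.
#' @export
classify_pair <- function(counts, n_cells, thr = ohnolog_thresholds()) {
  if (sum(counts) != n_cells) {
    stop("pair counts do not sum to the number of cells", call. = FALSE)
  }
  n_expr_a <- counts[["n_onlyA"]] + counts[["n_both"]]
  n_expr_b <- counts[["n_onlyB"]] + counts[["n_both"]]
  not_expressed <- if (thr$not_expressed_rule == "cells") {
    counts[["n_none"]] > thr$not_expressed
  } else {
    n_cells - n_expr_a > thr$not_expressed &&
      n_cells - n_expr_b > thr$not_expressed
  }
  if (not_expressed) return("NotExpressed")
  both_min_diff <- min(counts[["n_onlyA"]], counts[["n_onlyB"]]) -
    counts[["n_both"]]
  if (both_min_diff > thr$xor) return("XOR")
  if (abs(n_expr_a - n_expr_b) > thr$single) return("Single")
  "Mixed"
}

#' Classify a list of ohnolog pairs
#'
#' @param mat Cell-by-gene TPM matrix.
#' @param pairs Data frame with columns `gene_a` and `gene_b`.
#' @param thr An [ohnolog_thresholds()] list.
#' @return A list: `records` (one row per resolvable pair: identifiers,
#'   counts, `both_min_diff`, class), `tally` (named class counts),
#'   `skipped` (pairs whose genes were absent from the matrix).
#' @export
classify_all <- function(mat, pairs, thr = ohnolog_thresholds()) {
  if (nrow(pairs) == 0) stop("empty ohnolog pair list", call. = FALSE)
  bin <- binarize(mat, thr$cutoff)
  known <- pairs$gene_a %in% colnames(mat) & pairs$gene_b %in% colnames(mat)
  skipped <- pairs[!known, , drop = FALSE]
  pairs <- pairs[known, , drop = FALSE]
  n <- nrow(mat)
  records <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    cnt <- count_pair(bin, pairs$gene_a[i], pairs$gene_b[i])
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               n_onlyA = cnt[["n_onlyA"]], n_onlyB = cnt[["n_onlyB"]],
               n_both = cnt[["n_both"]], n_none = cnt[["n_none"]],
               both_min_diff = min(cnt[["n_onlyA"]], cnt[["n_onlyB"]]) -
                 cnt[["n_both"]],
               class = classify_pair(cnt, n, thr),
               stringsAsFactors = FALSE)
  }))
  tally <- table(factor(records$class,
                        levels = c("NotExpressed", "XOR", "Single", "Mixed")))
  list(records = records, tally = tally, skipped = skipped)
}
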