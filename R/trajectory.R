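#' Spearman rank correlation
#'
#' Ties receive average ranks. Errors on zero-variance input, where the
#' coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Spearman correlation undefined for zero-variance input", call. = FALSE)
  }
  stats::cor(rx, ry)
}

# log(TPM+1), drop zero-variance genes, standardize columns, rows sorted by
# cell identifier so the ordering never depends on input row order.
prepare_factor_input <- function(mat, standardize = TRUE) {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  x <- log(mat + 1)
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0) stop("matrix is constant; no usable genes", call. = FALSE)
  if (standardize) x <- scale(x)
  x
}

#' Choose the number of latent components by reconstruction-error elbow
#'
#' Computes the Frobenius-norm reconstruction error of the best rank-k
#' approximation for k = 1..`k_max` and returns the largest k whose
#' marginal error reduction still exceeds `frac` times the k = 1 to 2
#' reduction.
#'
#' @param mat Cell-by-gene TPM matrix (log-transform applied internally).
#' @param k_max Largest k examined.
#' @param frac Elbow threshold as a fraction of the first reduction.
#' @return Integer k.
#' @export
choose_k <- function(mat, k_max = 10, frac = 0.1) {
  x <- prepare_factor_input(mat)
  k_max <- min(k_max, nrow(x) - 1L, ncol(x))
  d <- svd(x, nu = 0, nv = 0)$d
  err <- sqrt(rev(cumsum(rev(d^2))))[-1] # err[k] after keeping k components
  err <- c(err, 0)[seq_len(k_max)]
  if (err[1] < 1e-8 * sqrt(sum(d^2))) return(1L)
  red <- -diff(c(sqrt(sum(d^2)), err)) # red[k] = gain of adding component k
  if (k_max < 2) return(1L)
  thr <- frac * red[2]
  above <- which(red[-1] > thr) + 1L
  if (length(above) == 0) 1L else max(above)
}

#' Independent component analysis of cells
#'
#' FastICA with the logcosh contrast and symmetric decorrelation, run on
#' standardized log(TPM+1) values whitened by SVD. Returns per-cell source
#' signals (the latent factors); deterministic given the seed.
#'
#' @param mat Cell-by-gene TPM matrix.
#' @param k Number of components.
#' @param seed Integer seed for the random orthonormal initialization.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return A list of class `"latent_factors"`: `factors` (cells x k),
#'   `roles` (filled by [assign_factor_roles()]), `seed`.
#' @export
fit_ica <- function(mat, k = 4, seed = 3984L, max_iter = 500, tol = 1e-7) {
  x <- prepare_factor_input(mat)
  n <- nrow(x)
  stopifnot(k >= 1, k <= min(dim(x)))
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = k, nv = 0)
  if (sv$d[k] < 1e-10) stop("matrix rank below k; cannot whiten", call. = FALSE)
  z <- sv$u * sqrt(n) # whitened: n x k, unit covariance

  set.seed(seed)
  w <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  sym_decorrelate <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*% t(e$vectors) %*% w
  }
  w <- sym_decorrelate(w)
  for (it in seq_len(max_iter)) {
    wx <- z %*% t(w)            # n x k sources
    gwx <- tanh(wx)
    w_new <- (t(gwx) %*% z) / n - diag(colMeans(1 - gwx^2), k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop(sprintf("FastICA did not converge in %d iterations (delta %.2e)",
                 max_iter, delta), call. = FALSE)
  }
  s <- z %*% t(w)
  rownames(s) <- rownames(x)
  colnames(s) <- paste0("IC", seq_len(k))
  structure(list(factors = s, roles = NULL, seed = seed),
            class = "latent_factors")
}

#' Orient latent factors by fluorescence
#'
#' Flips the sign of each factor whose correlation with fluorescence is
#' negative, so a higher factor value always corresponds to a higher
#' fluorescence. Zero-variance factors are left unchanged with a warning.
#'
#' @param lf A `"latent_factors"` object.
#' @param fluorescence Named per-cell vector covering all cells.
#' @return The oriented `"latent_factors"` object.
#' @export
orient_factors <- function(lf, fluorescence) {
  f <- fluorescence[rownames(lf$factors)]
  if (anyNA(f)) stop("fluorescence missing for some cells", call. = FALSE)
  for (j in seq_len(ncol(lf$factors))) {
    if (stats::sd(lf$factors[, j]) == 0) {
      warning("zero-variance factor left unoriented: ", colnames(lf$factors)[j])
      next
    }
    if (stats::cor(lf$factors[, j], f) < 0) lf$factors[, j] <- -lf$factors[, j]
  }
  lf
}

#' Ward clustering of cells in latent-factor space
#'
#' @param lf A `"latent_factors"` object.
#' @param n_clusters Number of clusters (default 6).
#' @return Named integer vector of cluster indices.
#' @export
cluster_cells <- function(lf, n_clusters = 6) {
  stopifnot(n_clusters <= nrow(lf$factors))
  hc <- stats::hclust(stats::dist(lf$factors), method = "ward.D2")
  stats::cutree(hc, k = n_clusters)
}

#' Assign functional roles to latent factors
#'
#' Identifies, among k = 4 factors: the outlier factor (largest excess
#' kurtosis, driven by a few extreme cells), the difference factor
#' (largest absolute rank correlation with fluorescence: the low-to-high
#' switch), the within-small factor (largest variance among
#' below-median-fluorescence cells) and the within-large factor (the
#' remaining one).
#'
#' @param lf A `"latent_factors"` object with 4 factors.
#' @param fluorescence Named per-cell vector.
#' @return `lf` with `roles` set (named character vector over columns).
#' @export
assign_factor_roles <- function(lf, fluorescence) {
  s <- lf$factors
  stopifnot(ncol(s) == 4)
  f <- fluorescence[rownames(s)]
  kurt <- apply(s, 2, function(v) mean((v - mean(v))^4) / stats::var(v)^2 - 3)
  roles <- rep(NA_character_, 4)
  roles[which.max(kurt)] <- "outlier"
  rest <- which(is.na(roles))
  rho_f <- vapply(rest, function(j) abs(spearman(s[, j], f)), numeric(1))
  roles[rest[which.max(rho_f)]] <- "difference"
  rest <- which(is.na(roles))
  low <- f <= stats::median(f)
  v_low <- vapply(rest, function(j) stats::var(s[low, j]), numeric(1))
  roles[rest[which.max(v_low)]] <- "within_small"
  roles[which(is.na(roles))] <- "within_large"
  names(roles) <- colnames(s)
  lf$roles <- roles
  lf
}

#' Label clusters as developmental stages
#'
#' The cluster most loaded on the outlier factor (breaking ties toward the
#' smaller cluster) is labeled `"outlier"`; the remaining clusters are
#' ordered by median fluorescence, then median position on the oriented
#' difference factor, then size, then index, and labeled `1a`, `1b`, `2`,
#' `3`, `4`.
#'
#' @param assignment Named cluster-index vector from [cluster_cells()].
#' @param lf Oriented `"latent_factors"` with roles assigned.
#' @param fluorescence Named per-cell vector.
#' @return A list: `labels` (named per-cell stage labels) and `stage_of`
#'   (stage label per cluster index).
#' @export
label_clusters <- function(assignment, lf, fluorescence) {
  if (is.null(lf$roles)) stop("assign_factor_roles() first", call. = FALSE)
  s <- lf$factors
  f <- fluorescence[rownames(s)]
  assignment <- assignment[rownames(s)]
  idx <- sort(unique(assignment))
  out_load <- vapply(idx, function(cl)
    mean(abs(s[assignment == cl, lf$roles == "outlier"])), numeric(1))
  sizes <- vapply(idx, function(cl) sum(assignment == cl), numeric(1))
  # most extreme on the outlier factor; smaller cluster wins ties
  out_cl <- idx[order(-out_load, sizes)][1]
  rest <- setdiff(idx, out_cl)
  med_f <- vapply(rest, function(cl) stats::median(f[assignment == cl]), numeric(1))
  med_d <- vapply(rest, function(cl)
    stats::median(s[assignment == cl, lf$roles == "difference"]), numeric(1))
  ord <- rest[order(med_f, med_d, sizes[match(rest, idx)], rest)]
  stage_names <- c("1a", "1b", "2", "3", "4")[seq_along(ord)]
  stage_of <- stats::setNames(c(stage_names, "outlier"), c(ord, out_cl))
  labels <- stats::setNames(unname(stage_of[as.character(assignment)]),
                            names(assignment))
  list(labels = labels, stage_of = stage_of)
}

#' Assemble the staged composite pseudotime
#'
#' Outlier cells are set aside; the rest are sorted primarily by stage
#' (1a < 1b < 2 < 3 < 4) and within each stage by the latent factor that
#' explains that stage's variability — the non-outlier factor whose
#' within-stage rank correlation with fluorescence is strongest, its
#' direction aligned to that local fluorescence trend (the reporter level
#' is itself part of the composite ordering) — with ties broken by
#' fluorescence and then cell identifier. Ranks are 0-based.
#'
#' @param labels Per-cell stage labels from [label_clusters()].
#' @param lf Oriented `"latent_factors"` with roles.
#' @param fluorescence Named per-cell vector.
#' @return A list of class `"pseudotime"`: `rank` (named 0-based integer
#'   ranks over non-outlier cells) and `outliers` (cell identifiers).
#' @export
assemble_pseudotime <- function(labels, lf, fluorescence) {
  if (is.null(lf$roles)) stop("assign_factor_roles() first", call. = FALSE)
  if (anyNA(labels)) stop("missing stage labels", call. = FALSE)
  s <- lf$factors
  cells <- rownames(s)
  labels <- labels[cells]
  f <- fluorescence[cells]
  keep <- labels != "outlier"
  stage_order <- c("1a" = 1, "1b" = 2, "2" = 3, "3" = 4, "4" = 5)
  prog_cols <- which(lf$roles != "outlier")
  key_factor <- numeric(length(cells))
  for (st in unique(labels[keep])) {
    in_st <- keep & labels == st
    rr <- vapply(prog_cols, function(j) {
      if (stats::sd(s[in_st, j]) == 0 || stats::sd(f[in_st]) == 0) return(0)
      stats::cor(rank(s[in_st, j]), rank(f[in_st]))
    }, numeric(1))
    j <- which.max(abs(rr))
    key_factor[in_st] <- sign(rr[j] + (rr[j] == 0)) * s[in_st, prog_cols[j]]
  }
  ord <- order(stage_order[labels[keep]], key_factor[keep], f[keep],
               cells[keep])
  rank <- integer(sum(keep))
  rank[ord] <- seq_len(sum(keep)) - 1L
  structure(list(rank = stats::setNames(rank, cells[keep]),
                 outliers = cells[!keep]),
            class = "pseudotime")
}

#' Two-dimensional stochastic neighbor embedding of the latent factors
#'
#' Exact (O(n^2)) t-SNE: per-point Gaussian bandwidths matched to the
#' requested perplexity by bisection, symmetrized affinities, and gradient
#' descent with early exaggeration and momentum. Depiction only — nothing
#' downstream depends on it.
#'
#' @param lf A `"latent_factors"` object.
#' @param perplexity Effective neighborhood size (default 75).
#' @param seed Seed for the random initialization.
#' @param n_iter Gradient-descent iterations.
#' @return Cells-by-2 coordinate matrix.
#' @export
embed_2d <- function(lf, perplexity = 75, seed = 254L, n_iter = 500) {
  x <- lf$factors
  n <- nrow(x)
  if (perplexity >= n) stop("perplexity must be below the number of cells",
                            call. = FALSE)
  if (n <= 3 * perplexity) warning("perplexity is large relative to n")
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, -i] <- w / sw
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  exaggeration <- 4
  eta <- 200
  for (it in seq_len(n_iter)) {
    pe <- if (it <= 100) p * exaggeration else p
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pe - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    if (it == 250) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  rownames(y) <- rownames(x)
  colnames(y) <- c("tsne1", "tsne2")
  y
}

#' Regress pseudotime into a 2-D embedding as a smooth path
#'
#' Kernel-smooths (Nadaraya-Watson, Gaussian kernel) each embedding
#' coordinate against pseudotime rank and returns the path as an ordered
#' polyline.
#'
#' @param pt A `"pseudotime"` object.
#' @param embedding Cells-by-2 coordinates covering the ranked cells.
#' @param n_points Number of polyline vertices.
#' @param bandwidth Kernel bandwidth in rank units; defaults to n/20.
#' @return Data frame with columns `rank`, and one column per embedding
#'   dimension, ordered along pseudotime.
#' @export
regress_path <- function(pt, embedding, n_points = 100, bandwidth = NULL) {
  cells <- names(pt$rank)
  stopifnot(all(cells %in% rownames(embedding)))
  e <- embedding[cells, , drop = FALSE]
  r <- pt$rank
  if (is.null(bandwidth)) bandwidth <- max(length(r) / 20, 1)
  grid <- seq(min(r), max(r), length.out = n_points)
  w <- exp(-outer(grid, r, "-")^2 / (2 * bandwidth^2))
  w <- w / rowSums(w)
  path <- w %*% e
  out <- data.frame(rank = grid, path)
  names(out)[-1] <- colnames(embedding)
  out
}

#' ICA-composite pseudotime in one call
#'
#' Convenience wrapper chaining [fit_ica()], [orient_factors()],
#' [assign_factor_roles()], [cluster_cells()], [label_clusters()] and
#' [assemble_pseudotime()] on a QC'd, renormalized, gene-filtered matrix.
#'
#' @param mat Cell-by-gene TPM matrix (endogenous genes).
#' @param fluorescence Named per-cell fluorescence vector.
#' @param k Number of ICA components.
#' @param n_clusters Number of Ward clusters.
#' @param seed Seed for ICA.
#' @return A list: `pseudotime`, `factors`, `clusters`, `stages`.
#' @export
order_cells <- function(mat, fluorescence, k = 4, n_clusters = 6,
                        seed = 3984L) {
  lf <- fit_ica(mat, k = k, seed = seed)
  lf <- orient_factors(lf, fluorescence)
  lf <- assign_factor_roles(lf, fluorescence)
  cl <- cluster_cells(lf, n_clusters = n_clusters)
  lab <- label_clusters(cl, lf, fluorescence)
  pt <- assemble_pseudotime(lab$labels, lf, fluorescence)
  list(pseudotime = pt, factors = lf, clusters = cl, stages = lab$labels)
}
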