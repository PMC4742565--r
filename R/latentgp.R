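#' One-dimensional Gaussian-process latent variable model
#'
#' Fits a MAP GPLVM: every gene (column) is modeled as an independent draw
#' from a zero-mean GP over a shared one-dimensional latent coordinate
#' with an RBF kernel plus noise, and the latent coordinates and kernel
#' hyperparameters are optimized jointly on the exact log marginal
#' likelihood (plus a standard-normal prior on the latents) with analytic
#' gradients. The latent coordinate is the model's pseudotime; its
#' orientation is arbitrary.
#'
#' Genes are reduced to the `n_top_genes` most variable log-transformed
#' columns, which are centered before fitting. Initialization is the first
#' principal coordinate; additional restarts perturb it, and the best
#' objective is kept.
#'
#' @param mat Cell-by-gene TPM matrix (QC'd and renormalized).
#' @param n_top_genes Number of high-variance genes used (default 500).
#' @param n_inducing Accepted for interface compatibility; the exact
#'   (non-sparse) marginal likelihood is used at this scale.
#' @param seed Integer seed (restart perturbations).
#' @param restarts Number of optimizer restarts (first one unperturbed).
#' @param max_iter L-BFGS iteration cap per restart.
#' @return A list of class `"latent_position"`: `latent` (named per-cell
#'   coordinate), `hyperparams` (signal variance, length-scale, noise
#'   variance), `objective` (penalized log marginal likelihood), and
#'   `objective_trace` (best objective per restart).
#' @export
fit_gplvm_1d <- function(mat, n_top_genes = 500, n_inducing = NULL,
                         seed = 1L, restarts = 3, max_iter = 300) {
  x <- log(mat + 1)
  x <- x[order(rownames(x)), , drop = FALSE]
  v <- apply(x, 2, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, sum(v > 0)))]
  y <- scale(x[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  n <- nrow(y); d <- ncol(y)
  s_mat <- tcrossprod(y) # n x n outer-product matrix of the data

  # objective and gradient over par = c(latent (n), log sf2, log l2, log sn2)
  eval_model <- function(par) {
    lat <- par[seq_len(n)]
    sf2 <- exp(par[n + 1]); l2 <- exp(par[n + 2]); sn2 <- exp(par[n + 3])
    diff <- outer(lat, lat, "-")
    krbf <- sf2 * exp(-diff^2 / (2 * l2))
    k <- krbf + diag(sn2, n)
    ch <- tryCatch(chol(k), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = -Inf))
    kinv <- chol2inv(ch)
    a <- kinv %*% s_mat
    logdet <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * d * logdet - 0.5 * sum(diag(a)) - 0.5 * n * d * log(2 * pi)
    prior <- -0.5 * sum(lat^2)
    g_k <- 0.5 * (a %*% kinv - d * kinv) # dL/dK = (K^-1 S K^-1 - d K^-1)/2
    # latent gradient: dK_ij/dx_i = krbf_ij * (-(x_i-x_j)/l2)
    m <- (g_k + t(g_k)) * krbf * (-diff / l2)
    g_lat <- rowSums(m) - lat
    g_sf2 <- sum(g_k * krbf)                       # d/d log sf2
    g_l2 <- sum(g_k * krbf * diff^2 / (2 * l2))    # d/d log l2
    g_sn2 <- sum(diag(g_k)) * sn2                  # d/d log sn2
    list(obj = ll + prior, grad = c(g_lat, g_sf2, g_l2, g_sn2))
  }

  cache <- new.env()
  fn <- function(par) {
    r <- eval_model(par)
    assign("last", list(par = par, r = r), envir = cache)
    if (!is.finite(r$obj)) return(1e10)
    -r$obj
  }
  gr <- function(par) {
    last <- get0("last", envir = cache)
    r <- if (!is.null(last) && identical(last$par, par)) last$r else eval_model(par)
    if (!is.finite(r$obj)) return(rep(0, length(par)))
    -r$grad
  }

  pc1 <- svd(y, nu = 1, nv = 0)$u[, 1]
  pc1 <- pc1 / stats::sd(pc1)
  set.seed(seed)
  best <- NULL
  trace <- numeric(0)
  for (r_i in seq_len(restarts)) {
    init_lat <- if (r_i == 1) pc1 else pc1 + stats::rnorm(n, 0, 0.3 * r_i)
    par0 <- c(init_lat, log(stats::var(as.vector(y))), log(1), log(0.5))
    fit <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = max_iter)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    obj <- -fit$value
    trace <- c(trace, obj)
    if (is.null(best) || obj > best$obj) best <- list(par = fit$par, obj = obj)
  }
  if (is.null(best) || !is.finite(best$obj)) {
    stop("GPLVM optimization diverged in every restart; trace: ",
         paste(signif(trace, 4), collapse = ", "), call. = FALSE)
  }
  structure(list(
    latent = stats::setNames(best$par[seq_len(n)], rownames(y)),
    hyperparams = c(signal_variance = exp(best$par[n + 1]),
                    length_scale = sqrt(exp(best$par[n + 2])),
                    noise_variance = exp(best$par[n + 3])),
    objective = best$obj,
    objective_trace = trace
  ), class = "latent_position")
}

#' Align a latent ordering's orientation to a reference
#'
#' The GPLVM latent coordinate is defined up to sign; this flips it when
#' its correlation with the reference is negative.
#'
#' @param lp A `"latent_position"` object.
#' @param reference Named per-cell numeric vector.
#' @return The (possibly flipped) `"latent_position"`.
#' @export
align_orientation <- function(lp, reference) {
  ref <- reference[names(lp$latent)]
  if (anyNA(ref)) stop("reference missing for some cells", call. = FALSE)
  if (stats::sd(ref) == 0) stop("zero-variance reference", call. = FALSE)
  if (stats::cor(lp$latent, ref) < 0) lp$latent <- -lp$latent
  lp
}

#' Agreement between two pseudotime orderings
#'
#' @param a,b Named per-cell numeric orderings over the same cell set.
#' @return Absolute Spearman correlation.
#' @export
compare_orderings <- function(a, b) {
  if (!setequal(names(a), names(b))) {
    stop("orderings are defined on different cell sets", call. = FALSE)
  }
  abs(spearman(a, b[names(a)]))
}
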