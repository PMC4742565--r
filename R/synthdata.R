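#' Default parameters for the synthetic single-cell generator
#'
#' Builds the parameter list consumed by [generate_dataset()]. The defaults
#' describe a plate-based (Smart-seq2-like) index-sorted experiment over a
#' one-dimensional differentiation continuum: five semi-discrete
#' transcriptional states plus a small outlier group, a low/high bimodal
#' fluorescence reporter, monotone marker genes, three dynamic trend groups
#' (transient peak, monotone decline, rise-then-plateau), declining
#' endogenous mRNA content and expressed-gene count along the continuum,
#' constant-amount spike-in transcripts, log-normal expression noise,
#' expression-dependent dropout, and planted ohnolog pair classes.
#'
#' @param n_cells Number of on-trajectory cells.
#' @param n_genes Number of endogenous genes (includes markers, trend
#'   groups, ohnolog members, outlier-program genes and flat genes).
#' @param n_spikeins Number of spike-in transcripts (identifier prefix
#'   `"ERCC-"`).
#' @param n_states Number of developmental states along the continuum.
#' @param state_centers,state_sd Centers (on the pseudotime axis, in
#'   `[0,1]`) and spread of the truncated-normal mixture cells are drawn
#'   from; the gaps between centers make states resolvable by clustering
#'   while keeping the continuum.
#' @param state_props Mixture weights; must sum to 1.
#' @param outlier_frac Fraction of additional off-trajectory outlier cells
#'   (high FSC/SSC, distinct expression program).
#' @param n_markers Number of monotone-increasing marker genes (the first
#'   two are tagged cd41-like and EGFP-like).
#' @param n_group1,n_group2,n_group3 Sizes of the three dynamic trend
#'   groups: I = up-then-down, II = monotone down, III = up-then-plateau.
#' @param n_outlier_genes Genes of the outlier-specific program.
#' @param n_ohnolog_pairs_per_class Planted ohnolog pairs for each of the
#'   four classes (NotExpressed, XOR, Single, Mixed).
#' @param noise_sd Log-scale standard deviation of expression noise.
#' @param dropout_base,dropout_slope Per-cell dropout probability is
#'   `dropout_base + dropout_slope * t` for a cell at pseudotime `t`,
#'   attenuated per gene by mean expression (highly expressed transcripts
#'   rarely drop out).
#' @param dropout_k Mean-expression scale (TPM-like units) of the dropout
#'   attenuation `k / (k + mu)`.
#' @param content_decay Exponential decay rate of endogenous mRNA content
#'   along pseudotime; drives the rising spike-in fraction.
#' @param content_noise_sd Log-scale noise on per-cell mRNA content.
#' @param spikein_amount Spike-in amount relative to the mRNA content of a
#'   cell at `t = 0`.
#' @param fluor_base,fluor_slope,fluor_jump,fluor_switch,fluor_switch_width,fluor_noise_sd
#'   Fluorescence model: `fluor_base * exp(fluor_slope * t) *
#'   (1 + fluor_jump * plogis((t - fluor_switch)/fluor_switch_width))`
#'   with log-normal noise; the jump produces the low/high bimodality.
#' @param mean_reads,reads_sd Log-normal read-count model.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   parameter list (which includes the seed).
#'
#' @return A named list of class `"generator_params"`.
#' @export
generator_params <- function(n_cells = 288,
                             n_genes = 500,
                             n_spikeins = 20,
                             n_states = 5,
                             state_centers = c(0.10, 0.28, 0.45, 0.60, 0.85),
                             state_sd = 0.045,
                             state_props = c(0.22, 0.14, 0.15, 0.14, 0.35),
                             outlier_frac = 0.01,
                             n_markers = 10,
                             n_group1 = 40,
                             n_group2 = 40,
                             n_group3 = 40,
                             n_outlier_genes = 30,
                             n_ohnolog_pairs_per_class = 6,
                             noise_sd = 0.28,
                             dropout_base = 0.18,
                             dropout_slope = 0.30,
                             dropout_k = 20,
                             content_decay = 2.0,
                             content_noise_sd = 0.12,
                             spikein_amount = 0.35,
                             fluor_base = 100,
                             fluor_slope = 1.5,
                             fluor_jump = 9,
                             fluor_switch = 0.70,
                             fluor_switch_width = 0.04,
                             fluor_noise_sd = 0.20,
                             mean_reads = 1e6,
                             reads_sd = 0.4,
                             seed = 3984L) {
  p <- as.list(environment())
  validate_generator_params(p)
  class(p) <- "generator_params"
  p
}

validate_generator_params <- function(p) {
  stopifnot(
    p$n_cells > 0, p$n_genes > 0, p$n_spikeins > 0, p$n_states > 0,
    length(p$state_centers) == p$n_states,
    length(p$state_props) == p$n_states
  )
  if (abs(sum(p$state_props) - 1) > 1e-8) {
    stop("state proportions must sum to 1", call. = FALSE)
  }
  if (any(p$state_props <= 0)) {
    stop("every state must have positive proportion", call. = FALSE)
  }
  if (p$dropout_base < 0 || p$dropout_base + p$dropout_slope > 1 ||
      p$outlier_frac < 0 || p$outlier_frac >= 1) {
    stop("dropout rates and outlier fraction must be probabilities", call. = FALSE)
  }
  n_special <- p$n_markers + p$n_group1 + p$n_group2 + p$n_group3 +
    p$n_outlier_genes + 8 * p$n_ohnolog_pairs_per_class
  if (n_special > p$n_genes) {
    stop("n_genes too small for the requested gene programs", call. = FALSE)
  }
  invisible(p)
}

# Smooth 0->1 ramp on [a, b]; constant outside.
smoothstep <- function(t, a, b) {
  x <- pmin(pmax((t - a) / (b - a), 0), 1)
  x * x * (3 - 2 * x)
}

# Mean log2-TPM-scale curves for the planted gene classes, over t in [0,1].
trend_curve <- function(class, t, pars) {
  switch(class,
    marker_cd41 = 2.0 + 8.0 * t^1.2,
    marker_egfp = 1.0 + 6.0 * t^1.8,
    marker_mono = pars$lo + pars$amp * t^pars$expo,
    group1 = pars$lo + pars$amp * exp(-(t - pars$peak)^2 / (2 * pars$width^2)),
    group2 = pars$lo + pars$amp * (1 - smoothstep(t, pars$a, pars$b)),
    group3 = pars$lo + pars$amp * smoothstep(t, pars$a, pars$b),
    flat = rep(pars$lo, length(t)),
    stop("unknown gene class: ", class)
  )
}

#' Generate a synthetic single-cell dataset with known ground truth
#'
#' Simulates a TPM-scale cell-by-gene expression matrix (each cell summing
#' to one million across endogenous genes plus spike-ins), per-cell
#' index-sort metadata, and a ground-truth record. See
#' [generator_params()] for the statistical structure emulated.
#'
#' The composition of a cell is built from log-normal draws around
#' class-specific mean curves of the true pseudotime, thinned by
#' expression-dependent dropout; the split between endogenous and spike-in
#' signal follows the cell's decaying mRNA content, so the spike-in
#' fraction rises along the continuum. Ohnolog-pair members are planted
#' directly as on/off patterns realizing their class so the classifier's
#' recovery can be checked exactly.
#'
#' @param params A list from [generator_params()].
#' @return A list with elements `matrix` (cells x genes, TPM), `metadata`
#'   (data.frame, one row per cell) and `truth` (list with `cells`,
#'   `genes`, `ohnolog_pairs` data.frames plus `params`).
#' @export
generate_dataset <- function(params = generator_params()) {
  validate_generator_params(params)
  p <- params
  set.seed(p$seed)

  n_out <- max(if (p$outlier_frac > 0) 1L else 0L,
               round(p$n_cells * p$outlier_frac))
  n_traj <- p$n_cells
  n <- n_traj + n_out

  ## --- cells: pseudotime from a truncated-normal mixture over states
  state <- sample.int(p$n_states, n_traj, replace = TRUE, prob = p$state_props)
  if (length(unique(state)) < p$n_states) {
    stop("a mandatory state received zero cells; increase n_cells", call. = FALSE)
  }
  t_traj <- stats::rnorm(n_traj, p$state_centers[state], p$state_sd)
  t_traj <- pmin(pmax(t_traj, 0), 1)
  # keep states ordered in t even where mixture tails overlap
  state <- state[order(t_traj)]
  t_traj <- sort(t_traj)

  cells <- sprintf("cell_%03d", seq_len(n))
  is_outlier <- c(rep(FALSE, n_traj), rep(TRUE, n_out))
  true_t <- c(t_traj, rep(NA_real_, n_out))
  true_state <- c(paste0("S", state), rep("outlier", n_out))

  ## --- genes: classes and identifiers
  classes <- c("marker_cd41", "marker_egfp",
               rep("marker_mono", p$n_markers - 2),
               rep("group1", p$n_group1),
               rep("group2", p$n_group2),
               rep("group3", p$n_group3),
               rep("outlier_program", p$n_outlier_genes))
  npc <- p$n_ohnolog_pairs_per_class
  ohno_classes <- rep(c("NotExpressed", "XOR", "Single", "Mixed"), each = npc)
  classes <- c(classes, rep("ohnolog", 8 * npc))
  classes <- c(classes, rep("flat", p$n_genes - length(classes)))
  genes <- sprintf("gene_%04d", seq_len(p$n_genes))
  spikes <- sprintf("ERCC-%04d", seq_len(p$n_spikeins))
  tag <- rep(NA_character_, p$n_genes)
  tag[classes == "marker_cd41"] <- "cd41_like"
  tag[classes == "marker_egfp"] <- "egfp_like"

  ## --- per-gene curve parameters
  gene_pars <- vector("list", p$n_genes)
  for (g in seq_len(p$n_genes)) {
    cl <- classes[g]
    gene_pars[[g]] <- switch(cl,
      marker_mono = list(lo = stats::runif(1, 0.5, 1.5), amp = stats::runif(1, 5.0, 7.0),
                         expo = stats::runif(1, 0.5, 2.5)),
      group1 = list(lo = stats::runif(1, 0.5, 1.5), amp = stats::runif(1, 5.0, 7.0),
                    peak = stats::runif(1, 0.25, 0.60), width = stats::runif(1, 0.10, 0.15)),
      group2 = local({a <- stats::runif(1, 0.0, 0.45)
                      list(lo = stats::runif(1, 0.5, 1.5), amp = stats::runif(1, 5.0, 7.0),
                           a = a, b = a + stats::runif(1, 0.20, 0.40))}),
      group3 = local({a <- stats::runif(1, 0.45, 0.85)
                      list(lo = stats::runif(1, 0.5, 1.5), amp = stats::runif(1, 5.0, 7.0),
                           a = a, b = a + stats::runif(1, 0.10, 0.20))}),
      flat = list(lo = stats::runif(1, 0.5, 5.0)),
      list(lo = NA)
    )
  }

  ## --- raw endogenous intensities (2^log2-mean * lognormal noise, dropout)
  t_all <- ifelse(is_outlier, 0.15, true_t) # outliers get baseline curves
  raw <- matrix(0, nrow = n, ncol = p$n_genes,
                dimnames = list(cells, genes))
  p_cell <- p$dropout_base + p$dropout_slope * ifelse(is_outlier, 0, t_all)
  for (g in seq_len(p$n_genes)) {
    cl <- classes[g]
    if (cl == "ohnolog") next # planted below
    curve_cl <- if (cl %in% c("outlier_program")) "flat" else cl
    mu_log2 <- trend_curve(curve_cl, t_all, gene_pars[[g]])
    if (cl == "outlier_program") {
      mu_log2 <- ifelse(is_outlier, 10, -2)
    }
    mu <- 2^mu_log2
    keep <- stats::rbinom(n, 1, 1 - p_cell * p$dropout_k / (p$dropout_k + mu))
    raw[, g] <- keep * mu * exp(stats::rnorm(n, 0, p$noise_sd * log(2)))
  }

  ## --- planted ohnolog on/off patterns
  ohno_idx <- which(classes == "ohnolog")
  pair_a <- ohno_idx[seq(1, length(ohno_idx), by = 2)]
  pair_b <- ohno_idx[seq(2, length(ohno_idx), by = 2)]
  on_value <- function(k) 2^stats::runif(k, 4.5, 6.5) # well above 1 TPM post-rescale
  for (i in seq_along(pair_a)) {
    cl <- ohno_classes[i]
    a <- logical(n); b <- logical(n)
    if (cl == "NotExpressed") {
      on <- sample.int(n, max(1, round(0.02 * n)))
      a[on] <- TRUE
      b[sample.int(n, max(1, round(0.02 * n)))] <- TRUE
    } else if (cl == "XOR") {
      ord <- sample.int(n)
      a[ord[seq_len(round(0.45 * n))]] <- TRUE
      b[ord[round(0.45 * n) + seq_len(round(0.45 * n))]] <- TRUE
    } else if (cl == "Single") {
      a[sample.int(n, round(0.80 * n))] <- TRUE
      b[sample.int(n, round(0.03 * n))] <- TRUE
    } else { # Mixed
      a[stats::runif(n) < 0.72] <- TRUE
      b[stats::runif(n) < 0.72] <- TRUE
    }
    raw[, pair_a[i]] <- a * on_value(n)
    raw[, pair_b[i]] <- b * on_value(n)
  }

  ## --- spike-ins: constant amounts, mild noise
  spike_base <- 2^stats::runif(p$n_spikeins, 2, 7)
  raw_spike <- matrix(
    rep(spike_base, each = n) * exp(stats::rnorm(n * p$n_spikeins, 0, 0.15)),
    nrow = n, dimnames = list(cells, spikes)
  )

  ## --- compose TPM: endogenous share follows decaying mRNA content
  content <- exp(-p$content_decay * ifelse(is_outlier, 0.1, t_all)) *
    exp(stats::rnorm(n, 0, p$content_noise_sd))
  f_spike <- p$spikein_amount / (p$spikein_amount + content)
  endo_sum <- rowSums(raw)
  if (any(endo_sum == 0)) stop("degenerate cell with zero endogenous signal")
  tpm <- cbind(raw / endo_sum * (1 - f_spike) * 1e6,
               raw_spike / rowSums(raw_spike) * f_spike * 1e6)

  ## --- index-sort metadata
  base_f <- p$fluor_base * exp(p$fluor_slope * t_all) *
    (1 + p$fluor_jump * stats::plogis((t_all - p$fluor_switch) / p$fluor_switch_width))
  fluor <- base_f * exp(stats::rnorm(n, 0, p$fluor_noise_sd))
  fluor[is_outlier] <- max(base_f) * exp(stats::rnorm(n_out, 0, p$fluor_noise_sd))
  fsc <- exp(stats::rnorm(n, log(200), 0.15))
  ssc <- exp(stats::rnorm(n, log(150), 0.15))
  # outliers stochastically dominate every state in size and granularity
  fsc[is_outlier] <- exp(stats::rnorm(n_out, log(800), 0.10))
  ssc[is_outlier] <- exp(stats::rnorm(n_out, log(600), 0.10))
  reads <- round(p$mean_reads * exp(stats::rnorm(n, 0, p$reads_sd)))
  gate <- p$fluor_base * exp(p$fluor_slope * p$fluor_switch) * (1 + p$fluor_jump / 2)
  population <- ifelse(fluor > gate, "EGFPhigh", "EGFPlow")

  metadata <- data.frame(
    cell = cells,
    fluorescence = fluor,
    fsc = fsc,
    ssc = ssc,
    population = population,
    reads = reads,
    tissue = "kidney",
    plate = "plate_1",
    well = sprintf("%s%02d", LETTERS[(seq_len(n) - 1L) %/% 24L + 1L],
                   (seq_len(n) - 1L) %% 24L + 1L),
    stringsAsFactors = FALSE
  )

  truth <- list(
    cells = data.frame(cell = cells, pseudotime = true_t, state = true_state,
                       stringsAsFactors = FALSE),
    genes = data.frame(
      gene = c(genes, spikes),
      class = c(ifelse(classes %in% c("marker_cd41", "marker_egfp",
                                      "marker_mono"),
                       "marker", classes),
                rep("spikein", p$n_spikeins)),
      tag = c(tag, rep(NA_character_, p$n_spikeins)),
      stringsAsFactors = FALSE
    ),
    ohnolog_pairs = data.frame(
      gene_a = genes[pair_a], gene_b = genes[pair_b],
      class = ohno_classes, stringsAsFactors = FALSE
    ),
    params = p
  )

  list(matrix = tpm, metadata = metadata, truth = truth)
}

#' Generate a QC-test plate with planted failing cells
#'
#' Produces a dataset in which exactly `n_failures` cells fall below both
#' the read-count and expressed-gene QC thresholds, for exercising
#' [filter_cells()].
#'
#' @param params A [generator_params()] list (`n_cells` is the plate size).
#' @param n_failures Number of cells to fail; must be at most `n_cells`.
#' @param thresholds A [qc_thresholds()] list the failures are planted
#'   against.
#' @return A list with `matrix` and `metadata`.
#' @export
generate_qc_plate <- function(params = generator_params(n_cells = 96),
                              n_failures = 5,
                              thresholds = qc_thresholds(min_genes = 100)) {
  stopifnot(n_failures >= 0, n_failures <= params$n_cells)
  params$outlier_frac <- 0
  ds <- generate_dataset(params)
  set.seed(params$seed + 1L)
  n <- nrow(ds$matrix)
  fail <- sample.int(n, n_failures)
  if (n_failures > 0) {
    ds$metadata$reads[fail] <- round(thresholds$min_reads / 2)
    # silence genes until below the expressed-gene threshold
    for (i in fail) {
      v <- ds$matrix[i, ]
      expressed <- which(v > thresholds$expression_cutoff)
      n_keep <- max(0L, thresholds$min_genes - 1L)
      if (length(expressed) > n_keep) {
        drop <- expressed[-seq_len(n_keep)]
        v[drop] <- 0
        ds$matrix[i, ] <- v / sum(v) * 1e6
      }
    }
  }
  list(matrix = ds$matrix, metadata = ds$metadata)
}
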