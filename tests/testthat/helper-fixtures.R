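# Shared fixtures. The default dataset and its derived orderings are
# expensive (GPLVM), so they are computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_dataset <- function() {
  fixture("default_dataset", generate_dataset())
}

# parameters for a small, fast dataset used by unit tests
small_params <- function(n_cells = 110, seed = 11L, ...) {
  generator_params(n_cells = n_cells, n_genes = 220, n_markers = 6,
                   n_group1 = 15, n_group2 = 15, n_group3 = 15,
                   n_outlier_genes = 12, n_ohnolog_pairs_per_class = 3,
                   n_spikeins = 10, seed = seed, ...)
}

small_dataset <- function() {
  fixture("small_dataset", generate_dataset(small_params()))
}

# QC'd, renormalized, gene-filtered endogenous matrix of the default set
default_qc <- function() {
  fixture("default_qc", {
    ds <- default_dataset()
    f <- filter_cells(ds$matrix, ds$metadata, qc_thresholds(min_genes = 100))
    endo <- strip_spikeins_and_rescale(f$matrix)
    list(matrix = filter_genes(endo), metadata = f$metadata)
  })
}

default_order <- function() {
  fixture("default_order", {
    qc <- default_qc()
    fl <- stats::setNames(qc$metadata$fluorescence, qc$metadata$cell)
    order_cells(qc$matrix, fl)
  })
}

default_gplvm <- function() {
  fixture("default_gplvm", fit_gplvm_1d(default_qc()$matrix, seed = 1L))
}

truth_pseudotime <- function(ds) {
  stats::setNames(ds$truth$cells$pseudotime, ds$truth$cells$cell)
}

truth_state <- function(ds) {
  stats::setNames(ds$truth$cells$state, ds$truth$cells$cell)
}

# tiny named matrix builder for hand examples
toy_matrix <- function(values, cells = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cells %||% sprintf("c%d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
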