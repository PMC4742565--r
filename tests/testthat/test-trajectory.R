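# builds a TPM-like matrix whose log(TPM+1) equals the given latent signal
signal_to_tpm <- function(x) {
  m <- exp(x - min(x)) - 1
  toy_matrix(m)
}

test_that("spearman matches the rank definition and rejects degenerate input", {
  x <- c(3, 1, 4, 2, 5)
  expect_equal(spearman(x, x), 1)
  expect_equal(spearman(sort(x), rev(sort(x))), -1) # reversed ordering
  xt <- c(3, 1, 4, 1, 5) # ties: average ranks, checked against the
  y <- c(2, 2, 9, 4, 7)  # explicit rank-based formula
  expect_equal(spearman(xt, y), cor(rank(xt), rank(y)))
  expect_error(spearman(rep(1, 5), x), "zero-variance")
})

test_that("component count is chosen at the reconstruction-error elbow", {
  set.seed(10)
  n <- 120
  mk_sources <- function(k) {
    s <- cbind(runif(n)^2, sin(seq_len(n) / 7), rbinom(n, 1, 0.3),
               sample(c(-2, 0, 2), n, TRUE))[, seq_len(k), drop = FALSE]
    scale(s)
  }
  mix <- function(s) s %*% matrix(rnorm(ncol(s) * 150, sd = 2), ncol(s), 150)
  x4 <- mix(mk_sources(4)) + matrix(rnorm(n * 150, sd = 0.05), n)
  expect_equal(choose_k(signal_to_tpm(x4)), 4)
  x2 <- mix(mk_sources(2)) + matrix(rnorm(n * 150, sd = 0.05), n)
  expect_equal(choose_k(signal_to_tpm(x2)), 2)
  r1 <- signal_to_tpm(outer(rnorm(n), rnorm(150))) # rank 1 on the log scale
  expect_equal(choose_k(r1), 1)
})

test_that("FastICA recovers independent sources up to permutation and sign", {
  set.seed(21)
  n <- 400
  s_true <- scale(cbind(runif(n), rexp(n),
                        sample(c(-2, 2), n, TRUE) + runif(n, -0.2, 0.2),
                        runif(n)^3))
  x <- s_true %*% matrix(rnorm(4 * 300), 4, 300) +
    matrix(rnorm(n * 300, sd = 0.01), n)
  mat <- signal_to_tpm(x)
  lf <- fit_ica(mat, k = 4, seed = 1L)
  # brute-force matching over factors and signs (rows back in input order)
  best <- apply(abs(cor(lf$factors[rownames(mat), ], s_true)), 2, max)
  expect_true(all(best >= 0.99))
  # determinism
  lf2 <- fit_ica(mat, k = 4, seed = 1L)
  expect_identical(lf$factors, lf2$factors)
  # row-permutation invariance (identifier order is canonicalized)
  perm <- sample(n)
  lf3 <- fit_ica(mat[perm, ], k = 4, seed = 1L)
  expect_equal(lf3$factors, lf$factors, tolerance = 1e-6)
})

test_that("orientation flips factors against fluorescence and is idempotent", {
  set.seed(3)
  f <- runif(50)
  fac <- cbind(-f + rnorm(50, sd = 0.1), f + rnorm(50, sd = 0.3))
  rownames(fac) <- sprintf("c%02d", 1:50)
  lf <- structure(list(factors = fac, roles = NULL, seed = 1L),
                  class = "latent_factors")
  fl <- stats::setNames(f, rownames(fac))
  o1 <- orient_factors(lf, fl)
  expect_gt(cor(o1$factors[, 1], f), 0)
  expect_equal(o1$factors[, 2], fac[, 2]) # already positive: unchanged
  expect_identical(orient_factors(o1, fl)$factors, o1$factors)
})

test_that("Ward clustering separates planted blobs and co-clusters duplicates", {
  set.seed(5)
  centers <- matrix(rnorm(6 * 4, sd = 12), 6, 4)
  lab <- rep(1:6, each = 20)
  pts <- centers[lab, ] + matrix(rnorm(120 * 4, sd = 0.5), 120, 4)
  rownames(pts) <- sprintf("c%03d", 1:120)
  lf <- structure(list(factors = pts), class = "latent_factors")
  cl <- cluster_cells(lf, 6)
  expect_equal(mclust::adjustedRandIndex(cl, lab), 1)
  # duplicated points merge first
  dup <- pts; dup[2, ] <- dup[1, ]
  lfd <- structure(list(factors = dup), class = "latent_factors")
  cld <- cluster_cells(lfd, 6)
  expect_equal(cld[1], cld[2], ignore_attr = TRUE)
  # one cluster per cell at the degenerate extreme
  expect_equal(length(unique(cluster_cells(lf, nrow(pts)))), nrow(pts))
})

test_that("a small extreme group is labeled outlier and stages follow fluorescence", {
  ds <- default_dataset()
  ord <- fixture("default_order", {
    qc <- default_qc()
    fl <- stats::setNames(qc$metadata$fluorescence, qc$metadata$cell)
    order_cells(qc$matrix, fl)
  })
  st <- truth_state(ds)
  planted_out <- names(st)[st == "outlier"]
  expect_setequal(ord$pseudotime$outliers, planted_out)
  # stage medians of true pseudotime are increasing 1a < 1b < 2 < 3 < 4
  tr <- truth_pseudotime(ds)
  med <- tapply(tr[names(ord$stages)], ord$stages, median, na.rm = TRUE)
  stages <- c("1a", "1b", "2", "3", "4")
  expect_true(all(diff(med[stages]) > 0))
})

test_that("pseudotime assembly sorts by stage then factor", {
  fac <- cbind(c(0.3, -1.0, 2.0, 0.5, 0.1, 0.9), 0, 0,
               c(0, 0, 0, 0, 0, 0))
  rownames(fac) <- paste0("c", 1:6)
  colnames(fac) <- paste0("IC", 1:4)
  roles <- c(IC1 = "within_small", IC2 = "difference", IC3 = "within_large",
             IC4 = "outlier")
  lf <- structure(list(factors = fac, roles = roles), class = "latent_factors")
  fl <- stats::setNames(c(0.3, -1, 2, 0.5, 0.1, 0.9), rownames(fac))
  # single stage: order by the factor
  labels <- stats::setNames(rep("1a", 6), rownames(fac))
  pt <- assemble_pseudotime(labels, lf, fl)
  expect_equal(unname(pt$rank[c("c2", "c5", "c1", "c4", "c6", "c3")]), 0:5)
  # two stages: brute-force lexicographic (stage, factor) order
  labels2 <- stats::setNames(c("4", "4", "4", "1a", "1a", "1a"), rownames(fac))
  pt2 <- assemble_pseudotime(labels2, lf, fl)
  brute <- order(c(2, 2, 2, 1, 1, 1), fac[, 1])
  expect_equal(unname(pt2$rank[rownames(fac)[brute]]), 0:5)
  expect_error(assemble_pseudotime(stats::setNames(rep(NA, 6), rownames(fac)),
                                   lf, fl), "missing stage")
})

test_that("pipeline ordering is deterministic and row-order invariant", {
  qc <- default_qc()
  fl <- stats::setNames(qc$metadata$fluorescence, qc$metadata$cell)
  ord1 <- fixture("default_order", order_cells(qc$matrix, fl))
  set.seed(77)
  perm <- sample(nrow(qc$matrix))
  ord2 <- order_cells(qc$matrix[perm, ], fl)
  expect_equal(ord2$pseudotime$rank[names(ord1$pseudotime$rank)],
               ord1$pseudotime$rank)
  expect_gte(spearman(ord1$pseudotime$rank,
                      fl[names(ord1$pseudotime$rank)]), 0)
})

test_that("2-D embedding is deterministic and separates distant groups", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(40 * 4), 40, 4),
               matrix(rnorm(40 * 4, mean = 25), 40, 4))
  rownames(pts) <- sprintf("c%02d", 1:80)
  lf <- structure(list(factors = pts), class = "latent_factors")
  e1 <- embed_2d(lf, perplexity = 15, seed = 254L, n_iter = 300)
  e2 <- embed_2d(lf, perplexity = 15, seed = 254L, n_iter = 300)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(80, 2))
  inter <- sqrt(sum((colMeans(e1[1:40, ]) - colMeans(e1[41:80, ]))^2))
  intra <- mean(c(dist(e1[1:40, ]), dist(e1[41:80, ])))
  expect_gt(inter, intra)
  expect_error(embed_2d(lf, perplexity = 80), "perplexity")
})

test_that("pseudotime path regression stays anchored to the data", {
  set.seed(13)
  n <- 60
  rank <- stats::setNames(sample(0:(n - 1)), sprintf("c%02d", 1:n))
  emb <- cbind(rank[sprintf("c%02d", 1:n)] / 10 + rnorm(n, sd = 0.1),
               rnorm(n, sd = 0.1))
  rownames(emb) <- sprintf("c%02d", 1:n)
  colnames(emb) <- c("tsne1", "tsne2")
  pt <- structure(list(rank = rank, outliers = character(0)),
                  class = "pseudotime")
  path <- regress_path(pt, emb)
  # endpoints near the rank-extreme cells' mean coordinates
  first_dec <- names(sort(rank))[1:6]
  last_dec <- names(sort(rank, decreasing = TRUE))[1:6]
  expect_lt(abs(path$tsne1[1] - mean(emb[first_dec, 1])), 1)
  expect_lt(abs(path$tsne1[nrow(path)] - mean(emb[last_dec, 1])), 1)
  # polyline length at least the straight-line endpoint distance
  seg <- sqrt(diff(path$tsne1)^2 + diff(path$tsne2)^2)
  straight <- sqrt((path$tsne1[nrow(path)] - path$tsne1[1])^2 +
                   (path$tsne2[nrow(path)] - path$tsne2[1])^2)
  expect_gte(sum(seg), straight)
  # constant embedding gives a constant path
  embc <- emb; embc[, 1] <- 2; embc[, 2] <- -1
  pc <- regress_path(pt, embc)
  expect_true(all(abs(pc$tsne1 - 2) < 1e-9) && all(abs(pc$tsne2 + 1) < 1e-9))
})
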