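test_that("constant-kernel likelihood matches its analytic oracles", {
  set.seed(14)
  # centered fit equals the i.i.d. Gaussian density at fitted mean/variance
  for (i in 1:3) {
    y <- rnorm(35, mean = runif(1, -2, 4), sd = runif(1, 0.3, 2))
    cf <- gp_loglik_const(NULL, y)
    oracle <- sum(dnorm(y, mean(y), sqrt(mean((y - mean(y))^2)), log = TRUE))
    expect_equal(cf$loglik, oracle, tolerance = 1e-8)
  }
  # uncentered fit matches a numeric optimizer over both kernel variances
  y <- rnorm(30, mean = 3, sd = 1.2)
  obj <- function(p) {
    n <- length(y)
    k <- exp(p[1]) * matrix(1, n, n) + diag(exp(p[2]), n)
    ch <- chol(k)
    0.5 * (2 * sum(log(diag(ch))) +
             sum(y * backsolve(ch, forwardsolve(t(ch), y))) + n * log(2 * pi))
  }
  num <- -optim(c(0, 0), obj, method = "Nelder-Mead",
                control = list(maxit = 3000, reltol = 1e-12))$value
  expect_equal(gp_loglik_const(NULL, y, center = FALSE)$loglik, num,
               tolerance = 1e-4)
  # exchangeable: permuting cells jointly with pseudotime changes nothing
  y <- rnorm(30)
  expect_equal(gp_loglik_const(1:30, y)$loglik,
               gp_loglik_const(30:1, sample(y))$loglik, tolerance = 1e-9)
  # constant input is guarded by the noise floor, stays finite
  expect_true(is.finite(gp_loglik_const(NULL, rep(2, 20))$loglik))
})

test_that("the RBF model wins on dynamic genes and ties on flat ones", {
  set.seed(15)
  x <- seq(0, 1, length.out = 100)
  y_dyn <- 2 * sin(2 * pi * x) + rnorm(100, sd = 0.3)
  ratio_dyn <- gp_loglik_rbf(x, y_dyn)$loglik - gp_loglik_const(x, y_dyn)$loglik
  expect_gt(ratio_dyn, 50)
  y_flat <- rnorm(100, 1, 0.5)
  ratio_flat <- gp_loglik_rbf(x, y_flat)$loglik -
    gp_loglik_const(x, y_flat)$loglik
  expect_lt(ratio_flat, 8)
  # the evidence gap grows with the number of cells
  x2 <- seq(0, 1, length.out = 200)
  y2 <- 2 * sin(2 * pi * x2) + rnorm(200, sd = 0.3)
  ratio2 <- gp_loglik_rbf(x2, y2)$loglik - gp_loglik_const(x2, y2)$loglik
  expect_gt(ratio2, ratio_dyn)
})

test_that("log likelihood ratio is invariant to affine rescaling of y", {
  set.seed(16)
  x <- seq(0, 1, length.out = 80)
  y <- sin(2 * pi * x) + rnorm(80, sd = 0.4)
  r1 <- gp_loglik_rbf(x, y)$loglik - gp_loglik_const(x, y)$loglik
  y2 <- 3.7 * y + 11
  r2 <- gp_loglik_rbf(x, y2)$loglik - gp_loglik_const(x, y2)$loglik
  expect_equal(r1, r2, tolerance = 0.05)
})

trend_fixture <- function(n_cells = 90, per_group = 8, seed = 17) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n_cells)
  curves <- list(
    I = function(t) 4 * exp(-(t - 0.45)^2 / 0.02),
    II = function(t) 4 * (1 - plogis((t - 0.35) / 0.08)),
    III = function(t) 4 * plogis((t - 0.35) / 0.08)
  )
  cols <- list(); truth <- character(0)
  for (g in names(curves)) {
    for (i in seq_len(per_group)) {
      cols[[paste0(g, "_", i)]] <- curves[[g]](t) + rnorm(n_cells, sd = 0.25)
      truth <- c(truth, g)
    }
  }
  y <- do.call(cbind, cols)
  mat <- exp(y - min(y)) - 1
  rownames(mat) <- sprintf("c%03d", seq_len(n_cells))
  list(matrix = mat, pt = stats::setNames(t, rownames(mat)),
       truth = stats::setNames(truth, colnames(mat)))
}

test_that("dynamic genes are flagged and trend groups recover planted shapes", {
  fx <- trend_fixture()
  dg <- detect_dynamic_genes(fx$matrix, fx$pt, restarts = 2)
  expect_true(all(dg$results$dynamic))
  dg <- cluster_trends(dg)
  called <- stats::setNames(dg$results$group, dg$results$gene)
  expect_gte(mclust::adjustedRandIndex(called[names(fx$truth)], fx$truth), 0.9)
  # shape labels follow the planted semantics
  expect_true(all(called[fx$truth == "II"] == "II"))
  expect_true(all(called[fx$truth == "I"] == "I"))
  # an infinite threshold flags nothing
  dg_inf <- detect_dynamic_genes(fx$matrix[, 1:4], fx$pt, threshold = Inf,
                                 restarts = 1)
  expect_false(any(dg_inf$results$dynamic))
})

test_that("identical curves fall into one trend group and labels are stable", {
  fx <- trend_fixture(per_group = 3)
  dg <- detect_dynamic_genes(fx$matrix, fx$pt, restarts = 2)
  same <- dg
  same$curves <- matrix(rep(sin(seq(0, 3, length.out = ncol(dg$curves))), 9),
                        nrow = 9, byrow = TRUE,
                        dimnames = list(rownames(dg$curves)[1:9], NULL))
  same$results <- same$results[1:9, ]
  out <- cluster_trends(same, n_groups = 1)
  expect_equal(length(unique(out$results$group[1:9])), 1)
  # determinism
  a <- cluster_trends(dg)
  b <- cluster_trends(dg)
  expect_identical(a$results, b$results)
  expect_error(cluster_trends(dg, n_groups = nrow(dg$curves) + 1), "fewer")
})

# step-down definition written independently, straight from the formula
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, a)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

test_that("Holm-Sidak adjustment matches the step-down definition", {
  expect_equal(holm_sidak(c(0.01, 0.04, 0.30)),
               c(1 - 0.99^3, 1 - 0.96^2, 0.30))
  expect_equal(holm_sidak(c(0.01, 0.04, 0.30))[1], 0.029701)
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(c(0, 1, 0.5)), c(0, 1, 1 - 0.5^2))
  expect_error(holm_sidak(c(0.1, 1.2)), "\\[0, 1\\]")
  # exhaustive check over permutations for m <= 6
  set.seed(18)
  for (m in 1:6) {
    p <- round(runif(m), 3)
    # all permutations, generated recursively
    allp <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in allp(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      }
      out
    }
    for (pp in allp(p)) {
      expect_equal(holm_sidak(pp), holm_sidak_oracle(pp))
    }
  }
  # invariants: adjusted >= raw, in [0,1], monotone along sorted sequence
  p <- runif(25)
  a <- holm_sidak(p)
  expect_true(all(a >= p) && all(a <= 1))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
})

test_that("two-group test flags a planted shift and not equal groups", {
  set.seed(19)
  n <- 40
  m <- matrix(rlnorm(2 * n * 60, 1, 0.6), 2 * n, 60)
  rownames(m) <- sprintf("c%02d", seq_len(2 * n))
  colnames(m) <- sprintf("g%02d", seq_len(60))
  a <- rownames(m)[1:n]; b <- rownames(m)[(n + 1):(2 * n)]
  # plant a 4-sd mean shift on the log scale in one gene
  lg <- log(m[, "g01"] + 1)
  m[a, "g01"] <- exp(lg[a] + 4 * sd(lg)) - 1
  res <- compare_groups(m, a, b)
  expect_true(res$significant[res$gene == "g01"])
  expect_false(any(res$significant[res$gene != "g01"]))
  expect_true(all(res$p_adjusted >= res$p))
  # equal group means and variances give a near-zero statistic
  eq <- toy_matrix(matrix(rep(c(1, 2, 3, 4, 5), 8), ncol = 2))
  stat <- compare_groups(eq, rownames(eq)[1:10], rownames(eq)[11:20])$statistic
  expect_lt(max(abs(stat)), 1e-9)
  expect_error(compare_groups(m, a[1], b), "at least 2")
})

test_that("false-positive rate on flat genes stays near nominal", {
  set.seed(20)
  fpr <- replicate(50, {
    m <- matrix(rlnorm(60 * 30, 1, 0.5), 60, 30)
    rownames(m) <- sprintf("c%02d", 1:60)
    colnames(m) <- sprintf("g%02d", 1:30)
    res <- compare_groups(m, rownames(m)[1:30], rownames(m)[31:60])
    mean(res$p < 0.05)
  })
  se <- sd(fpr) / sqrt(length(fpr))
  expect_lte(mean(fpr), 0.05 + 2 * se)
})
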