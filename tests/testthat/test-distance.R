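test_that("Gower partial dissimilarities match hand-computed values", {
  ds <- tiny_mixed_ds()
  D <- gower_podani(ds)
  # i1 vs i2: binary mismatch (1) + quantitative |2-4|/range 4 (0.5)
  expect_equal(D$d["i1", "i2"], (1 + 0.5) / 2)
  # i1 vs i3: binary match (0) + |2-6|/4 = 1
  expect_equal(D$d["i1", "i3"], 0.5)
  expect_equal(diag(D$d), setNames(rep(0, 3), ds$individuals))
  expect_true(all(D$d >= 0 & D$d <= 1))

  # identical individuals are at distance zero
  ds0 <- morpho_dataset(c("a", "b"), c("P", "P"), ds$descriptors,
                        ds$values[c(1, 1), ])
  expect_equal(gower_podani(ds0)$d["a", "b"], 0)
})

test_that("ordinal characters follow Podani's tie-corrected formula cell by cell", {
  ds <- ordinal_tie_ds()
  D <- gower_podani(ds)
  oracle <- podani_oracle(ds$values$bract, ds$descriptors$levels[[1]])
  expect_equal(unname(D$d), oracle, tolerance = 1e-12)

  # without ties, Podani reduces to plain rank-range scaling
  desc <- ds$descriptors
  ds2 <- morpho_dataset(paste0("i", 1:4), rep("A", 4), desc,
                        data.frame(bract = c("round", "acute", "mucronate",
                                             "apiculate")))
  D2 <- gower_podani(ds2)
  expect_equal(D2$d["i1", "i4"], 1)
  expect_equal(D2$d["i1", "i2"], 1 / 3)
})

test_that("missing values are excluded pair by pair, not imputed", {
  desc <- character_descriptors(c("q1", "q2"),
                                rep("quantitative_continuous", 2))
  ds <- morpho_dataset(paste0("i", 1:3), rep("A", 3), desc,
                       data.frame(q1 = c(0, 1, NA), q2 = c(0, 2, 4)))
  D <- gower_podani(ds)
  # i1 vs i3 can only use q2: |0-4|/4 = 1
  expect_equal(D$d["i1", "i3"], 1)
  # i1 vs i2 uses both: (1/1 + 2/4)/2
  expect_equal(D$d["i1", "i2"], 0.75)

  ds_all_na <- morpho_dataset(paste0("i", 1:3), rep("A", 3), desc,
                              data.frame(q1 = rep(NA_real_, 3),
                                         q2 = c(0, 2, 4)))
  expect_warning(gower_podani(ds_all_na), "entirely missing")
})

test_that("dissimilarity is invariant to character and individual order", {
  spec <- morpho_sim_spec(n_populations = 3, n_per_pop = 5, n_quant = 4,
                          n_binary = 2, n_nominal = 1, n_ordinal = 2,
                          effect_sd = 1, qual_effect = 0.2, seed = 11)
  ds <- gen_morpho_dataset(spec)
  D <- gower_podani(ds)
  perm <- rev(seq_len(nrow(ds$descriptors)))
  dsp <- morpho_dataset(ds$individuals, ds$populations,
                        {
                          d <- ds$descriptors[perm, ]
                          class(d) <- class(ds$descriptors); d
                        },
                        ds$values[, perm])
  expect_equal(gower_podani(dsp)$d, D$d, tolerance = 1e-12)

  iperm <- rev(seq_along(ds$individuals))
  dsi <- morpho_dataset(ds$individuals[iperm], ds$populations[iperm],
                        ds$descriptors, ds$values[iperm, ])
  expect_equal(gower_podani(dsi)$d[ds$individuals, ds$individuals], D$d,
               tolerance = 1e-12)
})

test_that("euclidean_check separates embeddable from non-embeddable matrices", {
  pts <- matrix(c(0, 0, 1, 0, 0.3, 1, 0.9, 0.8), ncol = 2, byrow = TRUE)
  D <- euclidean_check(planar_distance(pts))
  expect_true(D$is_euclidean)

  # triangle inequality violated: d(1,2)=d(1,3)=1 but d(2,3)=3
  m <- matrix(c(0, 1, 1, 1,
                1, 0, 3, 1,
                1, 3, 0, 1,
                1, 1, 1, 0), 4, 4)
  Dn <- euclidean_check(dissimilarity_matrix(m))
  expect_false(Dn$is_euclidean)
  expect_lt(Dn$min_eigenvalue, 0)
  expect_error(euclidean_check(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Cailliez constant matches bisection and the correction is idempotent", {
  m <- matrix(c(0, 1, 1, 1,
                1, 0, 3, 1.2,
                1, 3, 0, 1.1,
                1, 1.2, 1.1, 0), 4, 4)
  res <- cailliez_correction(dissimilarity_matrix(m))
  expect_true(res$D$is_euclidean)
  expect_equal(res$D$d[1, 2], 1 + res$c)

  # oracle: bisection on c over euclidean_check
  f <- function(cc) {
    mm <- m + cc; diag(mm) <- 0
    euclidean_check(dissimilarity_matrix(mm))$is_euclidean
  }
  lo <- 0; hi <- 10
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid)) hi <- mid else lo <- mid
  }
  expect_equal(res$c, hi, tolerance = 1e-6)

  # already-Euclidean input is untouched; second application adds nothing
  res2 <- cailliez_correction(res$D)
  expect_equal(res2$c, 0)
  expect_equal(res2$D$d, res$D$d)
})

test_that("Cailliez correction yields Euclidean matrices across random inputs", {
  set.seed(20)
  for (r in 1:15) {
    n <- sample(4:8, 1)
    m <- matrix(0, n, n)
    v <- runif(n * (n - 1) / 2, 0.2, 2)
    m[upper.tri(m)] <- v
    m <- m + t(m)
    res <- cailliez_correction(dissimilarity_matrix(m))
    expect_true(res$D$is_euclidean)
    expect_gte(res$c, 0)
  }
})

test_that("PCoA reproduces distances of Euclidean configurations", {
  # 3 collinear points, d = 1, 1, 2: one positive axis with spacings 1, 1
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  p <- pcoa(dissimilarity_matrix(m), m = 1)
  expect_equal(sum(p$eigenvalues > 1e-8), 1)
  ax <- sort(p$coordinates[, 1])
  expect_equal(diff(ax), c(1, 1), tolerance = 1e-8, ignore_attr = TRUE)

  set.seed(7)
  pts <- matrix(rnorm(40), ncol = 4)
  D <- planar_distance(pts)
  pc <- pcoa(D, m = 4)
  expect_equal(as.matrix(dist(pc$coordinates)), unname(D$d),
               ignore_attr = TRUE, tolerance = 1e-8)
  # total positive eigenvalue mass equals the trace of the centred matrix
  B <- -0.5 * D$d^2
  B <- sweep(sweep(B, 1, rowMeans(B)), 2, colMeans(B)) + mean(B)
  expect_equal(sum(p$eigenvalues), sum(diag(
    local({
      b <- -0.5 * m^2
      sweep(sweep(b, 1, rowMeans(b)), 2, colMeans(b)) + mean(b)
    }))), tolerance = 1e-10)
  expect_equal(sum(pc$eigenvalues), sum(diag(B)), tolerance = 1e-8)

  # agreement with the classical-scaling reference implementation
  ref <- stats::cmdscale(D$d, k = 4, eig = TRUE)
  expect_equal(abs(pc$coordinates), abs(ref$points), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("gower+cailliez pipelines always embed with non-negative spectra", {
  for (s in 1:5) {
    ds <- gen_morpho_dataset(morpho_sim_spec(
      n_populations = 3, n_per_pop = 4, n_quant = 3, n_binary = 2,
      n_nominal = 1, n_ordinal = 1, qual_effect = 0.3, seed = s))
    D <- euclidean_check(gower_podani(ds))
    if (!isTRUE(D$is_euclidean)) D <- cailliez_correction(D)$D
    p <- suppressWarnings(pcoa(D, m = 2))
    expect_gte(min(p$eigenvalues), -1e-8 * max(p$eigenvalues))
  }
})

test_that("sampling adequacy reports KMO and Bartlett on the correlation matrix", {
  # exactly uncorrelated columns (principal component scores): det R = 1
  set.seed(3)
  raw <- matrix(rnorm(200 * 4), 200, 4)
  sc <- prcomp(raw)$x
  desc <- character_descriptors(colnames(sc),
                                rep("quantitative_continuous", 4))
  ds <- morpho_dataset(paste0("i", 1:200), rep("A", 200), desc,
                       as.data.frame(sc))
  sa <- sampling_adequacy(ds)
  expect_equal(sa$bartlett_chisq, 0, tolerance = 1e-6)
  expect_equal(sa$bartlett_p, 1, tolerance = 1e-6)
  expect_equal(sa$bartlett_df, 6)

  # correlated block: KMO rises; partials validated against regression
  # residual correlations (independent oracle for the anti-image values)
  z <- rnorm(200)
  X <- cbind(x1 = z + rnorm(200, 0, 0.3), x2 = z + rnorm(200, 0, 0.3),
             x3 = z + rnorm(200, 0, 0.3), x4 = rnorm(200))
  desc2 <- character_descriptors(colnames(X),
                                 rep("quantitative_continuous", 4))
  ds2 <- morpho_dataset(paste0("i", 1:200), rep("A", 200), desc2,
                        as.data.frame(X))
  sa2 <- sampling_adequacy(ds2)
  expect_gt(sa2$kmo_msa, 0.5)
  expect_lt(sa2$bartlett_p, 1e-10)

  part_oracle <- function(X, i, j) {
    rest <- setdiff(seq_len(ncol(X)), c(i, j))
    ri <- resid(lm(X[, i] ~ X[, rest]))
    rj <- resid(lm(X[, j] ~ X[, rest]))
    cor(ri, rj)
  }
  R <- cor(X); Ri <- solve(R)
  s <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(s, s)
  for (pr in list(c(1, 2), c(1, 4), c(3, 4)))
    expect_equal(Q[pr[1], pr[2]], part_oracle(scale(X), pr[1], pr[2]),
                 tolerance = 1e-10)
  r2 <- sum(R[upper.tri(R)]^2); q2 <- sum(Q[upper.tri(Q)]^2)
  expect_equal(sa2$kmo_msa, r2 / (r2 + q2), tolerance = 1e-12)
})
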