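test_that("ANOSIM R is 1 for maximal separation and matches brute force", {
  # 2+2 points: within-distances 1, between-distances 2
  m <- matrix(2, 4, 4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 1
  diag(m) <- 0
  a <- anosim(dissimilarity_matrix(m), c("A", "A", "B", "B"),
              n_perm = 99, seed = 1)
  expect_equal(a$R, 1)

  # 6-point instance: R equals an independent double-loop recomputation and
  # the p-value equals exhaustive enumeration over all label permutations
  set.seed(5)
  pts <- matrix(rnorm(12), ncol = 2)
  pts[4:6, 1] <- pts[4:6, 1] + 1.5
  D <- planar_distance(pts)
  g <- rep(c("A", "B"), each = 3)
  a6 <- anosim(D, g, n_perm = 999, seed = 2)

  brute_R <- function(d, g) {
    n <- nrow(d)
    dv <- c(); wv <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dv <- c(dv, d[i, j]); wv <- c(wv, g[i] == g[j])
    }
    rk <- rank(dv)
    (mean(rk[!wv]) - mean(rk[wv])) / (length(dv) / 2)
  }
  expect_equal(a6$R, brute_R(D$d, g), tolerance = 1e-12)

  # exhaustive permutation null
  perms <- combn(6, 3)
  nullR <- apply(perms, 2, function(ix) {
    gg <- rep("B", 6); gg[ix] <- "A"
    brute_R(D$d, gg)
  })
  p_exact <- mean(nullR >= a6$R - 1e-12)
  expect_lt(abs(a6$p - p_exact), 0.05)

  skip_if_not_installed("vegan")
  va <- vegan::anosim(as.dist(D$d), factor(g), permutations = 99)
  expect_equal(a6$R, unname(va$statistic), tolerance = 1e-12)
})

test_that("ANOSIM R is rank-based: invariant under monotone transforms", {
  set.seed(9)
  pts <- matrix(rnorm(20), ncol = 2)
  D <- planar_distance(pts)
  g <- rep(c("A", "B"), each = 5)
  r1 <- anosim(D, g, n_perm = 99, seed = 3)$R
  Dsq <- dissimilarity_matrix(D$d^2)
  Dlg <- dissimilarity_matrix(log1p(D$d))
  expect_equal(anosim(Dsq, g, n_perm = 99, seed = 3)$R, r1)
  expect_equal(anosim(Dlg, g, n_perm = 99, seed = 3)$R, r1)
  expect_error(anosim(D, c("A", rep("B", 9)), n_perm = 99), ">= 2 members")
})

test_that("kappa and percent correct reproduce the published worked example", {
  cm <- published_confusion()
  expect_equal(percent_correct(cm), 100 * 194 / 223)
  expect_equal(round(percent_correct(cm)), 87)
  # p_o = 194/223, p_e = 17434/49729
  expect_equal(kappa_statistic(cm),
               (194 / 223 - 17434 / 49729) / (1 - 17434 / 49729))
  expect_equal(round(kappa_statistic(cm), 4), 0.7998)
  expect_equal(round(kappa_statistic(cm), 1), 0.8)

  # perfect, chance-level, and degenerate matrices
  expect_equal(kappa_statistic(diag(5) * 3), 1)
  expect_equal(percent_correct(diag(3)), 100)
  expect_equal(percent_correct(matrix(c(0, 2, 3, 0), 2, 2)), 0)
  # prediction independent of truth (outer-product counts): p_o = p_e
  expect_equal(kappa_statistic(outer(c(2, 4), c(3, 3))), 0)
  expect_equal(kappa_statistic(outer(c(10, 20, 30), c(12, 18, 30))), 0)
  expect_true(is.na(kappa_statistic(matrix(c(5, 0, 0, 0), 2, 2))))
})

test_that("kappa is invariant under simultaneous label permutation", {
  cm <- published_confusion()
  perm <- c(3, 1, 4, 2)
  cm2 <- confusion_matrix(unclass(cm)[perm, perm], rownames(cm)[perm])
  expect_equal(kappa_statistic(cm2), kappa_statistic(cm))
  expect_equal(percent_correct(cm2), percent_correct(cm))
})

test_that("jackknifed LDA separates planted groups and agrees with MASS on easy data", {
  spec <- morpho_sim_spec(n_populations = 4, n_per_pop = 15, n_quant = 10,
                          n_binary = 0, n_nominal = 0, n_ordinal = 0,
                          effect_sd = 5, n_effect_quant = 10, seed = 21)
  ds <- gen_morpho_dataset(spec)
  enc <- encode_qualitative(ds)
  g <- group_labels(ds, grouping_hypothesis(
    "true", setNames(paste0("G", rep(1:2, 2)), unique(ds$populations))))
  rep <- jackknife_lda(enc$x, g)
  expect_gt(rep$percent_correct, 95)
  expect_gt(rep$kappa, 0.75)
  expect_equal(sum(rep$confusion), length(g))
  expect_equal(unname(rowSums(rep$confusion)), unname(table(g)[rownames(rep$confusion)]),
               ignore_attr = TRUE)

  skip_if_not_installed("MASS")
  pred <- character(length(g))
  for (i in seq_along(g)) {
    fit <- MASS::lda(enc$x[-i, ], g[-i])
    pred[i] <- as.character(predict(fit, enc$x[i, , drop = FALSE])$class)
  }
  cm_mass <- table(g, pred)
  expect_equal(unname(diag(rep$confusion)), unname(diag(cm_mass)))
})

test_that("jackknife kappa is near zero when labels carry no information", {
  spec <- morpho_sim_spec(n_populations = 10, n_per_pop = 20, n_quant = 8,
                          n_binary = 0, n_nominal = 0, n_ordinal = 0,
                          effect_sd = 0, seed = 33)
  ds <- gen_morpho_dataset(spec)
  enc <- encode_qualitative(ds)
  g <- local({
    set.seed(77)
    sample(rep(c("X", "Y"), each = 100))
  })
  rep <- jackknife_lda(enc$x, g)
  expect_lt(abs(rep$kappa), 0.1)
})

test_that("constant training columns and singular covariances are handled", {
  X <- cbind(a = c(1, 1, 1, 1, 2, 2, 2, 2),
             b = c(0, 0, 0, 0.5, 3, 3, 3, 3.5),
             const = rep(5, 8))
  g <- rep(c("A", "B"), each = 4)
  w <- capture_warnings(rep <- jackknife_lda(X, g))
  expect_true(any(grepl("constant column", w)))
  expect_gt(rep$percent_correct, 80)
})

test_that("stepwise selection tracks exhaustive Wilks search and honours thresholds", {
  set.seed(13)
  n <- 60
  g <- rep(c("A", "B", "C"), each = n / 3)
  gi <- as.integer(factor(g))
  X <- cbind(v1 = gi * 2 + rnorm(n, 0, 0.7),
             v2 = rnorm(n),
             v3 = gi + rnorm(n, 0, 2))
  wl <- function(vars) {
    Xs <- X[, vars, drop = FALSE]
    Tm <- crossprod(sweep(Xs, 2, colMeans(Xs)))
    W <- matrix(0, length(vars), length(vars))
    for (c0 in unique(g)) {
      Xc <- Xs[g == c0, , drop = FALSE]
      W <- W + crossprod(sweep(Xc, 2, colMeans(Xc)))
    }
    det(W) / det(Tm)
  }
  # first entered variable must be the exhaustive single-variable argmin
  best1 <- colnames(X)[which.min(sapply(colnames(X), wl))]
  rep <- stepwise_lda(X, g)
  expect_equal(rep$selected_variables[1], best1)
  # the selected set's Wilks' lambda is no worse than any same-size subset
  k <- length(rep$selected_variables)
  subsets <- combn(colnames(X), k, simplify = FALSE)
  expect_lte(wl(rep$selected_variables),
             min(sapply(subsets, wl)) + 1e-10)

  # f_enter = Inf admits nothing: empty model, chance-level report
  rep0 <- stepwise_lda(X, g, f_enter = Inf, f_remove = 1)
  expect_length(rep0$selected_variables, 0)
  expect_lte(rep0$percent_correct, 100 / 3 + 1e-9)
  expect_error(stepwise_lda(X, g, f_enter = 1, f_remove = 2), "exceed")
})

test_that("confusion matrices serialize with correct margins", {
  cm <- published_confusion()
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion(cm, path)
  tab <- read.csv(path, row.names = 1)
  expect_equal(tab["Total", "Total"], 223)
  expect_equal(unname(unlist(tab["apennina", 1:4])), c(46, 5, 8, 0))
  expect_equal(tab[["Total"]][1:4], c(59, 110, 34, 20))
  expect_equal(unname(unlist(tab["Total", 1:4])), c(54, 115, 37, 17))
})
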