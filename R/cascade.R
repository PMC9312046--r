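# Adaptive per-character univariate testing. Each character is routed to a
# test family by its type and by normality/homoscedasticity diagnostics,
# pairwise group comparisons are run within that family, and Holm's
# correction is applied across the pairwise family of each character.

#' Holm step-down adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by (m - i + 1), enforces
#' monotone non-decrease, caps at 1, and returns the adjusted values in the
#' original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(p[o] * (m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Select the appropriate test for one character
#'
#' Decision tree for quantitative characters: Shapiro-Wilk on pooled
#' group-standardized residuals (group shifts and scale differences must not
#' look like non-normality) at the diagnostic alpha (default 0.01, following the
#' per-character testing convention); if non-normal and all values
#' positive, the test is repeated on log-transformed values (log-normal
#' branch). Normal or
#' log-normal data go to Bartlett's homoscedasticity test, routing to
#' ANOVA + Tukey-Kramer or Welch ANOVA + Games-Howell; non-normal data go to
#' the Levene-Brown-Forsythe test (median-centred), routing to
#' Kruskal-Wallis + pairwise Wilcoxon or a pairwise permutation test.
#' Nominal/binary characters use pairwise Fisher's exact tests; ordinal
#' characters a pairwise linear-by-linear (ordinal association) permutation
#' test on level scores.
#'
#' @param values numeric vector (quantitative) or character vector of states
#'   (qualitative).
#' @param groups group label per observation.
#' @param ctype the character's type string.
#' @param levels declared level order (qualitative characters).
#' @param alpha diagnostic significance level (default 0.01).
#' @return List with `test` (identifier), `log_transform` flag, and
#'   `diagnostics` (statistics + p of the checks performed).
#' @export
select_test <- function(values, groups, ctype = "quantitative_continuous",
                        levels = NULL, alpha = 0.01) {
  groups <- as.character(groups)
  if (is_qualitative(ctype)) {
    test <- if (ctype == "ordinal") "fisher_exact_ordinal"
            else "fisher_exact_nominal"
    return(list(test = test, log_transform = FALSE, diagnostics = list()))
  }
  ok <- !is.na(values) & !is.na(groups)
  x <- values[ok]; g <- groups[ok]
  tg <- table(g)
  if (any(tg < 3)) stop("each group needs >= 3 individuals for ",
                        "quantitative tests")
  std_resid <- function(v) {
    s <- stats::ave(v, g, FUN = stats::sd)
    s[s == 0] <- 1
    (v - stats::ave(v, g)) / s
  }
  centred <- std_resid(x)
  sw <- tryCatch(stats::shapiro.test(centred),
                 error = function(e) list(statistic = NA, p.value = 0))
  diag <- list(shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value)
  normal <- sw$p.value >= alpha
  log_transform <- FALSE
  if (!normal && all(x > 0)) {
    lx <- log(x)
    cl <- std_resid(lx)
    swl <- tryCatch(stats::shapiro.test(cl),
                    error = function(e) list(statistic = NA, p.value = 0))
    diag$shapiro_log_W <- unname(swl$statistic)
    diag$shapiro_log_p <- swl$p.value
    if (swl$p.value >= alpha) {
      normal <- TRUE
      log_transform <- TRUE
      x <- lx
    }
  }
  if (normal) {
    bt <- stats::bartlett.test(x, factor(g))
    diag$bartlett_K2 <- unname(bt$statistic)
    diag$bartlett_p <- bt$p.value
    test <- if (bt$p.value >= alpha) "anova_tukey" else "welch_games_howell"
  } else {
    lv <- car::leveneTest(x, factor(g), center = stats::median)
    diag$levene_F <- lv[1, "F value"]
    diag$levene_p <- lv[1, "Pr(>F)"]
    test <- if (lv[1, "Pr(>F)"] >= alpha) "kruskal_wilcoxon"
            else "permutation_pairwise"
  }
  list(test = test, log_transform = log_transform, diagnostics = diag)
}

tukey_kramer_p <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  ns <- tapply(x, g, length)
  ms <- tapply(x, g, mean)
  mse <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) /
    (length(x) - k)
  prs <- utils::combn(levels(g), 2)
  p <- apply(prs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    if (se == 0) return(if (ms[pr[1]] == ms[pr[2]]) 1 else 0)
    q <- abs(ms[pr[1]] - ms[pr[2]]) / se
    stats::ptukey(q, k, length(x) - k, lower.tail = FALSE)
  })
  data.frame(group1 = prs[1, ], group2 = prs[2, ], p = p,
             stringsAsFactors = FALSE)
}

games_howell_p <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  ns <- tapply(x, g, length)
  ms <- tapply(x, g, mean)
  vs <- tapply(x, g, stats::var)
  prs <- utils::combn(levels(g), 2)
  p <- apply(prs, 2, function(pr) {
    v1 <- vs[pr[1]] / ns[pr[1]]; v2 <- vs[pr[2]] / ns[pr[2]]
    se <- sqrt(v1 + v2)
    if (se == 0) return(if (ms[pr[1]] == ms[pr[2]]) 1 else 0)
    t <- abs(ms[pr[1]] - ms[pr[2]]) / se
    df <- (v1 + v2)^2 / (v1^2 / (ns[pr[1]] - 1) + v2^2 / (ns[pr[2]] - 1))
    stats::ptukey(t * sqrt(2), k, df, lower.tail = FALSE)
  })
  data.frame(group1 = prs[1, ], group2 = prs[2, ], p = p,
             stringsAsFactors = FALSE)
}

perm_mean_diff_p <- function(x1, x2, B, seed) {
  obs <- abs(mean(x1) - mean(x2))
  xx <- c(x1, x2); n1 <- length(x1)
  with_seed(seed, {
    cnt <- sum(vapply(seq_len(B), function(b) {
      idx <- sample(length(xx), n1)
      abs(mean(xx[idx]) - mean(xx[-idx])) >= obs - 1e-12
    }, logical(1)))
    (1 + cnt) / (1 + B)
  })
}

linear_by_linear_p <- function(v1, v2, lv, B, seed) {
  # ordinal association between group membership and level scores,
  # permutation null of the linear-by-linear statistic
  sc <- c(match(v1, lv), match(v2, lv))
  gr <- rep(0:1, c(length(v1), length(v2)))
  obs <- abs(sum(sc * gr) - sum(gr) * mean(sc))
  with_seed(seed, {
    cnt <- sum(vapply(seq_len(B), function(b) {
      gp <- sample(gr)
      abs(sum(sc * gp) - sum(gp) * mean(sc)) >= obs - 1e-12
    }, logical(1)))
    (1 + cnt) / (1 + B)
  })
}

#' Pairwise per-character tests across populations or groups
#'
#' Runs [select_test()] per character, performs all pairwise comparisons with
#' the selected procedure, and Holm-adjusts the p-values within each
#' character's pairwise family (alpha = 0.01 convention downstream).
#'
#' @param ds a `morpho_dataset`.
#' @param hyp optional [grouping_hypothesis]; when `NULL`, populations are
#'   compared.
#' @param perm_B resamples for the permutation branches (default 10000 for
#'   the mean-difference test; the ordinal permutation test uses
#'   `min(perm_B, 2000)`).
#' @param seed integer seed for the permutation branches.
#' @param alpha diagnostic alpha for test selection (default 0.01).
#' @return List of `character_test_result` objects: each has `character`,
#'   `test_used`, `log_transform`, `diagnostics`, and `pairs` (data.frame
#'   with `group1`, `group2`, `p_raw`, `p_adj`).
#' @export
pairwise_character_tests <- function(ds, hyp = NULL, perm_B = 10000,
                                     seed = 1, alpha = 0.01) {
  validate_morpho_dataset(ds)
  g <- if (is.null(hyp)) ds$populations else group_labels(ds, hyp)
  gl <- sort(unique(g))
  prs <- utils::combn(gl, 2)
  out <- vector("list", nrow(ds$descriptors))
  for (j in seq_len(nrow(ds$descriptors))) {
    ch <- ds$descriptors$name[j]
    ct <- ds$descriptors$ctype[j]
    lv <- ds$descriptors$levels[[j]]
    v <- ds$values[[j]]
    ok <- !is.na(v)
    cseed <- derive_seed(seed, 600L + j)

    zero_var <- if (is_qualitative(ct)) length(unique(v[ok])) < 2
                else isTRUE(stats::var(v[ok]) == 0) || sum(ok) == 0
    if (zero_var) {
      pairs <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                          p_raw = 1, p_adj = 1, stringsAsFactors = FALSE)
      out[[j]] <- structure(list(character = ch, test_used = "none",
                                 log_transform = FALSE,
                                 diagnostics = list(zero_variance = TRUE),
                                 pairs = pairs),
                            class = "character_test_result")
      next
    }

    sel <- select_test(v[ok], g[ok], ct, lv, alpha)
    x <- v[ok]; gg <- g[ok]
    if (sel$log_transform) x <- log(x)

    p_raw <- rep(NA_real_, ncol(prs))
    if (sel$test %in% c("anova_tukey", "welch_games_howell")) {
      tab <- if (sel$test == "anova_tukey") tukey_kramer_p(x, gg)
             else games_howell_p(x, gg)
      key <- paste(tab$group1, tab$group2)
      p_raw <- tab$p[match(paste(prs[1, ], prs[2, ]), key)]
    } else {
      for (c2 in seq_len(ncol(prs))) {
        a <- prs[1, c2]; b <- prs[2, c2]
        in_a <- gg == a; in_b <- gg == b
        if (!any(in_a) || !any(in_b)) next   # group entirely missing: skip
        p_raw[c2] <- switch(
          sel$test,
          kruskal_wilcoxon = suppressWarnings(
            stats::wilcox.test(x[in_a], x[in_b], exact = FALSE)$p.value),
          permutation_pairwise =
            perm_mean_diff_p(x[in_a], x[in_b], perm_B,
                             derive_seed(cseed, c2)),
          fisher_exact_nominal = {
            tb <- table(factor(x[in_a | in_b], levels = lv),
                        gg[in_a | in_b])
            tb <- tb[rowSums(tb) > 0, , drop = FALSE]
            if (nrow(tb) < 2) 1
            else stats::fisher.test(tb, simulate.p.value = nrow(tb) > 5,
                                    B = 10000)$p.value
          },
          fisher_exact_ordinal =
            linear_by_linear_p(x[in_a], x[in_b], lv,
                               min(perm_B, 2000), derive_seed(cseed, c2)))
      }
    }
    pairs <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                        p_raw = p_raw, stringsAsFactors = FALSE)
    pairs$p_adj <- NA_real_
    has <- !is.na(pairs$p_raw)
    pairs$p_adj[has] <- holm_adjust(pairs$p_raw[has])
    out[[j]] <- structure(list(character = ch, test_used = sel$test,
                               log_transform = sel$log_transform,
                               diagnostics = sel$diagnostics,
                               pairs = pairs),
                          class = "character_test_result")
  }
  out
}

#' Count matrix of significant pairwise differences
#'
#' Cell (a, b) counts the characters whose Holm-adjusted p-value for the
#' pair (a, b) is below `alpha` (default 0.01). The matrix is symmetric with
#' a zero diagonal and is the numeric content of the usual
#' pairwise-difference heatmap.
#'
#' @param results list returned by [pairwise_character_tests()].
#' @param alpha significance threshold.
#' @return Symmetric integer matrix with population/group codes as dimnames.
#' @export
difference_count_matrix <- function(results, alpha = 0.01) {
  all_pairs <- do.call(rbind, lapply(results, function(r)
    cbind(r$pairs, character = r$character)))
  codes <- sort(unique(c(all_pairs$group1, all_pairs$group2)))
  m <- matrix(0L, length(codes), length(codes),
              dimnames = list(codes, codes))
  sig <- all_pairs[!is.na(all_pairs$p_adj) & all_pairs$p_adj < alpha, ]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      a <- sig$group1[i]; b <- sig$group2[i]
      m[a, b] <- m[a, b] + 1L
      m[b, a] <- m[b, a] + 1L
    }
  }
  m
}

#' Export cascade results as a long-format table
#'
#' @param results list from [pairwise_character_tests()].
#' @return data.frame with columns `character`, `group1`, `group2`, `test`,
#'   `p_raw`, `p_adj`.
#' @export
cascade_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(character = r$character, group1 = r$pairs$group1,
               group2 = r$pairs$group2, test = r$test_used,
               p_raw = r$pairs$p_raw, p_adj = r$pairs$p_adj,
               stringsAsFactors = FALSE)
  }))
}
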