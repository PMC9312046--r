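#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of the null hypothesis of no difference
#' between groups on a dissimilarity matrix. All n(n-1)/2 dissimilarities
#' are ranked (mid-ranks for ties) and
#' \deqn{R = \frac{\bar r_B - \bar r_W}{M/2}, \quad M = n(n-1)/2,}
#' the difference between the mean between-group and mean within-group rank
#' scaled so that R is in \[-1, 1\]. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{R^* \ge R\})/(1 + n_{perm})} over random relabellings,
#' so it is never exactly zero.
#'
#' @param D a `dissimilarity_matrix`.
#' @param hyp a [grouping_hypothesis] mapping population codes to groups, or
#'   a plain vector of group labels (one per individual).
#' @param populations population codes per individual (required when `hyp`
#'   is a hypothesis and `D` has no attached dataset).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return List of class `anosim_result`: `R`, `p`, `n_perm`, `seed`,
#'   `perm_R` (the null statistics).
#' @export
anosim <- function(D, hyp, populations = NULL, n_perm = 999, seed = 1) {
  if (!inherits(D, "dissimilarity_matrix")) D <- dissimilarity_matrix(D)
  g <- resolve_groups(hyp, populations, D$labels)
  if (n_perm < 99) stop("n_perm must be >= 99")
  tg <- table(g)
  if (length(tg) < 2) stop("need >= 2 groups")
  if (any(tg < 2)) stop("every group needs >= 2 members (offending: ",
                        paste(names(tg)[tg < 2], collapse = ", "), ")")
  n <- nrow(D$d)
  iu <- which(upper.tri(D$d))
  rk <- rank(D$d[iu])              # mid-ranks
  M <- length(iu)
  row_i <- row(D$d)[iu]; col_j <- col(D$d)[iu]
  stat <- function(gl) {
    w <- gl[row_i] == gl[col_j]
    (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  }
  Robs <- stat(g)
  perm_R <- with_seed(derive_seed(seed, 510L),
                      vapply(seq_len(n_perm),
                             function(i) stat(sample(g)), numeric(1)))
  structure(list(R = Robs,
                 p = (1 + sum(perm_R >= Robs)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, perm_R = perm_R),
            class = "anosim_result")
}

resolve_groups <- function(hyp, populations, labels) {
  if (inherits(hyp, "grouping_hypothesis")) {
    if (is.null(populations))
      stop("populations required to apply a grouping hypothesis")
    group_labels(populations, hyp)
  } else {
    g <- as.character(hyp)
    if (length(g) != length(labels))
      stop("group labels must match the number of individuals")
    g
  }
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", round(x$R, 4), " p =", signif(x$p, 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

# Linear discriminant fit on a numeric matrix: pooled within-group
# covariance, proportional priors, ridge regularization when singular.
lda_fit <- function(X, g, ridge_tol = 1e-8) {
  cls <- unique(g)
  k <- length(cls)
  n <- nrow(X); p <- ncol(X)
  means <- do.call(rbind, lapply(cls, function(c0)
    colMeans(X[g == c0, , drop = FALSE])))
  S <- matrix(0, p, p)
  for (c0 in cls) {
    Xc <- X[g == c0, , drop = FALSE]
    if (nrow(Xc) > 1)
      S <- S + crossprod(sweep(Xc, 2, colMeans(Xc))) # (n_g-1) * cov
  }
  S <- S / (n - k)
  regularized <- FALSE
  A <- tryCatch(solve(S, t(means)), error = function(e) NULL)
  if (is.null(A) || !all(is.finite(A)) || rcond(S) < 1e-12) {
    lam <- ridge_tol * mean(diag(S))
    if (!isTRUE(lam > 0)) lam <- ridge_tol
    S <- S + diag(lam, p)
    A <- solve(S, t(means))
    regularized <- TRUE
  }
  prior <- as.numeric(table(factor(g, levels = cls))) / n
  const <- -0.5 * colSums(t(means) * A) + log(prior)
  list(classes = cls, A = A, const = const, regularized = regularized)
}

lda_predict <- function(fit, X) {
  sc <- X %*% fit$A + matrix(fit$const, nrow(X), length(fit$const),
                             byrow = TRUE)
  fit$classes[max.col(sc, ties.method = "first")]
}

#' Jackknifed (leave-one-out) linear discriminant classification
#'
#' For each individual, a linear discriminant model (pooled within-group
#' covariance, priors proportional to training-fold class frequencies) is
#' fitted on the remaining n-1 individuals and used to classify the held-out
#' one. Columns constant in a training fold are dropped for that fold; a
#' singular pooled covariance triggers ridge regularization
#' (lambda = 1e-8 x mean diagonal), flagged in the report.
#'
#' @param X numeric matrix (individuals x variables), e.g. the `x` component
#'   of [encode_qualitative()].
#' @param groups group label per individual (or a [grouping_hypothesis]
#'   plus `populations`).
#' @param populations population codes, needed when `groups` is a
#'   hypothesis.
#' @return Object of class `classification_report`: `confusion`
#'   ([confusion_matrix]), `percent_correct`, `kappa`,
#'   `per_class_sensitivity` (100 x diagonal / row total),
#'   `regularized`, `dropped_any`, `selected_variables` (NULL here).
#' @export
jackknife_lda <- function(X, groups, populations = NULL) {
  X <- as.matrix(X)
  g <- resolve_groups(groups, populations, rownames(X) %||% seq_len(nrow(X)))
  cls <- sort(unique(g))
  n <- nrow(X)
  if (n <= length(cls)) stop("need more individuals than groups")
  pred <- character(n)
  regularized <- FALSE; dropped <- FALSE
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; gtr <- g[-i]
    keep <- apply(Xtr, 2, function(v) stats::var(v) > 0)
    if (!all(keep)) dropped <- TRUE
    if (!any(keep)) { pred[i] <- names(which.max(table(gtr))); next }
    fit <- lda_fit(Xtr[, keep, drop = FALSE], gtr)
    regularized <- regularized || fit$regularized
    pred[i] <- lda_predict(fit, X[i, keep, drop = FALSE])
  }
  if (dropped)
    warning("constant column(s) dropped within at least one training fold")
  if (regularized)
    warning("singular pooled covariance; ridge regularization applied")
  cm <- table(factor(g, levels = cls), factor(pred, levels = cls))
  cm <- confusion_matrix(unclass(matrix(cm, length(cls), length(cls),
                                        dimnames = list(cls, cls))))
  classification_report(cm, regularized = regularized,
                        dropped_any = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

classification_report <- function(cm, selected_variables = NULL,
                                  regularized = FALSE, dropped_any = FALSE) {
  structure(list(confusion = cm,
                 percent_correct = percent_correct(cm),
                 kappa = kappa_statistic(cm),
                 per_class_sensitivity = 100 * diag(cm) /
                   pmax(rowSums(cm), 1),
                 selected_variables = selected_variables,
                 regularized = regularized,
                 dropped_any = dropped_any),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Leave-one-out classification:",
      sprintf("%.1f%% correct, kappa = %.4f\n",
              x$percent_correct, x$kappa))
  print(unclass(x$confusion))
  if (!is.null(x$selected_variables))
    cat("selected variables:", paste(x$selected_variables, collapse = ", "),
        "\n")
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' \eqn{K = (p_o - p_e)/(1 - p_e)} with observed agreement
#' \eqn{p_o = trace/N} and chance agreement
#' \eqn{p_e = \sum_g row_g \cdot col_g / N^2}. Returns `NA` when
#' \eqn{p_e = 1} (degenerate single-cell matrix), where kappa is undefined.
#'
#' @param cm a [confusion_matrix] (or square count matrix).
#' @return Kappa in \[-1, 1\], or `NA` if undefined.
#' @export
kappa_statistic <- function(cm) {
  cm <- as.matrix(cm)
  N <- sum(cm)
  if (N <= 0) stop("confusion matrix grand total must be positive")
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Percent correct classification
#'
#' @param cm a [confusion_matrix].
#' @return 100 x trace / grand total.
#' @export
percent_correct <- function(cm) {
  cm <- as.matrix(cm)
  N <- sum(cm)
  if (N <= 0) stop("confusion matrix grand total must be positive")
  100 * sum(diag(cm)) / N
}

# Wilks' lambda of a variable subset: det(W)/det(T) of within- and
# total-group cross-product matrices.
wilks_lambda <- function(X, g, vars) {
  Xs <- X[, vars, drop = FALSE]
  Tm <- crossprod(sweep(Xs, 2, colMeans(Xs)))
  W <- matrix(0, length(vars), length(vars))
  for (c0 in unique(g)) {
    Xc <- Xs[g == c0, , drop = FALSE]
    W <- W + crossprod(sweep(Xc, 2, colMeans(Xc)))
  }
  dT <- det(Tm)
  if (dT <= 0) return(1)
  max(det(W) / dT, .Machine$double.xmin)
}

#' Stepwise linear discriminant analysis (Wilks' lambda criterion)
#'
#' Forward-backward selection: at each step the candidate variable whose
#' entry most reduces Wilks' lambda is added if its partial F statistic
#' \deqn{F = \frac{\Lambda_p/\Lambda_{p+1} - 1}{(g-1)/(n-g-p)}}
#' reaches `f_enter`; variables already in the model whose removal partial F
#' falls below `f_remove` are dropped. The final variable set is evaluated
#' by leave-one-out classification as in [jackknife_lda()]. Defaults are the
#' common F-to-enter 3.84 / F-to-remove 2.71 thresholds.
#'
#' @param X numeric matrix (individuals x variables).
#' @param groups group labels (or hypothesis + `populations`).
#' @param populations population codes if `groups` is a hypothesis.
#' @param f_enter,f_remove partial-F thresholds (`f_enter > f_remove`).
#' @param max_steps safety bound on selection iterations.
#' @return A `classification_report` whose `selected_variables` names the
#'   final model (possibly empty: chance-level report).
#' @export
stepwise_lda <- function(X, groups, populations = NULL,
                         f_enter = 3.84, f_remove = 2.71, max_steps = 100) {
  if (f_enter <= f_remove) stop("f_enter must exceed f_remove")
  X <- as.matrix(X)
  g <- resolve_groups(groups, populations, rownames(X) %||% seq_len(nrow(X)))
  vn <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- vn
  k <- length(unique(g)); n <- nrow(X)
  usable <- vn[apply(X, 2, function(v) stats::var(v) > 0)]
  sel <- character(0)
  partial_f <- function(lam_small, lam_big, p_in) {
    # lam_small: model without the variable, lam_big: with it
    (lam_small / lam_big - 1) * (n - k - p_in) / (k - 1)
  }
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    cand <- setdiff(usable, sel)
    if (length(cand) && n - k - length(sel) > 0) {
      lam0 <- if (length(sel)) wilks_lambda(X, g, sel) else 1
      fs <- vapply(cand, function(v) {
        lam1 <- wilks_lambda(X, g, c(sel, v))
        partial_f(lam0, lam1, length(sel))
      }, numeric(1))
      if (max(fs) >= f_enter) {
        sel <- c(sel, cand[which.max(fs)])
        changed <- TRUE
      }
    }
    if (length(sel) > 1) {
      lam_full <- wilks_lambda(X, g, sel)
      fr <- vapply(sel, function(v) {
        lam0 <- wilks_lambda(X, g, setdiff(sel, v))
        partial_f(lam0, lam_full, length(sel) - 1)
      }, numeric(1))
      if (min(fr) < f_remove) {
        sel <- setdiff(sel, sel[which.min(fr)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(sel)) {
    cls <- sort(unique(g))
    maj <- names(which.max(table(g)))
    cm <- table(factor(g, levels = cls),
                factor(rep(maj, n), levels = cls))
    cm <- confusion_matrix(unclass(matrix(cm, k, k,
                                          dimnames = list(cls, cls))))
    return(classification_report(cm, selected_variables = character(0)))
  }
  rep <- jackknife_lda(X[, sel, drop = FALSE], g)
  rep$selected_variables <- sel
  rep
}

#' Write a confusion matrix as labelled CSV with margins
#'
#' Layout: rows = a-priori groups, columns = predicted groups, with `Total`
#' margins, as conventional for published jackknife tables.
#'
#' @param cm a [confusion_matrix].
#' @param path output CSV path.
#' @export
write_confusion <- function(cm, path) {
  m <- as.matrix(cm)
  out <- rbind(cbind(m, Total = rowSums(m)),
               Total = c(colSums(m), sum(m)))
  utils::write.csv(out, path, row.names = TRUE)
  invisible(path)
}
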