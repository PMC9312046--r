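#' Gower dissimilarity with Podani's ordinal correction
#'
#' Mixed-variable dissimilarity between individuals:
#' \deqn{d_{ij} = \frac{\sum_k w_k \delta_{ijk} s_{ijk}}{\sum_k w_k \delta_{ijk}}}
#' where the partial dissimilarity \eqn{s_{ijk}} is \eqn{|x_{ik}-x_{jk}|/range_k}
#' for quantitative characters, 0/1 match/mismatch for binary and nominal
#' characters (all states informative, symmetric treatment), and for ordinal
#' characters Podani's (1999) tie-corrected rank formula
#' \deqn{s_{ijk} = \frac{|r_{ik}-r_{jk}| - (T_{ik}-1)/2 - (T_{jk}-1)/2}
#'   {r_{k,max}-r_{k,min} - (T_{k,max}-1)/2 - (T_{k,min}-1)/2}}
#' with global mid-ranks \eqn{r} and tie counts \eqn{T}, clipped to [0,1].
#' \eqn{\delta_{ijk} = 0} (character ignored for the pair) when either value
#' is missing, or for a quantitative character with zero range; binary and
#' nominal characters remain comparable when only one state is observed
#' (match, partial dissimilarity 0), as does an all-tied ordinal character.
#'
#' @param ds a [morpho_dataset].
#' @param weights optional non-negative per-character weights (default equal).
#' @return Object of class `dissimilarity_matrix`: list with `labels`,
#'   symmetric matrix `d` with zero diagonal, `is_euclidean` (tri-state:
#'   `TRUE`/`FALSE`/`NA` until checked), `min_eigenvalue`, `provenance`.
#' @export
gower_podani <- function(ds, weights = NULL) {
  validate_morpho_dataset(ds)
  n <- length(ds$individuals)
  if (n < 2) stop("need >= 2 individuals")
  p <- nrow(ds$descriptors)
  if (p < 1) stop("need >= 1 character")
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p || any(weights < 0))
    stop("weights must be non-negative, one per character")

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (k in seq_len(p)) {
    ct <- ds$descriptors$ctype[k]
    w <- weights[k]
    if (w == 0) next
    v <- ds$values[[k]]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning("character '", ds$descriptors$name[k],
              "' is entirely missing; excluded")
      next
    }
    dl <- outer(ok, ok, "&")
    if (is_qualitative(ct) && ct != "ordinal") {
      code <- match(v, ds$descriptors$levels[[k]])
      s <- outer(code, code, "!=") * 1
      s[is.na(s)] <- 0
    } else if (ct == "ordinal") {
      code <- match(v, ds$descriptors$levels[[k]])
      r <- rank(code, na.last = "keep")          # global mid-ranks
      tie <- table(code)
      Tc <- as.numeric(tie[as.character(code)])  # tie count per object
      obs <- code[ok]
      rmax <- max(r, na.rm = TRUE); rmin <- min(r, na.rm = TRUE)
      Tmax <- sum(obs == max(obs)); Tmin <- sum(obs == min(obs))
      denom <- (rmax - rmin) - (Tmax - 1) / 2 - (Tmin - 1) / 2
      if (!isTRUE(denom > 0)) {
        s <- matrix(0, n, n)                     # all tied: everything matches
      } else {
        s <- (abs(outer(r, r, "-")) -
                outer((Tc - 1) / 2, (Tc - 1) / 2, "+")) / denom
        s <- pmin(pmax(s, 0), 1)
        s[is.na(s)] <- 0
      }
    } else {
      rg <- diff(range(v[ok]))
      if (rg == 0) next
      s <- abs(outer(v, v, "-")) / rg
      s[is.na(s)] <- 0
    }
    s[!dl] <- 0
    num <- num + w * dl * s
    den <- den + w * dl
  }
  if (any(den[upper.tri(den)] == 0)) {
    idx <- which(upper.tri(den) & den == 0, arr.ind = TRUE)[1, ]
    stop("no comparable characters for pair ('", ds$individuals[idx[1]],
         "', '", ds$individuals[idx[2]], "')")
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(ds$individuals, ds$individuals)
  dissimilarity_matrix(d, provenance = "gower+podani")
}

#' Dissimilarity matrix constructor
#'
#' @param d symmetric non-negative matrix with zero diagonal.
#' @param labels optional identifiers (default: dimnames of `d`).
#' @param provenance free-text method tag.
#' @return Object of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(d, labels = NULL, provenance = "") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d, is_euclidean = NA,
                 min_eigenvalue = NA_real_, provenance = provenance),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("dissimilarity_matrix:", nrow(x$d), "x", ncol(x$d),
      "(", x$provenance, ")\n")
  cat("  euclidean:", x$is_euclidean, " min eigenvalue:",
      signif(x$min_eigenvalue, 4), "\n")
  invisible(x)
}

gower_centre <- function(d2) {
  # double-centring J (-1/2 D^2) J
  n <- nrow(d2)
  a <- -0.5 * d2
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

#' Test whether a dissimilarity matrix is Euclidean-embeddable
#'
#' A matrix is Euclidean iff the double-centred \eqn{-\frac12 D \circ D}
#' matrix is positive semi-definite. The tolerance is relative:
#' `min eigenvalue >= -tol * max eigenvalue` with `tol = 1e-8`, absorbing
#' double-precision eigensolver noise.
#'
#' @param D a `dissimilarity_matrix` (or plain symmetric matrix).
#' @param tol relative eigenvalue tolerance.
#' @return The matrix with `is_euclidean` and `min_eigenvalue` filled in.
#' @export
euclidean_check <- function(D, tol = 1e-8) {
  if (!inherits(D, "dissimilarity_matrix")) D <- dissimilarity_matrix(D)
  B <- gower_centre(D$d^2)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  D$min_eigenvalue <- min(ev)
  D$is_euclidean <- min(ev) >= -tol * max(max(ev), .Machine$double.eps)
  D
}

#' Cailliez correction
#'
#' Adds the smallest constant `c >= 0` to every off-diagonal dissimilarity
#' that makes the matrix Euclidean-embeddable. Following Cailliez (1983),
#' `c` is the largest real eigenvalue of the 2n x 2n companion matrix
#' built from the double-centred matrices of `D` and of `D^2`; the diagonal
#' stays zero.
#'
#' @param D a `dissimilarity_matrix`.
#' @return List with `D` (corrected `dissimilarity_matrix`, flagged
#'   Euclidean) and the constant `c` (0 when the input is already Euclidean).
#' @export
cailliez_correction <- function(D) {
  if (!inherits(D, "dissimilarity_matrix")) D <- dissimilarity_matrix(D)
  D <- euclidean_check(D)
  if (isTRUE(D$is_euclidean)) {
    D$provenance <- paste0(D$provenance, "+cailliez(c=0)")
    return(list(D = D, c = 0))
  }
  n <- nrow(D$d)
  d1 <- gower_centre(D$d^2)   # centred -1/2 D^2
  d2 <- gower_centre(D$d)     # centred -1/2 D
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  cc <- max(cc, 0)
  d <- D$d + cc
  diag(d) <- 0
  out <- dissimilarity_matrix(d, D$labels,
                              paste0(D$provenance, "+cailliez(c=",
                                     signif(cc, 6), ")"))
  out <- euclidean_check(out)
  list(D = out, c = cc)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres \eqn{-\frac12 D \circ D}, eigendecomposes, and returns
#' axis scores (eigenvectors scaled by the square roots of the eigenvalues).
#' Non-Euclidean input triggers a warning; axes are restricted to positive
#' eigenvalues. Axis signs are arbitrary.
#'
#' @param D a `dissimilarity_matrix`.
#' @param m number of axes to keep (truncated to the positive-eigenvalue
#'   count, with a warning).
#' @return Object of class `pcoa_result`: `coordinates` (n x m),
#'   `eigenvalues` (all, descending), `relative_eigenvalues` (positive
#'   eigenvalues / their sum).
#' @export
pcoa <- function(D, m = 2) {
  if (!inherits(D, "dissimilarity_matrix")) D <- dissimilarity_matrix(D)
  B <- gower_centre(D$d^2)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- 1e-8 * max(abs(ev))
  if (min(ev) < -tol)
    warning("dissimilarity matrix is not Euclidean; negative eigenvalues ",
            "reported, axes restricted to positive ones")
  npos <- sum(ev > tol)
  if (m > npos) {
    warning("only ", npos, " positive axes available; m truncated")
    m <- npos
  }
  keep <- seq_len(m)
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), nrow = m)
  rownames(coords) <- D$labels
  colnames(coords) <- paste0("Axis", keep)
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 relative_eigenvalues = ev[ev > tol] / sum(ev[ev > tol])),
            class = "pcoa_result")
}

#' Sampling adequacy: Kaiser-Meyer-Olkin MSA and Bartlett's sphericity test
#'
#' Both operate on the correlation matrix of the quantitative characters.
#' KMO overall MSA is \eqn{\sum r^2 / (\sum r^2 + \sum q^2)} over
#' off-diagonal correlations \eqn{r} and anti-image partial correlations
#' \eqn{q} (from the scaled inverse correlation matrix). Bartlett's
#' statistic is \eqn{\chi^2 = -(n-1-(2p+5)/6)\,\ln\det R} on
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param ds a `morpho_dataset` with >= 3 quantitative characters (rows with
#'   missing quantitative values are dropped).
#' @return List with `kmo_msa`, `bartlett_chisq`, `bartlett_df`,
#'   `bartlett_p`, `n`, `p`, and `pseudo_inverse` flag (TRUE when the
#'   correlation matrix was singular and partials used the pseudo-inverse).
#' @export
sampling_adequacy <- function(ds) {
  validate_morpho_dataset(ds)
  qn <- ds$descriptors$name[is_quantitative(ds$descriptors$ctype)]
  if (length(qn) < 3) stop("need >= 3 quantitative characters")
  X <- as.matrix(ds$values[, qn, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (p < 3) stop("fewer than 3 non-constant quantitative characters")
  R <- stats::cor(X)

  flag <- FALSE
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Ri) || !all(is.finite(Ri))) {
    flag <- TRUE
    e <- eigen(R, symmetric = TRUE)
    pos <- e$values > 1e-10 * max(e$values)
    Ri <- e$vectors[, pos, drop = FALSE] %*%
      diag(1 / e$values[pos], nrow = sum(pos)) %*%
      t(e$vectors[, pos, drop = FALSE])
    warning("singular correlation matrix; partial correlations from ",
            "pseudo-inverse")
  }
  s <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(s, s)          # anti-image partial correlations
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))

  detR <- det(R)
  chisq <- if (detR > 0) -(n - 1 - (2 * p + 5) / 6) * log(detR) else Inf
  df <- p * (p - 1) / 2
  list(kmo_msa = kmo,
       bartlett_chisq = chisq,
       bartlett_df = df,
       bartlett_p = stats::pchisq(chisq, df, lower.tail = FALSE),
       n = n, p = p, pseudo_inverse = flag)
}

#' Write / read a dissimilarity matrix as square CSV
#'
#' @param D a `dissimilarity_matrix`.
#' @param path CSV path (header row and first column are individual IDs).
#' @return `read_dissimilarity` returns a `dissimilarity_matrix`.
#' @export
write_dissimilarity <- function(D, path) {
  utils::write.csv(as.data.frame(D$d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  m <- (m + t(m)) / 2   # absorb decimal-printing asymmetry
  dissimilarity_matrix(m, provenance = paste0("file:", basename(path)))
}
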