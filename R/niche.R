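# PCA-based environmental niche quantification: a PCA of the pooled
# background environment defines a two-dimensional environmental space, a
# kernel-smoothed occupancy grid describes each taxon's density in that
# space relative to the available environment, Schoener's D measures
# overlap, and a background-randomization test asks whether two niches are
# more similar than expected given where each taxon could occur.

env_at <- function(env, cells) {
  sapply(env, function(m) m[cbind(cells[, 2], cells[, 1])])
}

mask_cells <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' PCA of the pooled background environment
#'
#' Fits a centred, scaled PCA on the environmental values of all background
#' cells of both taxa pooled, then projects presences and backgrounds onto
#' the first two components. Constant environmental variables are dropped
#' with a warning.
#'
#' @param env list of environmental landscape matrices (same dimensions).
#' @param occ list of two presence coordinate matrices (columns x, y; cell
#'   coordinates).
#' @param background list of two logical background masks.
#' @return List: `rotation` (the fitted [stats::prcomp] object),
#'   `explained` (variance proportions), `presence_scores` (list of two
#'   n x 2 score matrices), `background_scores` (list of two matrices).
#' @export
env_pca <- function(env, occ, background) {
  if (length(env) < 2) stop("need >= 2 environmental variables")
  bg_cells <- lapply(background, mask_cells)
  pooled <- rbind(env_at(env, bg_cells[[1]]), env_at(env, bg_cells[[2]]))
  keep <- apply(pooled, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("constant environmental variable(s) dropped")
    if (sum(keep) < 2) stop("fewer than 2 informative variables")
  }
  pooled <- pooled[, keep, drop = FALSE]
  fit <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  proj <- function(cells) {
    stats::predict(fit, env_at(env, cells)[, keep, drop = FALSE])[, 1:2,
                                                                  drop = FALSE]
  }
  list(rotation = fit,
       explained = fit$sdev^2 / sum(fit$sdev^2),
       presence_scores = lapply(occ, proj),
       background_scores = lapply(bg_cells, proj))
}

gauss_kde_grid <- function(pts, gx, gy, h) {
  # Gaussian product-kernel density evaluated on the grid defined by gx, gy
  dx <- outer(gx, pts[, 1], function(a, b) stats::dnorm(a - b, sd = h[1]))
  dy <- outer(gy, pts[, 2], function(a, b) stats::dnorm(a - b, sd = h[2]))
  (dx %*% t(dy)) / nrow(pts)   # [x, y]
}

silverman_bw <- function(v) {
  # Silverman's rule per axis, with the two-dimensional exponent n^(-1/6)
  # appropriate for a product Gaussian kernel on a planar score space;
  # robust scale = min(sd, IQR/1.34)
  n <- length(v)
  s <- min(stats::sd(v), stats::IQR(v) / 1.34)
  if (s <= 0) s <- stats::sd(v)
  s * n^(-1 / 6)
}

#' Kernel-smoothed occupancy grid in environmental space
#'
#' Gaussian kernel densities of the presences (o) and of the background (e)
#' are evaluated on a common R x R grid spanning the pooled background score
#' range expanded by 5%; occupancy is z proportional to o/e where e > 0 (0
#' where the environment is unavailable), normalized to sum to one.
#' Bandwidths follow Silverman's rule per axis (two-dimensional exponent)
#' on the distinct presence scores, so duplicated records do not alter the
#' density.
#'
#' @param presence_scores n x 2 matrix of presence scores.
#' @param background_scores m x 2 matrix of background-cell scores.
#' @param R grid resolution per axis (default 100).
#' @param grid_range optional 2 x 2 matrix (rows = axis, cols = min/max) to
#'   force a common grid across taxa.
#' @param bandwidth optional numeric length-2 override.
#' @return Object of class `niche_grid`: `z` (R x R, sums to 1), `o` and `e`
#'   (presence and availability kernel densities), `gx`, `gy` axis break
#'   centres, `bandwidth`.
#' @export
occupancy_grid <- function(presence_scores, background_scores, R = 100,
                           grid_range = NULL, bandwidth = NULL) {
  pts <- as.matrix(presence_scores)
  if (nrow(pts) < 5) stop("need >= 5 presences")
  bg <- as.matrix(background_scores)
  if (is.null(grid_range)) {
    grid_range <- t(apply(bg, 2, range))
    pad <- 0.05 * (grid_range[, 2] - grid_range[, 1])
    grid_range[, 1] <- grid_range[, 1] - pad
    grid_range[, 2] <- grid_range[, 2] + pad
  }
  gx <- seq(grid_range[1, 1], grid_range[1, 2], length.out = R)
  gy <- seq(grid_range[2, 1], grid_range[2, 2], length.out = R)
  if (is.null(bandwidth)) {
    up <- unique(pts)
    bandwidth <- c(silverman_bw(up[, 1]), silverman_bw(up[, 2]))
  }
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
    stop("zero kernel bandwidth (presences concentrated in one cell)")
  o <- gauss_kde_grid(pts, gx, gy, bandwidth)
  ub <- unique(bg)
  e <- gauss_kde_grid(bg, gx, gy, c(silverman_bw(ub[, 1]),
                                    silverman_bw(ub[, 2])))
  ethr <- max(e) * 1e-6
  z <- ifelse(e > ethr, o / pmax(e, ethr), 0)
  z <- z / sum(z)
  structure(list(z = z, o = o, e = e, gx = gx, gy = gy,
                 bandwidth = bandwidth),
            class = "niche_grid")
}

#' Schoener's D niche overlap
#'
#' \eqn{D = 1 - \frac12 \sum_{cells} |z_1 - z_2|}, ranging from 0 (no
#' overlap) to 1 (identical occupancy).
#'
#' @param z1,z2 `niche_grid` objects on the same axes (or plain matrices
#'   summing to 1).
#' @return D in \[0, 1\].
#' @export
schoener_d <- function(z1, z2) {
  m1 <- if (inherits(z1, "niche_grid")) z1$z else z1
  m2 <- if (inherits(z2, "niche_grid")) z2$z else z2
  if (!all(dim(m1) == dim(m2))) stop("mismatched grids")
  if (inherits(z1, "niche_grid") && inherits(z2, "niche_grid") &&
      (max(abs(z1$gx - z2$gx)) > 1e-9 || max(abs(z1$gy - z2$gy)) > 1e-9))
    stop("grids are not on the same axes")
  1 - 0.5 * sum(abs(m1 - m2))
}

#' Background-randomization niche similarity test
#'
#' Computes the observed Schoener's D between the two taxa in the shared
#' environmental space, then builds a null distribution by re-drawing one
#' taxon's presences (same number) uniformly at random from its background
#' cells and recomputing D. The one-sided p-value
#' \eqn{(1 + \#\{D^* \ge D\})/(1 + n_{reps})} asks whether the niches are
#' more similar than expected from the available background; both directions
#' (randomizing taxon 1, randomizing taxon 2) are reported.
#'
#' @param env list of environmental matrices.
#' @param occ list of two presence coordinate matrices.
#' @param background list of two background masks.
#' @param n_reps randomization replicates (>= 99).
#' @param R grid resolution.
#' @param seed integer seed.
#' @return Object of class `overlap_result`: `D`, `p_sim` (length-2:
#'   randomizing taxon 1, then taxon 2), `n_reps`, `seed`.
#' @export
similarity_test <- function(env, occ, background, n_reps = 99, R = 100,
                            seed = 1) {
  if (n_reps < 99) stop("n_reps must be >= 99")
  sc <- env_pca(env, occ, background)
  allbg <- rbind(sc$background_scores[[1]], sc$background_scores[[2]])
  rng <- t(apply(allbg, 2, range))
  pad <- 0.05 * (rng[, 2] - rng[, 1])
  rng[, 1] <- rng[, 1] - pad; rng[, 2] <- rng[, 2] + pad
  gridz <- function(p, b) occupancy_grid(p, b, R = R, grid_range = rng)
  z <- list(gridz(sc$presence_scores[[1]], sc$background_scores[[1]]),
            gridz(sc$presence_scores[[2]], sc$background_scores[[2]]))
  Dobs <- schoener_d(z[[1]], z[[2]])
  bg_cells <- lapply(background, mask_cells)
  p_sim <- numeric(2)
  for (t0 in 1:2) {
    nocc <- nrow(occ[[t0]])
    if (nrow(bg_cells[[t0]]) < nocc)
      stop("background smaller than presence count for taxon ", t0)
    Dnull <- with_seed(derive_seed(seed, 700L + t0), {
      vapply(seq_len(n_reps), function(r) {
        cells <- bg_cells[[t0]][sample(nrow(bg_cells[[t0]]), nocc,
                                       replace = TRUE), , drop = FALSE]
        stars <- stats::predict(sc$rotation,
                                env_at(env, cells))[, 1:2, drop = FALSE]
        zr <- gridz(stars, sc$background_scores[[t0]])
        schoener_d(zr, z[[3 - t0]])
      }, numeric(1))
    })
    p_sim[t0] <- (1 + sum(Dnull >= Dobs)) / (1 + n_reps)
  }
  structure(list(D = Dobs, p_sim = p_sim, n_reps = n_reps, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Niche overlap: Schoener's D = %.3f; similarity p = %.3f / %.3f (%d reps)\n",
              x$D, x$p_sim[1], x$p_sim[2], x$n_reps))
  invisible(x)
}

#' Write / read an environmental grid as a plain-text file
#'
#' Format: 4 header lines (`ncols`, `nrows`, `cellsize`, `origin`) followed
#' by `nrows` whitespace-separated rows.
#'
#' @param m landscape matrix.
#' @param path file path.
#' @param cellsize,origin grid metadata.
#' @export
write_env_grid <- function(m, path, cellsize = 1, origin = c(0, 0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("cellsize", cellsize),
               paste("origin", origin[1], origin[2])), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  hdr <- readLines(path, n = 4)
  ncols <- as.integer(strsplit(hdr[1], " +")[[1]][2])
  nrows <- as.integer(strsplit(hdr[2], " +")[[1]][2])
  m <- as.matrix(utils::read.table(path, skip = 4))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(nrows, ncols))) stop("grid dimensions disagree with header")
  m
}

#' Read occurrences from CSV (`taxon,x,y`)
#'
#' @param path CSV path.
#' @return Named list of coordinate matrices, one per taxon.
#' @export
read_occurrences <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "x", "y") %in% colnames(tab)))
    stop("occurrence file must have columns taxon,x,y")
  lapply(split(tab, tab$taxon), function(d) cbind(x = d$x, y = d$y))
}
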