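# Seed outline extraction and elliptic Fourier shape analysis.
#
# Pixel convention: 0-based coordinates, origin top-left, x = column,
# y = row; polygon vertices at pixel centres. Outlines are simple closed
# polygons stored counterclockwise (positive shoelace area), first vertex
# not repeated.

to_gray <- function(image) {
  if (length(dim(image)) == 3) (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  else image
}

moore_trace <- function(mask) {
  # Moore-neighbour boundary tracing of the TRUE region in a logical matrix.
  nr <- nrow(mask); nc <- ncol(mask)
  start <- which(t(mask))[1]          # row-major scan: topmost, then leftmost
  if (is.na(start)) return(NULL)
  sr <- (start - 1) %/% nc + 1; sc <- (start - 1) %% nc + 1
  # clockwise Moore neighbourhood starting west
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  path <- matrix(NA_integer_, nrow = 4 * sum(mask) + 8, ncol = 2)
  path[1, ] <- c(sr, sc)
  np <- 1
  pr <- sr; pc <- sc
  bdir <- 1L  # entered from the west (scan direction)
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- ((bdir - 1 + s) %% 8) + 1
      r2 <- pr + dr[k]; c2 <- pc + dc[k]
      if (inside(r2, c2)) {
        if (np == 1) first_move <- k
        np <- np + 1
        path[np, ] <- c(r2, c2)
        # new backtrack: direction pointing to the previously examined
        # (background) neighbour, relative to the new pixel
        prevk <- ((k - 2) %% 8) + 1
        back_r <- pr + dr[prevk]; back_c <- pc + dc[prevk]
        pr <- r2; pc <- c2
        bdir <- which(dr == back_r - pr & dc == back_c - pc)
        found <- TRUE
        break
      }
    }
    if (!found) break                      # isolated pixel
    if (pr == sr && pc == sc) {
      # Jacob's stopping criterion: re-entered start with the same move
      nx <- ((bdir - 1 + 0:7) %% 8) + 1
      nxt <- nx[vapply(nx, function(k)
        inside(pr + dr[k], pc + dc[k]), logical(1))][1]
      if (is.na(nxt) || nxt == first_move) break
    }
    if (np >= nrow(path) - 1) break        # safety
  }
  path <- path[seq_len(np), , drop = FALSE]
  if (np > 1 && all(path[np, ] == path[1, ])) path <- path[-np, , drop = FALSE]
  cbind(x = path[, 2] - 1, y = path[, 1] - 1)
}

signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Trace seed outlines in an image
#'
#' Global thresholding (Otsu by default; seeds darker than the background),
#' connected-component labelling, and Moore boundary tracing of each
#' component. Components below `min_area` pixels or touching the image
#' border are excluded.
#'
#' @param image numeric matrix (grayscale, 0..1) or H x W x 3 RGB array.
#' @param threshold grey threshold in (0,1); `NULL` uses Otsu's method.
#' @param min_area minimum component area, pixels.
#' @param pixel_size physical size of one pixel (mm); default corresponds to
#'   1200-dpi scans (25.4/1200 mm).
#' @return List of outlines of class `seed_outline`: counterclockwise
#'   two-column matrices of pixel-centre coordinates with attributes
#'   `pixel_size` and `area_px` (component pixel count). Empty list (with a
#'   warning) when nothing is found.
#' @export
trace_outline <- function(image, threshold = NULL, min_area = 50,
                          pixel_size = 25.4 / 1200) {
  g <- to_gray(image)
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  mask <- g < threshold
  if (!any(mask)) {
    warning("no foreground components found")
    return(list())
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(g), ncol(g))
  out <- list()
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    npx <- sum(comp)
    if (npx < min_area) next
    rws <- range(which(rowSums(comp) > 0))
    cls <- range(which(colSums(comp) > 0))
    if (rws[1] == 1 || rws[2] == nrow(g) || cls[1] == 1 ||
        cls[2] == ncol(g)) {
      message("component ", id, " touches the image border; excluded")
      next
    }
    b <- moore_trace(comp)
    if (is.null(b) || nrow(b) < 8) next
    if (signed_area(b) < 0) b <- b[rev(seq_len(nrow(b))), ]
    attr(b, "pixel_size") <- pixel_size
    attr(b, "area_px") <- npx
    class(b) <- c("seed_outline", class(b))
    out[[length(out) + 1]] <- b
  }
  if (!length(out)) warning("no usable components after filtering")
  out
}

efd_raw <- function(xy, N) {
  x <- xy[, 1]; y <- xy[, 2]
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (!length(dt)) stop("degenerate (zero-length) outline")
  t <- cumsum(dt); T <- t[length(t)]
  t0 <- c(0, t[-length(t)])
  co <- matrix(0, N, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(N)) {
    w <- 2 * pi * n / T
    f <- T / (2 * n^2 * pi^2)
    cs <- cos(w * t) - cos(w * t0)
    sn <- sin(w * t) - sin(w * t0)
    co[n, "a"] <- f * sum(dx / dt * cs)
    co[n, "b"] <- f * sum(dx / dt * sn)
    co[n, "c"] <- f * sum(dy / dt * cs)
    co[n, "d"] <- f * sum(dy / dt * sn)
  }
  # position terms (centroid of the parametrized curve)
  xi <- cumsum(dx) - dx / 2
  a0 <- 2 / T * sum(dt * (xi + x[1]))
  yi <- cumsum(dy) - dy / 2
  c0 <- 2 / T * sum(dt * (yi + y[1]))
  list(coef = co, a0 = a0 / 2, c0 = c0 / 2, T = T)
}

rotate_start <- function(co, theta) {
  out <- co
  for (n in seq_len(nrow(co))) {
    R <- matrix(c(cos(n * theta), sin(n * theta),
                  -sin(n * theta), cos(n * theta)), 2, 2)
    m <- matrix(co[n, ], 2, 2, byrow = TRUE) %*% R
    out[n, ] <- c(m[1, ], m[2, ])
  }
  out
}

rotate_space <- function(co, psi) {
  R <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2)
  out <- co
  for (n in seq_len(nrow(co))) {
    m <- R %*% matrix(co[n, ], 2, 2, byrow = TRUE)
    out[n, ] <- c(m[1, ], m[2, ])
  }
  out
}

normalize_one <- function(co, theta) {
  co1 <- rotate_start(co, theta)
  psi <- atan2(co1[1, "c"], co1[1, "a"])
  co2 <- rotate_space(co1, psi)
  if (co2[1, "a"] < 0) co2 <- rotate_space(co2, pi)
  co2
}

#' Elliptic Fourier descriptors of a closed outline
#'
#' Kuhl-Giardina chain integrals over the closed polygon give four
#' coefficients (a, b, c, d) per harmonic. With `normalize = TRUE` the set
#' is standardized for start point (rotation of the parameter so t = 0 sits
#' on the first-harmonic major axis), orientation (spatial rotation aligning
#' that axis with x, so the first harmonic satisfies a1 > 0, b1 = c1 = 0)
#' and size (division by the first-harmonic major semi-axis, so a1 = 1).
#' The residual half-turn ambiguity of the start point is resolved by
#' choosing the candidate with the lexicographically larger coefficient
#' vector, which makes normalized descriptors invariant under rotation,
#' translation, scaling and cyclic shift of the input vertices.
#'
#' @param outline two-column matrix of vertices (closed polygon, first
#'   vertex not repeated).
#' @param N number of harmonics (default 20).
#' @param normalize standardize size/rotation/start point.
#' @return Object of class `efd_set`: `coef` (N x 4 matrix), `centre`
#'   (a0, c0 position terms), `scale` (the semi-axis divided out; 1 if not
#'   normalized), `normalized` flag, `T` (outline perimeter).
#' @export
efd_coefficients <- function(outline, N = 20, normalize = TRUE) {
  raw <- efd_raw(as.matrix(outline), N)
  co <- raw$coef
  scale <- 1
  if (normalize) {
    a1 <- co[1, "a"]; b1 <- co[1, "b"]
    c1 <- co[1, "c"]; d1 <- co[1, "d"]
    theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                         a1^2 + c1^2 - b1^2 - d1^2)
    cand <- normalize_one(co, theta)
    # make sure t = 0 is on the major (not minor) axis
    if (cand[1, "a"]^2 + cand[1, "c"]^2 <
        cand[1, "b"]^2 + cand[1, "d"]^2)
      cand <- normalize_one(co, theta + pi / 2)
    alt <- normalize_one(co, theta + pi)
    pick_lex <- function(u, v) {
      du <- as.vector(t(u)); dv <- as.vector(t(v))
      i <- which(abs(du - dv) > 1e-9)[1]
      if (is.na(i) || du[i] >= dv[i]) u else v
    }
    co <- pick_lex(cand, alt)
    scale <- co[1, "a"]
    co <- co / scale
  }
  structure(list(coef = co, centre = c(x = raw$a0, y = raw$c0),
                 scale = scale, normalized = normalize, T = raw$T),
            class = "efd_set")
}

#' Reconstruct an outline from elliptic Fourier descriptors
#'
#' Inverse Fourier sum
#' \eqn{x(t) = x_0 + \sum_n a_n \cos(2\pi n t/T) + b_n \sin(2\pi n t/T)}
#' (and likewise y with c, d) evaluated at `n_points` equally spaced
#' parameter values. Reconstruction error versus the source outline is
#' non-increasing in the number of harmonics.
#'
#' @param efd an `efd_set`.
#' @param n_points number of polygon vertices to generate.
#' @param harmonics how many harmonics to use (default: all in `efd`).
#' @return Two-column matrix of reconstructed vertices.
#' @export
reconstruct_outline <- function(efd, n_points = 300, harmonics = NULL) {
  co <- efd$coef * efd$scale
  if (is.null(harmonics)) harmonics <- nrow(co)
  harmonics <- min(harmonics, nrow(co))
  t <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  x <- rep(if (efd$normalized) 0 else efd$centre["x"], n_points)
  y <- rep(if (efd$normalized) 0 else efd$centre["y"], n_points)
  for (n in seq_len(harmonics)) {
    x <- x + co[n, "a"] * cos(2 * pi * n * t) + co[n, "b"] * sin(2 * pi * n * t)
    y <- y + co[n, "c"] * cos(2 * pi * n * t) + co[n, "d"] * sin(2 * pi * n * t)
  }
  cbind(x = x, y = y)
}

polygon_perimeter <- function(p) {
  dx <- diff(c(p[, 1], p[1, 1])); dy <- diff(c(p[, 2], p[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

feret_diameters <- function(p) {
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  nh <- nrow(hp)
  dmax <- 0
  for (i in seq_len(nh - 1))
    for (j in (i + 1):nh)
      dmax <- max(dmax, sum((hp[i, ] - hp[j, ])^2))
  dmax <- sqrt(dmax)
  dmin <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1 else i + 1
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- as.matrix(hp) %*% nrm
    dmin <- min(dmin, diff(range(proj)))
  }
  c(max = dmax, min = dmin)
}

fill_mask <- function(outline, nr, nc) {
  # scanline polygon fill on the pixel-centre grid (half-open rule)
  m <- matrix(FALSE, nr, nc)
  x <- outline[, 1]; y <- outline[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (row in seq_len(nr)) {
    yc <- row - 1 + 1e-7
    cross <- (y <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xc <- x[cross] + (yc - y[cross]) / (y2[cross] - y[cross]) *
      (x2[cross] - x[cross])
    xc <- sort(xc)
    for (i in seq(1, length(xc) - 1, by = 2)) {
      c1 <- ceiling(xc[i]) + 1
      c2 <- floor(xc[i + 1]) + 1
      if (c2 >= c1) m[row, max(c1, 1):min(c2, nc)] <- TRUE
    }
  }
  m
}

smooth_polygon <- function(p, w) {
  # circular moving average of the vertices; suppresses the stair-step bias
  # of pixel-centre boundaries in perimeter estimates
  if (w < 2) return(p)
  n <- nrow(p); h <- w %/% 2
  out <- p
  for (i in seq_len(n)) {
    idx <- ((i - h - 1):(i + h - 1)) %% n + 1
    out[i, ] <- colMeans(p[idx, , drop = FALSE])
  }
  out
}

#' Morpho-colorimetric descriptors of one seed
#'
#' Geometry from the outline polygon (shoelace area, perimeter,
#' rotating-calipers Feret diameters, convex hull) and colour statistics
#' over the interior pixels. The pixel-centre boundary is lightly smoothed
#' (window-3 circular moving average) before measuring, and the shoelace
#' area is corrected by half the perimeter for the half-pixel rim outside
#' the boundary centres; Feret diameters gain one pixel for the same
#' reason. Physical units come from the outline's pixel size.
#'
#' @param image the source image (grayscale matrix or RGB array).
#' @param outline a `seed_outline` from [trace_outline()] (or any closed
#'   polygon with a `pixel_size` attribute).
#' @param smooth_window boundary smoothing window (vertices; 1 disables).
#' @return One-row data.frame: `area_mm2`, `perimeter_mm`, `feret_max_mm`,
#'   `feret_min_mm`, `aspect_ratio`, `circularity` (4 pi A / P^2),
#'   `solidity`, `hull_area_mm2`, colour channel means/sds (`mean_R` ...)
#'   and greyscale mean/sd.
#' @export
seed_descriptors <- function(image, outline, smooth_window = 3) {
  px <- attr(outline, "pixel_size") %||% 1
  p <- as.matrix(outline)
  g <- to_gray(image)
  if (any(p[, 1] < 0) || any(p[, 2] < 0) ||
      any(p[, 1] > ncol(g) - 1) || any(p[, 2] > nrow(g) - 1))
    stop("outline lies outside the image")
  ps <- smooth_polygon(p, smooth_window)
  P_px <- polygon_perimeter(ps)
  A <- (abs(signed_area(ps)) + P_px / 2) * px^2
  P <- P_px * px
  fer <- (feret_diameters(p) + 1) * px
  hull <- ps[grDevices::chull(ps), , drop = FALSE]
  hullA <- (abs(signed_area(hull)) + polygon_perimeter(hull) / 2) * px^2
  mask <- fill_mask(p, nrow(g), ncol(g))
  rgb <- if (length(dim(image)) == 3) image else NULL
  stats1 <- function(v) c(mean = mean(v), sd = if (length(v) > 1)
    stats::sd(v) else 0)
  res <- data.frame(
    area_mm2 = A, perimeter_mm = P,
    feret_max_mm = fer["max"], feret_min_mm = fer["min"],
    aspect_ratio = fer["max"] / fer["min"],
    circularity = 4 * pi * A / P^2,
    solidity = A / hullA,
    hull_area_mm2 = hullA)
  gv <- g[mask]
  res$mean_gray <- mean(gv); res$sd_gray <- if (length(gv) > 1)
    stats::sd(gv) else 0
  if (!is.null(rgb)) {
    for (ch in 1:3) {
      v <- rgb[, , ch][mask]
      s <- stats1(v)
      res[[paste0("mean_", c("R", "G", "B")[ch])]] <- s["mean"]
      res[[paste0("sd_", c("R", "G", "B")[ch])]] <- s["sd"]
    }
  }
  rownames(res) <- NULL
  res
}

#' Feature table for a batch of seed images
#'
#' Traces the largest outline in each image, computes the descriptor set and
#' the normalized elliptic Fourier coefficients, and returns one row per
#' seed. With `N` harmonics the coefficient block has `4N - 2` columns
#' (b1 and c1 are fixed to zero by the normalization and omitted).
#'
#' @param images list of images (or of `gen_seed_images()` elements).
#' @param harmonics number of EFD harmonics.
#' @param labels optional class label per image (added as column `label`).
#' @param ... passed to [trace_outline()].
#' @return data.frame of descriptors + EFD coefficients (+ `label`).
#' @export
seed_feature_table <- function(images, harmonics = 20, labels = NULL, ...) {
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (is.list(img) && !is.null(img$image)) img <- img$image
    ols <- trace_outline(img, ...)
    if (!length(ols)) return(NULL)
    ol <- ols[[which.max(vapply(ols, function(o) attr(o, "area_px"),
                                numeric(1)))]]
    d <- seed_descriptors(img, ol)
    ef <- efd_coefficients(ol, N = harmonics)
    cf <- ef$coef
    v <- c(t(cf))
    names(v) <- paste0(rep(c("a", "b", "c", "d"), harmonics),
                       rep(seq_len(harmonics), each = 4))
    v <- v[setdiff(names(v), c("b1", "c1"))]
    cbind(d, as.data.frame(as.list(v)))
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (!is.null(labels)) out$label <- labels[keep]
  out
}
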