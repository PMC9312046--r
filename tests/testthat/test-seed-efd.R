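circle_poly <- function(r, n = 512, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_poly <- function(a, b, n = 2048) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = a * cos(th), y = b * sin(th))
}

# dense arc-length quadrature oracle for the Fourier coefficients of a
# closed curve given as a very fine polygon
efd_quadrature_oracle <- function(p, n) {
  x <- p[, 1]; y <- p[, 2]
  ds <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  s <- cumsum(ds); T <- s[length(s)]
  sm <- s - ds / 2
  xm <- (x + c(x[-1], x[1])) / 2; ym <- (y + c(y[-1], y[1])) / 2
  w <- 2 * pi * n / T
  c(a = 2 / T * sum(xm * cos(w * sm) * ds),
    b = 2 / T * sum(xm * sin(w * sm) * ds),
    c = 2 / T * sum(ym * cos(w * sm) * ds),
    d = 2 / T * sum(ym * sin(w * sm) * ds))
}

test_that("a circle is a pure first harmonic", {
  ef <- efd_coefficients(circle_poly(10, 512), N = 10, normalize = FALSE)
  expect_equal(abs(unname(ef$coef[1, "a"])), 10, tolerance = 1e-3)
  expect_equal(abs(unname(ef$coef[1, "d"])), 10, tolerance = 1e-3)
  expect_equal(unname(ef$coef[1, "b"]), 0, tolerance = 1e-3)
  expect_equal(unname(ef$coef[1, "c"]), 0, tolerance = 1e-3)
  amp <- sqrt(rowSums(ef$coef[2:10, ]^2))
  expect_lt(max(amp), 1e-3 * 10)
})

test_that("ellipse coefficients match the quadrature oracle; reconstruction recovers the axes", {
  p <- ellipse_poly(20, 10)
  ef <- efd_coefficients(p, N = 5, normalize = FALSE)
  for (n in c(1, 3, 5)) {
    orc <- efd_quadrature_oracle(ellipse_poly(20, 10, 20000), n)
    expect_equal(unname(ef$coef[n, "a"]), unname(orc["a"]),
                 tolerance = 2e-3)
    expect_equal(unname(ef$coef[n, "d"]), unname(orc["d"]),
                 tolerance = 2e-3)
  }
  # the full harmonic sum, not harmonic 1 alone, carries the true axes
  ef20 <- efd_coefficients(p, N = 20, normalize = FALSE)
  rec <- reconstruct_outline(ef20, 2000)
  expect_equal(diff(range(rec[, 1])) / 2, 20, tolerance = 0.005)
  expect_equal(diff(range(rec[, 2])) / 2, 10, tolerance = 0.005)
  # at N = 1 an ellipse-like fit is exact up to discretization for a circle
  efc <- efd_coefficients(circle_poly(7), N = 1, normalize = FALSE)
  rec1 <- reconstruct_outline(efc, 100)
  expect_equal(max(abs(sqrt(rec1[, 1]^2 + rec1[, 2]^2) - 7)), 0,
               tolerance = 1e-3)
})

test_that("square outlines show the 1/n^2 decay and vanishing even harmonics", {
  t <- seq(0, 1, length.out = 201)[-201]
  side <- function(p0, p1) cbind(p0[1] + t * (p1[1] - p0[1]),
                                 p0[2] + t * (p1[2] - p0[2]))
  sq <- rbind(side(c(1, 1), c(-1, 1)), side(c(-1, 1), c(-1, -1)),
              side(c(-1, -1), c(1, -1)), side(c(1, -1), c(1, 1)))
  ef <- efd_coefficients(sq, N = 12, normalize = FALSE)
  amp <- sqrt(rowSums(ef$coef^2))
  expect_lt(max(amp[c(2, 4, 6, 8, 10, 12)]), 1e-6)
  # odd amplitudes decay like 1/n^2 (Fourier of a piecewise-linear curve)
  expect_equal(amp[3] / amp[1], 1 / 9, tolerance = 0.05)
  expect_equal(amp[5] / amp[1], 1 / 25, tolerance = 0.1)
  # and match the dense quadrature oracle
  orc3 <- efd_quadrature_oracle(sq, 3)
  expect_equal(unname(ef$coef[3, ]), unname(orc3), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("normalized descriptors are invariant to similarity transforms and start point", {
  set.seed(17)
  s <- gen_seed_images(1, r0 = 40, axis_ratio = 1.4,
                       harmonic_amp = c("2" = 0.05, "3" = 0.08),
                       img_size = 160, seed = 10)
  p <- s[[1]]$outline
  base <- efd_coefficients(p, N = 12)$coef
  expect_equal(unname(base[1, "a"]), 1, tolerance = 1e-9)  # unit semi-axis
  expect_equal(unname(base[1, "b"]), 0, tolerance = 1e-6)
  expect_equal(unname(base[1, "c"]), 0, tolerance = 1e-6)

  for (rep in 1:5) {
    ang <- runif(1, 0, 2 * pi)
    sc <- runif(1, 0.3, 3)
    sh <- sample(nrow(p), 1)
    R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
    q <- sweep(p %*% t(R) * sc, 2, c(runif(1, -40, 40), runif(1, -40, 40)),
               "+")
    q <- q[c(sh:nrow(q), seq_len(sh - 1)), ]
    tr <- efd_coefficients(q, N = 12)$coef
    expect_equal(tr, base, tolerance = 1e-6)
  }
})

test_that("reconstruction error is non-increasing in harmonic count", {
  s <- gen_seed_images(1, r0 = 50, axis_ratio = 1.3,
                       harmonic_amp = c("4" = 0.06, "7" = 0.08),
                       img_size = 200, seed = 11)
  p <- s[[1]]$outline
  ef <- efd_coefficients(p, N = 25, normalize = FALSE)
  rms <- function(nh) {
    rec <- reconstruct_outline(ef, nrow(p), harmonics = nh)
    # nearest-vertex RMS distance to the source outline
    sqrt(mean(apply(rec, 1, function(v)
      min((p[, 1] - v[1])^2 + (p[, 2] - v[2])^2))))
  }
  e5 <- rms(5); e10 <- rms(10); e20 <- rms(20); e25 <- rms(25)
  expect_lt(e20, e5)
  expect_lte(e25, e20 + 1e-9)
  expect_lt(e25, 0.5)   # sub-half-pixel for a smooth synthetic seed
})

test_that("outline tracing recovers discs, counts seeds, and flags empties", {
  s <- gen_seed_images(1, r0 = 60, axis_ratio = 1, harmonic_amp = c("3" = 0),
                       img_size = 200, seed = 3)
  ols <- trace_outline(s[[1]]$image)
  expect_length(ols, 1)
  o <- ols[[1]]
  px_area <- abs(sum(o[, 1] * c(o[-1, 2], o[1, 2]) -
                       c(o[-1, 1], o[1, 1]) * o[, 2]) / 2)
  perim <- sum(sqrt(diff(c(o[, 1], o[1, 1]))^2 +
                      diff(c(o[, 2], o[1, 2]))^2))
  # boundary through pixel centres: polygon area + half-pixel rim = disc
  expect_equal(px_area + perim / 2, pi * 60^2, tolerance = 0.015)

  # several seeds: centroids recovered within a pixel
  imgs <- gen_seed_images(5, r0 = 20, img_size = 90, harmonic_sd = 0.01,
                          seed = 12)
  for (i in seq_along(imgs)) {
    oi <- trace_outline(imgs[[i]]$image, min_area = 30)
    expect_length(oi, 1)
    expect_lt(max(abs(colMeans(oi[[1]][, 1:2]) -
                        imgs[[i]]$params$centre)), 1)
  }

  blank <- matrix(1, 50, 50)
  expect_warning(empty <- trace_outline(blank), "no")
  expect_length(empty, 0)
})

test_that("seed descriptors match analytic geometry and exact colour fields", {
  s <- gen_seed_images(1, r0 = 60, axis_ratio = 1, harmonic_amp = c("3" = 0),
                       colour_mean = c(0.5, 0.5, 0.5), img_size = 200,
                       seed = 3)
  o <- trace_outline(s[[1]]$image)[[1]]
  d <- seed_descriptors(s[[1]]$image, o)
  px <- 25.4 / 1200
  expect_equal(d$circularity, 1, tolerance = 0.02)
  expect_equal(d$area_mm2, pi * (60 * px)^2, tolerance = 0.01)
  expect_gt(d$solidity, 0.98)
  # uniform mid-grey interior: channel means are exact
  expect_equal(d$mean_R, 0.5)
  expect_equal(d$mean_G, 0.5)
  expect_equal(d$sd_B, 0)

  e <- gen_seed_images(1, r0 = 55, axis_ratio = 2, harmonic_amp = c("3" = 0),
                       img_size = 260, seed = 4)
  oe <- trace_outline(e[[1]]$image)[[1]]
  de <- seed_descriptors(e[[1]]$image, oe)
  expect_equal(de$aspect_ratio, 2, tolerance = 0.02)

  expect_error(seed_descriptors(matrix(1, 10, 10), o), "outside")
})

test_that("descriptor geometry agrees with brute-force pixel counting", {
  s <- gen_seed_images(1, r0 = 45, axis_ratio = 1.3,
                       harmonic_amp = c("3" = 0.06), img_size = 160,
                       seed = 21)
  g <- (s[[1]]$image[, , 1] + s[[1]]$image[, , 2] + s[[1]]$image[, , 3]) / 3
  o <- trace_outline(s[[1]]$image)[[1]]
  d <- seed_descriptors(s[[1]]$image, o)
  px <- 25.4 / 1200
  npx <- sum(g < 0.9)
  expect_equal(d$area_mm2, npx * px^2, tolerance = 0.02)
})
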