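# Synthetic generators for every evidence stream. All are pure functions of
# their arguments: a root seed is combined with a fixed per-generator offset
# so the streams are independent but reproducible.

derive_seed <- function(seed, offset) {
  (as.integer(seed) + offset) %% .Machine$integer.max
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulation specification for a mixed-type morphometric dataset
#'
#' Describes populations, their latent group assignment, and per-character
#' group effects. Quantitative characters are drawn from per-group normal
#' (or log-normal) distributions whose means are shifted between groups in
#' units of the residual sd; qualitative characters are drawn from per-group
#' state-probability vectors.
#'
#' @param n_populations number of populations.
#' @param n_per_pop individuals per population (field-realistic default 20).
#' @param group_assignment named vector population code -> latent group; by
#'   default populations are split evenly into `n_groups` groups.
#' @param n_groups number of latent groups when `group_assignment` is NULL.
#' @param n_quant,n_binary,n_nominal,n_ordinal character counts by type.
#' @param effect_sd mean shift between successive groups, in sd units,
#'   applied to the first `n_effect_quant` quantitative characters.
#' @param n_effect_quant number of quantitative characters carrying the shift.
#' @param qual_effect strength in (0,1) of the qualitative state-probability
#'   tilt between groups (0 = identical distributions in all groups).
#' @param lognormal logical: draw the shifted quantitative characters on the
#'   log scale (values are then exponentiated).
#' @param noise_sd residual standard deviation of quantitative characters.
#' @param seed integer root seed.
#' @return List of class `morpho_sim_spec`.
#' @export
morpho_sim_spec <- function(n_populations = 12, n_per_pop = 20,
                            group_assignment = NULL, n_groups = 2,
                            n_quant = 28, n_binary = 15, n_nominal = 2,
                            n_ordinal = 4, effect_sd = 0, n_effect_quant = 10,
                            qual_effect = 0, lognormal = FALSE,
                            noise_sd = 1, seed = 1) {
  if (n_per_pop < 2) stop("n_per_pop must be >= 2")
  pops <- sprintf("P%02d", seq_len(n_populations))
  if (is.null(group_assignment)) {
    group_assignment <- stats::setNames(
      paste0("G", rep_len(seq_len(n_groups), n_populations)), pops)
  } else {
    if (!all(pops %in% names(group_assignment)) &&
        !is.null(names(group_assignment)))
      pops <- names(group_assignment)
  }
  structure(list(n_populations = length(pops), n_per_pop = n_per_pop,
                 populations = pops, group_assignment = group_assignment,
                 n_quant = n_quant, n_binary = n_binary,
                 n_nominal = n_nominal, n_ordinal = n_ordinal,
                 effect_sd = effect_sd, n_effect_quant = n_effect_quant,
                 qual_effect = qual_effect, lognormal = lognormal,
                 noise_sd = noise_sd, seed = seed),
            class = "morpho_sim_spec")
}

#' Generate a synthetic mixed-type morphometric dataset
#'
#' @param spec a [morpho_sim_spec].
#' @return A validated [morpho_dataset]; deterministic given the spec's seed.
#' @export
gen_morpho_dataset <- function(spec) {
  stopifnot(inherits(spec, "morpho_sim_spec"))
  with_seed(derive_seed(spec$seed, 101L), {
    pops <- rep(spec$populations, each = spec$n_per_pop)
    n <- length(pops)
    grp <- spec$group_assignment[pops]
    gidx <- as.integer(factor(grp, levels = unique(spec$group_assignment)))

    name <- c(sprintf("QC%02d", seq_len(spec$n_quant)),
              sprintf("BI%02d", seq_len(spec$n_binary)),
              sprintf("CN%02d", seq_len(spec$n_nominal)),
              sprintf("CO%02d", seq_len(spec$n_ordinal)))
    ctype <- c(rep("quantitative_continuous", spec$n_quant),
               rep("binary", spec$n_binary),
               rep("nominal", spec$n_nominal),
               rep("ordinal", spec$n_ordinal))
    levels <- c(vector("list", spec$n_quant),
                rep(list(c("no", "yes")), spec$n_binary),
                rep(list(c("green", "pink", "white")), spec$n_nominal),
                rep(list(c("round", "acute", "mucronate", "apiculate")),
                    spec$n_ordinal))
    desc <- character_descriptors(name, ctype, levels)

    vals <- vector("list", length(name))
    names(vals) <- name
    for (j in seq_len(spec$n_quant)) {
      shift <- if (j <= spec$n_effect_quant)
        (gidx - 1) * spec$effect_sd * spec$noise_sd else 0
      mu <- 10 + shift
      x <- stats::rnorm(n, mu, spec$noise_sd)
      if (spec$lognormal && j <= spec$n_effect_quant) x <- exp(x / 4)
      vals[[j]] <- x
    }
    tilt_probs <- function(base, g) {
      # shift probability mass toward later states for later groups
      w <- base * (1 + spec$qual_effect * (g - 1) *
                     (seq_along(base) - mean(seq_along(base))))
      w <- pmax(w, 1e-6)
      w / sum(w)
    }
    qual_draw <- function(lv, base) {
      vapply(gidx, function(g)
        sample(lv, 1, prob = tilt_probs(base, g)), character(1))
    }
    off <- spec$n_quant
    for (j in seq_len(spec$n_binary))
      vals[[off + j]] <- qual_draw(c("no", "yes"), c(0.5, 0.5))
    off <- off + spec$n_binary
    for (j in seq_len(spec$n_nominal))
      vals[[off + j]] <- qual_draw(c("green", "pink", "white"),
                                   c(0.4, 0.35, 0.25))
    off <- off + spec$n_nominal
    for (j in seq_len(spec$n_ordinal))
      vals[[off + j]] <- qual_draw(c("round", "acute", "mucronate",
                                     "apiculate"), c(0.3, 0.3, 0.25, 0.15))

    morpho_dataset(sprintf("ind%03d", seq_len(n)), pops, desc,
                   as.data.frame(vals, stringsAsFactors = FALSE))
  })
}

#' Generate seed images with known outlines
#'
#' Renders `n` dark seed silhouettes, one per image, on a white background.
#' Each boundary is a truncated radial Fourier series
#' \eqn{r(\phi) = r_0 (1 + \sum_k A_k \cos(k\phi + \phi_k))} whose true
#' parameters are returned; an optional axis ratio squeezes the base circle
#' into an ellipse. Silhouettes are centred, so seeds never touch image
#' borders or one another.
#'
#' @param n number of seeds (one image each).
#' @param r0 base radius in pixels.
#' @param axis_ratio major/minor axis ratio of the underlying ellipse.
#' @param harmonic_amp named numeric vector of radial harmonic amplitudes,
#'   e.g. `c("2" = 0.05)`; sampled per-seed with sd `harmonic_sd`.
#' @param harmonic_sd per-seed sd of the amplitudes.
#' @param colour_mean mean RGB of the seed interior (0..1, length 3).
#' @param colour_sd per-pixel Gaussian colour noise sd.
#' @param img_size image side in pixels.
#' @param seed integer seed.
#' @return List of `n` elements, each with `image` (img_size x img_size x 3
#'   array in \[0,1\]), `outline` (ground-truth polygon, x/y columns, pixel
#'   coordinates, counterclockwise), and `params` (true shape parameters).
#' @export
gen_seed_images <- function(n, r0 = 60, axis_ratio = 1,
                            harmonic_amp = c("3" = 0.04),
                            harmonic_sd = 0, colour_mean = c(0.35, 0.22, 0.12),
                            colour_sd = 0, img_size = 200, seed = 1) {
  stopifnot(n >= 1)
  with_seed(derive_seed(seed, 202L), {
    lapply(seq_len(n), function(i) {
      ks <- as.integer(names(harmonic_amp))
      amp <- harmonic_amp + if (harmonic_sd > 0)
        stats::rnorm(length(harmonic_amp), 0, harmonic_sd) else 0
      pha <- stats::runif(length(harmonic_amp), 0, 2 * pi)
      cx <- img_size / 2; cy <- img_size / 2
      radial <- function(phi) {
        f <- rep(1, length(phi))
        for (h in seq_along(ks)) f <- f + amp[h] * cos(ks[h] * phi + pha[h])
        pmax(f, 0.05)
      }
      # silhouette mask: pixel centres (0-based) inside the boundary
      xs <- matrix(rep(seq_len(img_size) - 1, each = img_size), img_size)
      ys <- matrix(rep(seq_len(img_size) - 1, times = img_size), img_size)
      dx <- (xs - cx) / axis_ratio
      dy <- ys - cy
      phi <- atan2(dy, dx)
      rr <- sqrt(dx^2 + dy^2)
      inside <- rr <= r0 * radial(phi)
      img <- array(1, c(img_size, img_size, 3))
      for (ch in 1:3) {
        plane <- img[, , ch]
        col <- colour_mean[ch] + if (colour_sd > 0)
          stats::rnorm(sum(inside), 0, colour_sd) else 0
        plane[inside] <- pmin(pmax(col, 0), 1)
        img[, , ch] <- plane
      }
      phis <- seq(0, 2 * pi, length.out = 721)[-721]
      ol <- cbind(x = cx + axis_ratio * r0 * radial(phis) * cos(phis),
                  y = cy + r0 * radial(phis) * sin(phis))
      list(image = img,
           outline = ol,
           params = list(r0 = r0, axis_ratio = axis_ratio,
                         harmonics = ks, amplitudes = amp, phases = pha,
                         centre = c(cx, cy), colour_mean = colour_mean))
    })
  })
}

#' Generate synthetic karyotype metaphase plates
#'
#' Each plate carries `2n` chromosomes; haploid arm lengths are drawn from a
#' log-normal model and duplicated (with optional measurement noise) into
#' homologue pairs, matching how measured plates list all 2n chromosomes.
#'
#' @param n_plates number of plates.
#' @param two_n diploid chromosome number (must be even; default 18, the
#'   diploid complement typical of the study group).
#' @param mean_cl mean chromosome length, micrometres.
#' @param arm_ratio mean long/short arm ratio.
#' @param cv_cl between-chromosome coefficient of variation of length (%).
#' @param noise_sd measurement noise sd (micrometres) added per chromosome.
#' @param population population code attached to every plate.
#' @param seed integer seed.
#' @return List of `karyo_plate` objects (see [karyo_plate()]).
#' @export
gen_karyotype_plates <- function(n_plates, two_n = 18, mean_cl = 4.7,
                                 arm_ratio = 1.5, cv_cl = 15, noise_sd = 0,
                                 population = "POP", seed = 1) {
  stopifnot(two_n %% 2 == 0, two_n >= 2)
  with_seed(derive_seed(seed, 303L), {
    lapply(seq_len(n_plates), function(i) {
      nh <- two_n / 2
      sdlog <- sqrt(log(1 + (cv_cl / 100)^2))
      cl <- stats::rlnorm(nh, log(mean_cl) - sdlog^2 / 2, sdlog)
      ci <- 1 / (1 + arm_ratio)           # short / total
      S <- cl * ci
      L <- cl - S
      L2 <- rep(L, each = 2); S2 <- rep(S, each = 2)
      if (noise_sd > 0) {
        L2 <- pmax(L2 + stats::rnorm(two_n, 0, noise_sd), 0.1)
        S2 <- pmax(S2 + stats::rnorm(two_n, 0, noise_sd), 0.05)
        sw <- S2 > L2
        tmp <- L2[sw]; L2[sw] <- S2[sw]; S2[sw] <- tmp
      }
      karyo_plate(population, sprintf("%s_plate%02d", population, i),
                  long_arm = L2, short_arm = S2)
    })
  })
}

#' Simulation specification for a two-taxon niche scenario
#'
#' @param landscape_size side length of the square landscape, cells.
#' @param n_env number of environmental variables (surfaces).
#' @param centres list of two numeric vectors (length `n_env`): niche optima
#'   of the two taxa in environmental units.
#' @param widths list of two positive numeric vectors: niche breadths (sd of
#'   the Gaussian suitability) per variable.
#' @param n_occ occurrences per taxon (>= 5).
#' @param buffer_cells background buffer radius around occurrences, cells
#'   (the planar analogue of a fixed-km buffer).
#' @param smooth_radius Gaussian blur radius (cells) generating spatial
#'   autocorrelation of the environmental surfaces.
#' @param seed integer seed.
#' @return List of class `niche_sim_spec`.
#' @export
niche_sim_spec <- function(landscape_size = 120, n_env = 2,
                           centres = list(c(0, 0), c(0, 0)),
                           widths = list(c(1, 1), c(1, 1)),
                           n_occ = 100, buffer_cells = 10,
                           smooth_radius = 8, seed = 1) {
  stopifnot(n_occ >= 5, all(unlist(widths) > 0))
  structure(list(landscape_size = landscape_size, n_env = n_env,
                 centres = centres, widths = widths, n_occ = n_occ,
                 buffer_cells = buffer_cells, smooth_radius = smooth_radius,
                 seed = seed),
            class = "niche_sim_spec")
}

gaussian_blur <- function(m, radius) {
  # separable Gaussian blur with reflecting edges
  half <- max(1L, ceiling(3 * radius))
  k <- stats::dnorm(-half:half, sd = radius)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    idx <- c(rev(seq_len(half)), seq_along(v),
             length(v) - seq_len(half) + 1)
    stats::filter(v[idx], k, sides = 2)[half + seq_along(v)]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(t(m), 2, smooth_vec))
}

#' Generate a two-taxon niche scenario
#'
#' Environmental surfaces are smoothed white noise (spatially
#' autocorrelated, standardized); occurrences are placed by sampling cells
#' with probability proportional to a Gaussian suitability around each
#' taxon's niche centre in environment space; each taxon's background mask
#' is the union of circular buffers around its occurrences.
#'
#' @param spec a [niche_sim_spec].
#' @return List with `env` (list of landscape matrices), `occ` (list of two
#'   two-column cell-coordinate matrices), `background` (list of two logical
#'   masks), and `spec`.
#' @export
gen_niche_scenario <- function(spec) {
  stopifnot(inherits(spec, "niche_sim_spec"))
  with_seed(derive_seed(spec$seed, 404L), {
    R <- spec$landscape_size
    env <- lapply(seq_len(spec$n_env), function(v) {
      m <- gaussian_blur(matrix(stats::rnorm(R * R), R, R),
                         spec$smooth_radius)
      (m - mean(m)) / stats::sd(m)
    })
    cellxy <- cbind(x = rep(seq_len(R), each = R), y = rep(seq_len(R), R))
    E <- sapply(env, function(m) m[cbind(cellxy[, "y"], cellxy[, "x"])])
    occ <- lapply(1:2, function(t) {
      su <- rep(1, nrow(E))
      for (v in seq_len(spec$n_env))
        su <- su * exp(-0.5 * ((E[, v] - spec$centres[[t]][v]) /
                                 spec$widths[[t]][v])^2)
      if (sum(su) <= 0) stop("niche centre outside available environment")
      cells <- sample(nrow(E), spec$n_occ, replace = TRUE, prob = su)
      cellxy[cells, , drop = FALSE]
    })
    background <- lapply(occ, function(o) {
      mask <- matrix(FALSE, R, R)
      gx <- rep(seq_len(R), each = R); gy <- rep(seq_len(R), R)
      for (i in seq_len(nrow(o))) {
        near <- (gx - o[i, "x"])^2 + (gy - o[i, "y"])^2 <=
          spec$buffer_cells^2
        mask[cbind(gy[near], gx[near])] <- TRUE
      }
      mask
    })
    list(env = env, occ = occ, background = background, spec = spec)
  })
}
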