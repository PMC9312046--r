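#' Karyotype metaphase plate
#'
#' Per-plate chromosome arm lengths. By convention the long arm `L` is at
#' least as long as the short arm `S`; both are positive (micrometres).
#'
#' @param population population code.
#' @param plate_id plate identifier.
#' @param long_arm,short_arm numeric vectors of arm lengths, one entry per
#'   chromosome (2n entries for a diploid plate).
#' @return Object of class `karyo_plate`.
#' @export
karyo_plate <- function(population, plate_id, long_arm, short_arm) {
  long_arm <- as.numeric(long_arm); short_arm <- as.numeric(short_arm)
  if (length(long_arm) != length(short_arm))
    stop("arm vectors must have equal length")
  if (any(short_arm <= 0)) stop("arm lengths must be positive")
  if (any(long_arm < short_arm))
    stop("orientation convention violated: long arm shorter than short arm")
  structure(list(population = as.character(population),
                 plate_id = as.character(plate_id),
                 long_arm = long_arm, short_arm = short_arm),
            class = "karyo_plate")
}

#' Read karyotype plates from CSV
#'
#' Expected columns: `population,plate_id,chromosome,long_arm_um,short_arm_um`.
#'
#' @param path CSV path.
#' @return List of [karyo_plate] objects.
#' @export
read_karyo_plates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "plate_id", "chromosome", "long_arm_um",
            "short_arm_um")
  if (!all(need %in% colnames(tab)))
    stop("plate file must have columns ", paste(need, collapse = ","))
  unname(lapply(split(tab, tab$plate_id), function(d)
    karyo_plate(d$population[1], d$plate_id[1], d$long_arm_um,
                d$short_arm_um)))
}

#' Per-chromosome metrics and Levan morphology class
#'
#' For arm lengths `L >= S > 0`: total length `CL = L + S`, centromeric
#' index `CI = S/CL`, arm ratio `r = L/S`, centromeric asymmetry
#' `CA = 100 (L - S)/CL`. Morphology by arm ratio: metacentric
#' \eqn{r \in [1, 1.7)}, submetacentric \eqn{[1.7, 3)}, subtelocentric
#' \eqn{[3, 7)}, acrocentric/telocentric \eqn{\ge 7} (boundary values go to
#' the more asymmetric class).
#'
#' @param L,S long and short arm lengths (vectorized).
#' @return data.frame with `CL`, `CI`, `arm_ratio`, `CA`, `levan_class`.
#' @export
chromosome_metrics <- function(L, S) {
  if (any(S <= 0)) stop("arm lengths must be positive")
  if (any(L < S)) stop("orientation convention violated: L must be >= S")
  CL <- L + S
  r <- L / S
  cls <- cut(r, breaks = c(1, 1.7, 3, 7, Inf), right = FALSE,
             labels = c("metacentric", "submetacentric", "subtelocentric",
                        "acro_telocentric"))
  data.frame(CL = CL, CI = S / CL, arm_ratio = r, CA = 100 * (L - S) / CL,
             levan_class = as.character(cls), stringsAsFactors = FALSE)
}

#' Plate-level karyotype asymmetry indices
#'
#' Homologues are paired by sorting on total length (descending) with
#' centromeric index as tiebreak, then averaging adjacent pairs into the
#' haploid complement, on which the indices are computed:
#' total haploid length `THL` (sum of haploid `CL`), mean centromeric
#' asymmetry `MCA` (mean of per-chromosome `CA`), and the heterogeneity
#' coefficients `CVCL = 100 sd(CL)/mean(CL)` and `CVCI = 100 sd(CI)/mean(CI)`
#' (sample sd). Levan-class counts are tallied over the haploid complement.
#'
#' @param plate a [karyo_plate] with an even number of chromosomes.
#' @return Object of class `karyo_indices`: list with `THL`, `MCA`, `CVCL`,
#'   `CVCI`, `mean_CL`, `morphology` (named class counts), plus the plate's
#'   `population` and `plate_id`.
#' @export
plate_indices <- function(plate) {
  stopifnot(inherits(plate, "karyo_plate"))
  n <- length(plate$long_arm)
  if (n %% 2 != 0) stop("odd chromosome count: homologues cannot be paired")
  cm <- chromosome_metrics(plate$long_arm, plate$short_arm)
  o <- order(-cm$CL, cm$CI)
  idx1 <- o[seq(1, n, by = 2)]; idx2 <- o[seq(2, n, by = 2)]
  hapL <- (plate$long_arm[idx1] + plate$long_arm[idx2]) / 2
  hapS <- (plate$short_arm[idx1] + plate$short_arm[idx2]) / 2
  hap <- chromosome_metrics(hapL, hapS)
  nh <- nrow(hap)
  structure(list(
    population = plate$population, plate_id = plate$plate_id,
    THL = sum(hap$CL),
    MCA = mean(hap$CA),
    CVCL = if (nh >= 2) 100 * stats::sd(hap$CL) / mean(hap$CL) else NA_real_,
    CVCI = if (nh >= 2) 100 * stats::sd(hap$CI) / mean(hap$CI) else NA_real_,
    mean_CL = mean(hap$CL),
    morphology = table(factor(hap$levan_class,
                              levels = c("metacentric", "submetacentric",
                                         "subtelocentric",
                                         "acro_telocentric")))),
    class = "karyo_indices")
}

#' @export
print.karyo_indices <- function(x, ...) {
  cat(sprintf("karyo_indices [%s/%s]: THL = %.2f um, MCA = %.2f%%, ",
              x$population, x$plate_id, x$THL, x$MCA),
      sprintf("CVCL = %.2f%%, CVCI = %.2f%%\n", x$CVCL, x$CVCI))
  invisible(x)
}

#' Collect plate indices into a data frame
#'
#' @param plates list of [karyo_plate] objects.
#' @return data.frame, one row per plate, with the four asymmetry indices.
#' @export
karyo_index_table <- function(plates) {
  do.call(rbind, lapply(plates, function(p) {
    ki <- plate_indices(p)
    data.frame(population = ki$population, plate_id = ki$plate_id,
               THL = ki$THL, MCA = ki$MCA, CVCL = ki$CVCL, CVCI = ki$CVCI,
               mean_CL = ki$mean_CL, stringsAsFactors = FALSE)
  }))
}

#' Compare karyotype indices between groups
#'
#' Two groups: pooled two-sample t-test per index. Three or more groups:
#' one-way ANOVA with Tukey-Kramer pairwise comparisons. Zero within-group
#' variance is flagged (exact ties give p = 1 for identical means, p = 0
#' otherwise, from the degenerate test limit).
#'
#' @param indices data.frame from [karyo_index_table()].
#' @param groups group label per plate (or [grouping_hypothesis]; the
#'   `population` column is then mapped).
#' @param which indices to test.
#' @return data.frame with one row per index (and per pair when >= 3
#'   groups): `index`, `statistic`, `df`, `p`, and pair columns.
#' @export
compare_karyo_groups <- function(indices, groups,
                                 which = c("THL", "MCA", "CVCL", "CVCI")) {
  g <- if (inherits(groups, "grouping_hypothesis"))
    group_labels(indices$population, groups) else as.character(groups)
  if (length(g) != nrow(indices))
    stop("need one group label per plate")
  tg <- table(g)
  if (length(tg) < 2 || any(tg < 2))
    stop("need >= 2 groups with >= 2 plates each")
  out <- list()
  for (ix in which) {
    x <- indices[[ix]]
    if (length(tg) == 2) {
      sp <- split(x, g)
      if (all(vapply(sp, stats::var, numeric(1)) == 0)) {
        p <- if (mean(sp[[1]]) == mean(sp[[2]])) 1 else 0
        out[[length(out) + 1]] <- data.frame(
          index = ix, comparison = paste(names(sp), collapse = " vs "),
          statistic = NA_real_, df = NA_real_, p = p,
          note = "zero within-group variance", stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = TRUE)
        out[[length(out) + 1]] <- data.frame(
          index = ix, comparison = paste(names(sp), collapse = " vs "),
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, note = "pooled t-test", stringsAsFactors = FALSE)
      }
    } else {
      fit <- stats::aov(x ~ factor(g))
      an <- summary(fit)[[1]]
      out[[length(out) + 1]] <- data.frame(
        index = ix, comparison = "omnibus",
        statistic = an[1, "F value"], df = an[1, "Df"],
        p = an[1, "Pr(>F)"], note = "one-way ANOVA",
        stringsAsFactors = FALSE)
      tk <- tukey_kramer_p(x, g)
      out[[length(out) + 1]] <- data.frame(
        index = ix, comparison = paste(tk$group1, "vs", tk$group2),
        statistic = NA_real_, df = NA_real_, p = tk$p,
        note = "Tukey-Kramer", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
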