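#' Run the grouping-hypothesis competition across evidence streams
#'
#' For each grouping hypothesis, runs the morphometric stream (Gower-Podani
#' dissimilarity, Cailliez correction when needed, ANOSIM; integer encoding,
#' jackknifed LDA, Cohen's kappa) and any configured optional streams
#' (karyology index comparisons, seed-feature classification, niche
#' overlap + similarity test), all under one root seed. Hypotheses are
#' ranked by kappa — the chance-corrected agreement between a-priori and
#' predicted groups — with the conventional kappa > 0.75 flag for excellent
#' agreement. Streams are juxtaposed, not aggregated: the verdict is a
#' ranking plus per-stream statistics, never an automated taxonomic
#' decision.
#'
#' @param morpho a [morpho_dataset] (required stream).
#' @param hypotheses list of [grouping_hypothesis] objects.
#' @param karyo optional data.frame from [karyo_index_table()].
#' @param seed_features optional data.frame of per-seed features with a
#'   `population` column (classified per hypothesis with [jackknife_lda()]).
#' @param niche optional list with `env`, `occ`, `background` as produced by
#'   [gen_niche_scenario()] (used only for two-group hypotheses; occurrence
#'   sets must already correspond to the two groups).
#' @param n_perm ANOSIM permutations.
#' @param n_reps niche similarity replicates.
#' @param seed root seed; every stochastic stage derives its stream from it.
#' @return Object of class `hypothesis_report`: data.frame with one row per
#'   hypothesis (`hypothesis`, `anosim_R`, `anosim_p`, `percent_correct`,
#'   `kappa`, `excellent_agreement`, optional stream columns), ranked by
#'   kappa, with per-hypothesis details in `attr(, "details")`.
#' @export
run_competition <- function(morpho, hypotheses, karyo = NULL,
                            seed_features = NULL, niche = NULL,
                            n_perm = 999, n_reps = 99, seed = 1) {
  stopifnot(inherits(morpho, "morpho_dataset"))
  if (inherits(hypotheses, "grouping_hypothesis"))
    hypotheses <- list(hypotheses)
  pops <- unique(morpho$populations)
  for (h in hypotheses) {
    miss <- setdiff(pops, names(h$mapping))
    if (length(miss))
      stop("hypothesis '", h$name, "' misses population(s): ",
           paste(miss, collapse = ", "))
    if (!is.null(karyo)) {
      miss <- setdiff(unique(karyo$population), names(h$mapping))
      if (length(miss))
        stop("karyology stream has unmapped population(s) under '",
             h$name, "': ", paste(miss, collapse = ", "))
    }
    if (!is.null(seed_features)) {
      miss <- setdiff(unique(seed_features$population), names(h$mapping))
      if (length(miss))
        stop("seed stream has unmapped population(s) under '",
             h$name, "': ", paste(miss, collapse = ", "))
    }
  }

  D <- gower_podani(morpho)
  D <- euclidean_check(D)
  if (!isTRUE(D$is_euclidean)) D <- cailliez_correction(D)$D
  enc <- encode_qualitative(morpho)

  rows <- list(); details <- list()
  for (i in seq_along(hypotheses)) {
    h <- hypotheses[[i]]
    g <- group_labels(morpho, h)
    an <- anosim(D, g, n_perm = n_perm, seed = derive_seed(seed, 11L * i))
    cl <- jackknife_lda(enc$x, g)
    row <- data.frame(hypothesis = h$name,
                      anosim_R = an$R, anosim_p = an$p,
                      percent_correct = cl$percent_correct,
                      kappa = cl$kappa,
                      excellent_agreement = isTRUE(cl$kappa > 0.75),
                      stringsAsFactors = FALSE)
    det <- list(anosim = an, classification = cl)
    if (!is.null(karyo)) {
      kg <- group_labels(karyo$population, h)
      kc <- tryCatch(compare_karyo_groups(karyo, kg),
                     error = function(e) NULL)
      det$karyo <- kc
      row$karyo_min_p <- if (is.null(kc)) NA_real_ else
        min(kc$p, na.rm = TRUE)
    }
    if (!is.null(seed_features)) {
      sg <- group_labels(seed_features$population, h)
      fx <- as.matrix(seed_features[, vapply(seed_features, is.numeric,
                                             logical(1)), drop = FALSE])
      sc <- jackknife_lda(fx, sg)
      det$seed_classification <- sc
      row$seed_percent_correct <- sc$percent_correct
      row$seed_kappa <- sc$kappa
    }
    if (!is.null(niche) && length(unique(g)) == 2) {
      nt <- similarity_test(niche$env, niche$occ, niche$background,
                            n_reps = n_reps,
                            seed = derive_seed(seed, 13L * i))
      det$niche <- nt
      row$niche_D <- nt$D
      row$niche_p_sim <- min(nt$p_sim)
    }
    rows[[i]] <- row; details[[h$name]] <- det
  }
  rep <- do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(unique(unlist(lapply(rows, names))), names(r)))
      r[[cc]] <- NA
    r
  }))
  rep <- rep[order(-rep$kappa), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "details") <- details
  attr(rep, "seed") <- seed
  class(rep) <- c("hypothesis_report", class(rep))
  rep
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Grouping-hypothesis competition (ranked by Cohen's kappa):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Render a hypothesis report to files
#'
#' Writes the ranked summary as CSV, a plain-text summary, and one
#' margin-annotated confusion-matrix CSV per hypothesis.
#'
#' @param report a `hypothesis_report`.
#' @param dir output directory (created if missing).
#' @param format currently `"csv"`.
#' @return Invisibly, the written paths.
#' @export
render_report <- function(report, dir, format = "csv") {
  if (!identical(format, "csv")) stop("unknown format: ", format)
  if (!nrow(report)) stop("empty report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "hypothesis_report.csv")
  utils::write.csv(as.data.frame(report), paths[1], row.names = FALSE)
  details <- attr(report, "details")
  txt <- c("Grouping-hypothesis competition", "")
  for (nm in report$hypothesis) {
    d <- details[[nm]]
    cmp <- file.path(dir, paste0("confusion_", nm, ".csv"))
    write_confusion(d$classification$confusion, cmp)
    paths <- c(paths, cmp)
    txt <- c(txt, sprintf(
      "%s: ANOSIM R = %.4f (p = %.4g); %.1f%% correct, kappa = %.4f%s",
      nm, d$anosim$R, d$anosim$p, d$classification$percent_correct,
      d$classification$kappa,
      if (isTRUE(d$classification$kappa > 0.75))
        " [excellent agreement]" else ""))
  }
  sp <- file.path(dir, "summary.txt")
  writeLines(txt, sp)
  invisible(c(paths, sp))
}
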