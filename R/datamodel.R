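#' Character descriptor table
#'
#' Builds and validates the per-character metadata table used throughout the
#' package. Each character (variable) measured on an individual plant has a
#' type: `binary`, `nominal`, `ordinal`, `quantitative_continuous` or
#' `quantitative_discrete`. Qualitative characters carry an ordered vector of
#' admissible states (`levels`); for ordinal characters the order of the
#' levels is the rank order used by the ordinal dissimilarity correction.
#'
#' @param name character vector of character (variable) names.
#' @param ctype character vector of types, one per character.
#' @param levels list of character vectors of admissible states (qualitative
#'   characters only; `NULL` entries for quantitative ones).
#' @param units character vector of measurement units (free text, optional).
#' @return A data.frame of class `character_descriptors` with columns
#'   `name`, `ctype`, `levels` (list column) and `units`.
#' @export
character_descriptors <- function(name, ctype, levels = NULL, units = NULL) {
  ctypes <- c("binary", "nominal", "ordinal",
              "quantitative_continuous", "quantitative_discrete")
  name <- as.character(name)
  ctype <- as.character(ctype)
  if (length(ctype) != length(name))
    stop("'name' and 'ctype' must have the same length")
  bad <- setdiff(unique(ctype), ctypes)
  if (length(bad))
    stop("unknown ctype(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(name))
    stop("duplicated character names")
  if (is.null(levels)) levels <- vector("list", length(name))
  if (length(levels) != length(name))
    stop("'levels' must have one entry per character")
  if (is.null(units)) units <- rep("", length(name))
  for (i in seq_along(name)) {
    qual <- ctype[i] %in% c("binary", "nominal", "ordinal")
    if (qual) {
      lv <- levels[[i]]
      if (is.null(lv) || length(lv) < 2)
        stop("qualitative character '", name[i], "' needs >= 2 declared levels")
      if (ctype[i] == "binary" && length(lv) != 2)
        stop("binary character '", name[i], "' must have exactly 2 levels")
      if (anyDuplicated(lv))
        stop("duplicated levels for character '", name[i], "'")
    } else if (!is.null(levels[[i]]) && length(levels[[i]]) > 0) {
      stop("quantitative character '", name[i], "' must not declare levels")
    }
  }
  out <- data.frame(name = name, ctype = ctype, units = as.character(units),
                    stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("character_descriptors", "data.frame")
  out
}

is_qualitative <- function(ctype) ctype %in% c("binary", "nominal", "ordinal")
is_quantitative <- function(ctype) !is_qualitative(ctype)

#' Morphometric dataset
#'
#' Container for an individuals-by-characters table of mixed-type
#' morphological measurements with per-individual population codes and
#' per-character descriptors. Missing cells are `NA` and are propagated, not
#' imputed; the Gower machinery excludes them pair by pair.
#'
#' @param individuals character vector of individual identifiers.
#' @param populations character vector of population codes, one per
#'   individual.
#' @param descriptors a [character_descriptors] table.
#' @param values data.frame with one row per individual and one column per
#'   character, in descriptor order. Qualitative columns are character,
#'   quantitative columns numeric.
#' @return Object of class `morpho_dataset`.
#' @export
morpho_dataset <- function(individuals, populations, descriptors, values) {
  individuals <- as.character(individuals)
  populations <- as.character(populations)
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  ds <- structure(list(individuals = individuals,
                       populations = populations,
                       descriptors = descriptors,
                       values = values),
                  class = "morpho_dataset")
  validate_morpho_dataset(ds)
  ds
}

#' Validate a morphometric dataset
#'
#' Checks dimension consistency, non-empty population codes, and that every
#' qualitative value is among its descriptor's declared levels. Errors name
#' the offending row and column.
#'
#' @param ds a `morpho_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_morpho_dataset <- function(ds) {
  stopifnot(inherits(ds, "morpho_dataset"))
  n <- length(ds$individuals)
  if (length(ds$populations) != n)
    stop("populations must match the number of individuals")
  if (any(!nzchar(ds$populations)) || anyNA(ds$populations))
    stop("population codes must be non-empty")
  if (nrow(ds$values) != n)
    stop("value table has ", nrow(ds$values), " rows for ", n, " individuals")
  dn <- ds$descriptors$name
  if (!identical(colnames(ds$values), dn))
    stop("value table columns must match descriptor names (same order)")
  for (j in seq_along(dn)) {
    ct <- ds$descriptors$ctype[j]
    v <- ds$values[[j]]
    if (is_qualitative(ct)) {
      lv <- ds$descriptors$levels[[j]]
      obs <- v[!is.na(v)]
      bad <- which(!(v %in% lv) & !is.na(v))
      if (length(bad))
        stop("value '", v[bad[1]], "' in row ", bad[1], " (individual '",
             ds$individuals[bad[1]], "'), column '", dn[j],
             "' is not among declared levels")
    } else {
      if (!is.numeric(v))
        stop("quantitative column '", dn[j], "' is not numeric")
    }
  }
  invisible(ds)
}

#' @export
print.morpho_dataset <- function(x, ...) {
  cat("morpho_dataset:", length(x$individuals), "individuals x",
      nrow(x$descriptors), "characters;",
      length(unique(x$populations)), "populations\n")
  tab <- table(x$descriptors$ctype)
  cat("  character types:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a morphometric value table and its descriptor file
#'
#' The value CSV has columns `individual_id`, `population`, then one column
#' per character. The descriptor CSV has columns `name,ctype,levels,units`
#' with levels pipe-separated in rank order (ordinals). Empty cells become
#' missing values.
#'
#' @param values_path path to the value CSV.
#' @param descriptor_path path to the descriptor CSV.
#' @return A [morpho_dataset].
#' @export
read_morpho_table <- function(values_path, descriptor_path) {
  dtab <- utils::read.csv(descriptor_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("name", "ctype", "levels", "units")
  if (!all(need %in% colnames(dtab)))
    stop("descriptor file must have columns ", paste(need, collapse = ","))
  lv <- lapply(dtab$levels, function(s) {
    if (is.na(s) || !nzchar(s)) NULL else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  desc <- character_descriptors(dtab$name, dtab$ctype, lv, dtab$units)

  vtab <- utils::read.csv(values_path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("individual_id", "population") %in% colnames(vtab)))
    stop("value file must start with columns individual_id,population")
  chars <- setdiff(colnames(vtab), c("individual_id", "population"))
  if (!setequal(chars, desc$name))
    stop("descriptor file must list every value-table column; mismatch: ",
         paste(union(setdiff(chars, desc$name), setdiff(desc$name, chars)),
               collapse = ", "))
  vals <- vtab[, desc$name, drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    v[!nzchar(v)] <- NA
    if (is_quantitative(desc$ctype[j])) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' in row ", bad[1],
             ", quantitative column '", desc$name[j], "'")
      v <- num
    }
    vals[[j]] <- v
  }
  morpho_dataset(vtab$individual_id, vtab$population, desc, vals)
}

#' Write a morphometric dataset to CSV
#'
#' Inverse of [read_morpho_table()]: writes the value table and the
#' descriptor table in the same dialect, so a write/read round trip
#' reproduces the dataset field by field.
#'
#' @param ds a `morpho_dataset`.
#' @param values_path,descriptor_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_morpho_table <- function(ds, values_path, descriptor_path) {
  validate_morpho_dataset(ds)
  dtab <- data.frame(
    name = ds$descriptors$name,
    ctype = ds$descriptors$ctype,
    levels = vapply(ds$descriptors$levels, function(l)
      if (is.null(l)) "" else paste(l, collapse = "|"), character(1)),
    units = ds$descriptors$units,
    stringsAsFactors = FALSE)
  utils::write.csv(dtab, descriptor_path, row.names = FALSE, na = "")
  vtab <- cbind(data.frame(individual_id = ds$individuals,
                           population = ds$populations,
                           stringsAsFactors = FALSE),
                ds$values)
  utils::write.csv(vtab, values_path, row.names = FALSE, na = "")
  invisible(c(values = values_path, descriptors = descriptor_path))
}

#' Grouping hypothesis
#'
#' A named mapping from population code to hypothesised taxon (group) label,
#' e.g. the currently accepted subspecies circumscription or an alternative
#' re-assignment under test.
#'
#' @param name label for the hypothesis.
#' @param mapping named character vector: `names()` are population codes,
#'   values are group labels.
#' @return Object of class `grouping_hypothesis`.
#' @export
grouping_hypothesis <- function(name, mapping) {
  mapping <- vapply(mapping, as.character, character(1))
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("mapping must be a named vector population -> group")
  if (length(unique(mapping)) < 2)
    stop("a grouping hypothesis needs >= 2 distinct groups")
  structure(list(name = as.character(name), mapping = mapping),
            class = "grouping_hypothesis")
}

#' Read a grouping hypothesis from a key=value config file
#'
#' Each non-comment line is `POPULATION = group`. The hypothesis name is the
#' file name without extension unless given.
#'
#' @param path config file path.
#' @param name optional hypothesis label.
#' @return A [grouping_hypothesis].
#' @export
read_grouping <- function(path, name = NULL) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed line in ", path, ": expected 'population = group'")
  m <- vapply(kv, function(x) trimws(x[2]), character(1))
  names(m) <- vapply(kv, function(x) trimws(x[1]), character(1))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grouping_hypothesis(name, m)
}

#' Apply a grouping hypothesis to a dataset
#'
#' @param ds a `morpho_dataset` (or any object with a `populations` field /
#'   a character vector of population codes).
#' @param hyp a [grouping_hypothesis].
#' @return Character vector of group labels, one per individual.
#' @export
group_labels <- function(ds, hyp) {
  pops <- if (inherits(ds, "morpho_dataset")) ds$populations else as.character(ds)
  miss <- setdiff(unique(pops), names(hyp$mapping))
  if (length(miss))
    stop("hypothesis '", hyp$name, "' does not map population(s): ",
         paste(miss, collapse = ", "))
  unname(hyp$mapping[pops])
}

#' Integer-encode qualitative characters
#'
#' Replaces every binary/nominal/ordinal state by its 0-based position in the
#' declared level order; quantitative columns pass through unchanged. The
#' encoding map is returned so the operation is reversible with
#' [decode_qualitative()]. For nominal characters the integer codes are
#' order-arbitrary (the declared order is the convention), which is why the
#' level order must be explicit in the descriptor file.
#'
#' @param ds a `morpho_dataset`.
#' @return List with `x` (numeric matrix, individuals x characters), `map`
#'   (named list of level vectors for the qualitative columns), and the
#'   dataset's `individuals`, `populations` and `descriptors` for decoding.
#' @export
encode_qualitative <- function(ds) {
  validate_morpho_dataset(ds)
  p <- nrow(ds$descriptors)
  x <- matrix(NA_real_, nrow = length(ds$individuals), ncol = p,
              dimnames = list(ds$individuals, ds$descriptors$name))
  map <- list()
  for (j in seq_len(p)) {
    ct <- ds$descriptors$ctype[j]
    v <- ds$values[[j]]
    if (is_qualitative(ct)) {
      lv <- ds$descriptors$levels[[j]]
      if (is.null(lv)) stop("missing levels for qualitative column '",
                            ds$descriptors$name[j], "'")
      x[, j] <- match(v, lv) - 1
      map[[ds$descriptors$name[j]]] <- lv
    } else {
      x[, j] <- v
    }
  }
  list(x = x, map = map, individuals = ds$individuals,
       populations = ds$populations, descriptors = ds$descriptors)
}

#' Decode an integer-encoded dataset back to states
#'
#' @param enc the list returned by [encode_qualitative()].
#' @return A [morpho_dataset] identical to the encoder's input.
#' @export
decode_qualitative <- function(enc) {
  desc <- enc$descriptors
  vals <- as.data.frame(enc$x, stringsAsFactors = FALSE)
  colnames(vals) <- desc$name
  rownames(vals) <- NULL
  for (j in seq_len(nrow(desc))) {
    if (is_qualitative(desc$ctype[j])) {
      lv <- enc$map[[desc$name[j]]]
      vals[[j]] <- lv[vals[[j]] + 1]
    }
  }
  morpho_dataset(enc$individuals, enc$populations, desc, vals)
}

#' Per-group descriptive statistics of quantitative characters
#'
#' @param ds a `morpho_dataset` with at least one quantitative character.
#' @param hyp a [grouping_hypothesis]; if `NULL`, populations are the groups.
#' @return data.frame with columns `group`, `character`, `n` (non-missing),
#'   `mean`, `sd` (sample sd; `NA` when fewer than 2 non-missing values —
#'   undefined, not zero).
#' @export
group_descriptives <- function(ds, hyp = NULL) {
  validate_morpho_dataset(ds)
  qn <- ds$descriptors$name[is_quantitative(ds$descriptors$ctype)]
  if (!length(qn)) stop("no quantitative characters in dataset")
  g <- if (is.null(hyp)) ds$populations else group_labels(ds, hyp)
  out <- expand.grid(group = sort(unique(g)), character = qn,
                     stringsAsFactors = FALSE)
  st <- t(mapply(function(gr, ch) {
    v <- ds$values[[ch]][g == gr]
    v <- v[!is.na(v)]
    c(n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  }, out$group, out$character))
  cbind(out, as.data.frame(st, stringsAsFactors = FALSE), row.names = NULL)
}

#' Confusion matrix constructor
#'
#' Rows are the a-priori groups, columns the predicted groups, in the same
#' label order.
#'
#' @param counts k x k non-negative integer matrix.
#' @param labels optional group labels (defaults to existing dimnames).
#' @return Matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix entries must be non-negative integers")
  if (is.null(labels)) labels <- rownames(counts)
  if (is.null(labels)) labels <- paste0("G", seq_len(nrow(counts)))
  dimnames(counts) <- list(a_priori = labels, predicted = labels)
  class(counts) <- c("confusion_matrix", class(counts))
  counts
}
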