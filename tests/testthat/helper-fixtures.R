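# Shared fixtures built in code.

# Tiny hand-written mixed dataset: 3 individuals, one binary + one
# quantitative character (range 4 across individuals).
tiny_mixed_ds <- function() {
  desc <- character_descriptors(
    name = c("apex", "len"),
    ctype = c("binary", "quantitative_continuous"),
    levels = list(c("acute", "cucullate"), NULL))
  morpho_dataset(c("i1", "i2", "i3"), c("A", "A", "B"), desc,
                 data.frame(apex = c("acute", "cucullate", "acute"),
                            len = c(2, 4, 6)))
}

# Five individuals, single ordinal character with ties, for the Podani
# formula oracle.
ordinal_tie_ds <- function() {
  desc <- character_descriptors(
    "bract", "ordinal",
    list(c("round", "acute", "mucronate", "apiculate")))
  morpho_dataset(paste0("i", 1:5), rep(c("A", "B"), c(3, 2)), desc,
                 data.frame(bract = c("round", "acute", "acute",
                                      "mucronate", "apiculate")))
}

# Independent brute-force Podani ordinal partial dissimilarity for a single
# ordinal character; straight transcription of the tie-corrected rank
# formula, one pair at a time.
podani_oracle <- function(states, levels) {
  code <- match(states, levels)
  r <- rank(code)
  Tc <- vapply(code, function(v) sum(code == v), numeric(1))
  rmax <- max(r); rmin <- min(r)
  Tmax <- sum(code == max(code)); Tmin <- sum(code == min(code))
  den <- (rmax - rmin) - (Tmax - 1) / 2 - (Tmin - 1) / 2
  n <- length(code)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- abs(r[i] - r[j]) - (Tc[i] - 1) / 2 - (Tc[j] - 1) / 2
    d[i, j] <- min(max(num / den, 0), 1)
  }
  d
}

# Printed 4-class jackknife confusion matrix used as a worked example
# (counts of a-priori vs predicted subspecies assignments).
published_confusion <- function() {
  confusion_matrix(
    matrix(c(46, 5, 8, 0,
             2, 105, 1, 2,
             6, 0, 28, 0,
             0, 5, 0, 15), 4, 4, byrow = TRUE),
    c("apennina", "arenaria", "marginata", "praecox"))
}

# Distances among planar points (Euclidean by construction).
planar_distance <- function(pts) {
  dissimilarity_matrix(as.matrix(stats::dist(pts)))
}
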