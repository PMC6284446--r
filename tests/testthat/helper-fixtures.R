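# Shared fixtures and independent oracles for the test suite.

# K2P closed form, written out independently of the package
k2pClosedForm <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# Brute-force single-pass site classifier: explicit per-site case
# analysis, no shared code with countSitePairs()
oracleSiteCounts <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(va) == length(vb))
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  L <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(va)) {
    x <- va[k]; y <- vb[k]
    if (!(x %in% c(purines, pyrimidines)) || !(y %in% c(purines, pyrimidines)))
      next
    L <- L + 1L
    if (x == y) next
    if ((x %in% purines && y %in% purines) ||
        (x %in% pyrimidines && y %in% pyrimidines)) ts <- ts + 1L
    else tv <- tv + 1L
  }
  list(L = L, transitions = ts, transversions = tv)
}

# random aligned sequence over ACGT with optional gap/ambiguity noise
randomSeq <- function(len, gap_prob = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, len, replace = TRUE)
  if (gap_prob > 0) {
    messy <- runif(len) < gap_prob
    s[messy] <- sample(c("-", "N", "R", "Y"), sum(messy), replace = TRUE)
  }
  paste(s, collapse = "")
}

# small two-genus alignment used across stats tests:
# species S1 = {x1, x2}, congener S2 = {y1}, other-genus S3 = {z1}
statsToy <- function() {
  len <- 1000
  base <- strsplit(strrep("ACGT", len / 4), "")[[1]]
  mutate <- function(s, pos, to) { s[pos] <- to; s }
  x1 <- base
  x2 <- mutate(base, 1, "G")                     # 1 transition vs x1
  y1 <- base
  for (p in seq(5, 5 + 4 * 110 - 1, by = 4)) y1[p] <- "G"  # 110 transitions
  z1 <- base
  for (p in seq(2, 2 + 4 * 150 - 1, by = 4)) z1[p] <- "A"  # 150 transversions
  seqs <- vapply(list(x1, x2, y1, z1), paste, "", collapse = "")
  names(seqs) <- c("x1", "x2", "y1", "z1")
  tax <- data.frame(
    specimen_id = names(seqs),
    species = c("Ga one", "Ga one", "Ga two", "Gb one"),
    genus = c("Ga", "Ga", "Ga", "Gb"),
    subfamily = "Sf", stringsAsFactors = FALSE)
  BarcodeAlignment(seqs, tax)
}

toyFiles <- function() {
  c(fasta = system.file("extdata", "toy_alignment.fasta",
                        package = "barcodegap"),
    taxonomy = system.file("extdata", "toy_taxonomy.tsv",
                           package = "barcodegap"))
}

# tiny simulation config for fast pipeline tests
smallSimConfig <- function(seed = 11, ...) {
  simulationConfig(n_subfamilies = 2, genera_per_subfamily = 2,
                   species_per_genus = 3, specimens_per_species = 1:3,
                   specimen_probs = c(0.2, 0.6, 0.2), seq_length = 400,
                   seed = seed, ...)
}
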