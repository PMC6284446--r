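# hand-checkable distance matrix used in several tests: species S1 =
# {a, b}, congener S2 = {c}, built directly as a matrix
gapToyMatrix <- function() {
  ids <- c("a", "b", "c")
  d <- matrix(0, 3, 3, dimnames = list(ids, ids))
  d["a", "b"] <- d["b", "a"] <- 0.002
  d["a", "c"] <- d["c", "a"] <- 0.11
  d["b", "c"] <- d["c", "b"] <- 0.12
  d
}

gapToyTax <- function() data.frame(
  specimen_id = c("a", "b", "c"),
  species = c("S one", "S one", "S two"),
  genus = "S", subfamily = "Sf", stringsAsFactors = FALSE)

test_that("every specimen pair lands in exactly one class", {
  # three specimens: two congeneric species plus one from another genus
  # in the same subfamily
  ids <- c("x", "y", "z")
  d <- matrix(0.1, 3, 3, dimnames = list(ids, ids)); diag(d) <- 0
  tax <- data.frame(specimen_id = ids,
                    species = c("A x", "A y", "B z"),
                    genus = c("A", "A", "B"), subfamily = "Sf")
  pc <- pairClasses(d, tax)
  expect_equal(as.character(pc$class[pc$id1 == "x" & pc$id2 == "y"]),
               "congeneric")
  expect_equal(sum(pc$class == "congeneric"), 1)
  expect_equal(sum(pc$class == "within_subfamily"), 2)
  expect_equal(sum(pc$class == "intraspecific"), 0)

  # same species pair
  tax2 <- tax; tax2$species <- c("A x", "A x", "B z")
  pc2 <- pairClasses(d, tax2)
  expect_equal(sum(pc2$class == "intraspecific"), 1)

  # cross-subfamily pairs fall in no within-subfamily class
  tax3 <- tax; tax3$subfamily <- c("Sf1", "Sf1", "Sf2")
  pc3 <- pairClasses(d, tax3)
  expect_equal(sum(pc3$class == "other"), 2)
})

test_that("pair classes partition all C(n,2) pairs (random datasets)", {
  set.seed(31)
  for (r in 1:10) {
    sim <- simulateBarcodes(smallSimConfig(seed = r))
    ba <- sim$alignment
    n <- length(ba)
    d <- matrix(0, n, n, dimnames = list(specimenIds(ba), specimenIds(ba)))
    pc <- pairClasses(d, ba)
    expect_equal(nrow(pc), choose(n, 2))
    expect_equal(sum(table(pc$class)), choose(n, 2))
  }
})

test_that("per-species maxima and minima follow the strict definitions", {
  rows <- speciesGapTable(gapToyMatrix(), gapToyTax(), criterion = NULL)
  s1 <- rows[rows$species == "S one", ]
  s2 <- rows[rows$species == "S two", ]
  expect_equal(s1$max_intra, 0.002)
  expect_equal(s1$min_inter_congeneric, 0.11)
  expect_true(is.na(s2$max_intra))          # single specimen
  expect_equal(s2$min_inter_congeneric, 0.11)

  # a genus with a single sampled species has no congeneric distance
  tax <- gapToyTax(); tax$genus <- c("S", "S", "T")
  rows2 <- speciesGapTable(gapToyMatrix(), tax, criterion = NULL)
  expect_true(all(is.na(rows2$min_inter_congeneric)))
})

test_that("the gap report averages defined values and uses unrounded means", {
  rows <- data.frame(species = c("s1", "s2", "s3"),
                     max_intra = c(0.002, 0.004, NA),
                     min_inter_congeneric = c(0.11, 0.13, NA))
  rep <- barcodingGapReport(rows)
  expect_equal(rep$avg_max_intra_pct, 0.3)
  expect_equal(rep$avg_min_inter_congeneric_pct, 12.0)
  expect_equal(rep$gap_ratio, 0.12 / 0.003)
  expect_equal(round(rep$gap_ratio), 40)
  expect_true(rep$gap_criterion_met)
  expect_equal(rep$n_species_intra, 2)
  expect_equal(rep$n_species_inter, 2)

  # all-zero intraspecific averages flag an infinite gap
  rows0 <- data.frame(species = "s", max_intra = 0,
                      min_inter_congeneric = 0.1)
  rep0 <- barcodingGapReport(rows0)
  expect_true(rep0$infinite_gap)
  expect_true(is.na(rep0$gap_ratio))
  expect_true(rep0$gap_criterion_met)
})

test_that("average min congeneric distance matches a brute-force double loop", {
  set.seed(67)
  for (r in 1:5) {
    sim <- simulateBarcodes(smallSimConfig(seed = 100 + r))
    ba <- sim$alignment
    d <- k2pDistanceMatrix(ba)
    tax <- taxonomyTable(ba)
    rows <- speciesGapTable(d, ba, criterion = NULL)
    # oracle: all congeneric heterospecific pairs, minimum per species
    oracle <- vapply(unique(tax$species), function(s) {
      g <- tax$genus[tax$species == s][1]
      best <- Inf
      for (i in seq_len(nrow(tax))) for (j in seq_len(nrow(tax))) {
        if (tax$species[i] == s && tax$species[j] != s &&
            tax$genus[j] == g && !is.na(d[i, j]))
          best <- min(best, d[i, j])
      }
      if (is.finite(best)) best else NA_real_
    }, 0)
    expect_equal(rows$min_inter_congeneric,
                 unname(oracle[rows$species]))
    expect_equal(barcodingGapReport(rows)$avg_min_inter_congeneric_pct,
                 100 * mean(oracle, na.rm = TRUE))
  }
})

test_that("adding a specimen cannot raise min_inter or lower max_intra", {
  set.seed(29)
  for (r in 1:5) {
    sim <- simulateBarcodes(smallSimConfig(seed = 200 + r))
    ba <- sim$alignment
    d <- k2pDistanceMatrix(ba)
    rows_full <- speciesGapTable(d, ba, criterion = NULL)
    drop <- sample(length(ba), 1)
    keep <- setdiff(seq_len(length(ba)), drop)
    rows_sub <- speciesGapTable(d[keep, keep], ba[keep], criterion = NULL)
    common <- intersect(rows_full$species, rows_sub$species)
    for (s in common) {
      mi_full <- rows_full$max_intra[rows_full$species == s]
      mi_sub <- rows_sub$max_intra[rows_sub$species == s]
      if (!is.na(mi_full) && !is.na(mi_sub)) expect_gte(mi_full, mi_sub)
      ii_full <- rows_full$min_inter_congeneric[rows_full$species == s]
      ii_sub <- rows_sub$min_inter_congeneric[rows_sub$species == s]
      if (!is.na(ii_full) && !is.na(ii_sub)) expect_lte(ii_full, ii_sub)
    }
  }
})

test_that("level summaries report mean/range per class and per subfamily", {
  ls <- levelSummaries(gapToyMatrix(), gapToyTax())
  intra <- ls[ls$level == "intraspecific" & ls$group == "overall", ]
  expect_equal(intra$mean_pct, 0.2)
  expect_equal(intra$n_pairs, 1)
  cong <- ls[ls$level == "interspecific_congeneric" & ls$group == "overall", ]
  expect_equal(cong$mean_pct, 11.5)
  expect_equal(cong$min_pct, 11)
  expect_equal(cong$max_pct, 12)
  expect_equal(cong$n_pairs, 2)
  # the within-subfamily interspecific class is a superset of congeneric
  sf <- ls[ls$level == "interspecific_within_subfamily" & ls$group == "Sf", ]
  expect_equal(sf$n_pairs, 2)
  expect_true(all(ls$min_pct <= ls$mean_pct & ls$mean_pct <= ls$max_pct,
                  na.rm = TRUE))

  # single species: no interspecific pairs at all
  tax1 <- gapToyTax(); tax1$species <- "S one"
  ls1 <- levelSummaries(gapToyMatrix(), tax1)
  cong1 <- ls1[ls1$level == "interspecific_congeneric", ]
  expect_equal(cong1$n_pairs, 0)
  expect_true(is.na(cong1$mean_pct))
})

test_that("subset statistics pool pairs within and between listed species", {
  st <- subsetStats(gapToyMatrix(), gapToyTax(), c("S one", "S two"))
  expect_equal(st$mean_inter_pct, 11.5)
  expect_equal(st$mean_intra_pct, 0.2)
  st1 <- subsetStats(gapToyMatrix(), gapToyTax(), "S two")
  expect_true(is.na(st1$mean_inter_pct))
  expect_error(subsetStats(gapToyMatrix(), gapToyTax(), "missing sp"),
               "missing sp")
})

test_that("species sharing a haplotype always fail discrimination", {
  seqs <- c(p1 = "ACGTACGTAC", p2 = "ACGTACGTAC",
            q1 = "ACGTACGTAC", q2 = "ACGAACTTAC")
  tax <- data.frame(specimen_id = names(seqs),
                    species = c("G p", "G p", "G q", "G q"),
                    genus = "G", subfamily = "Sf")
  d <- k2pDistanceMatrix(seqs)
  for (crit in c("both", "nearest-neighbor", "local-gap")) {
    disc <- assessDiscrimination(d, tax, criterion = crit)
    expect_false(any(disc$discriminated), info = crit)
    expect_equal(disc$failure_partners[disc$species == "G p"], "G q")
    expect_equal(disc$failure_partners[disc$species == "G q"], "G p")
  }
})

test_that("well separated species pass under both criteria", {
  for (crit in c("both", "nearest-neighbor", "local-gap")) {
    disc <- assessDiscrimination(gapToyMatrix(), gapToyTax(),
                                 criterion = crit)
    expect_true(all(disc$discriminated), info = crit)
    expect_equal(disc$failure_partners, c("", ""))
  }
  expect_error(assessDiscrimination(gapToyMatrix(), gapToyTax(),
                                    criterion = "bogus"))
})

test_that("nearest-neighbor and local-gap criteria differ where they should", {
  # species X straggles (max_intra 0.10) across the distance to the
  # heterospecific y1 (0.05), yet every X specimen is still closest to a
  # conspecific: nearest-neighbor passes, local-gap fails, "both" fails
  ids <- c("x1", "x2", "x3", "y1")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["x1", "x2"] <- 0.02; d["x1", "x3"] <- 0.10; d["x2", "x3"] <- 0.09
  d["x1", "y1"] <- 0.05; d["x2", "y1"] <- 0.06; d["x3", "y1"] <- 0.095
  d <- d + t(d)
  tax <- data.frame(specimen_id = ids,
                    species = c("G x", "G x", "G x", "G y"),
                    genus = "G", subfamily = "Sf")
  nn <- assessDiscrimination(d, tax, criterion = "nearest-neighbor")
  expect_true(nn$discriminated[nn$species == "G x"])
  gap <- assessDiscrimination(d, tax, criterion = "local-gap")
  expect_false(gap$discriminated[gap$species == "G x"])
  expect_equal(gap$failure_partners[gap$species == "G x"], "G y")
  both <- assessDiscrimination(d, tax, criterion = "both")
  expect_false(both$discriminated[both$species == "G x"])

  # singleton species: fails only on a zero-distance heterospecific
  ids2 <- c("s1", "t1")
  d2 <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(ids2, ids2))
  tax2 <- data.frame(specimen_id = ids2, species = c("G s", "G t"),
                     genus = "G", subfamily = "Sf")
  disc2 <- assessDiscrimination(d2, tax2)
  expect_true(all(disc2$discriminated))
  d2["s1", "t1"] <- d2["t1", "s1"] <- 0
  disc0 <- assessDiscrimination(d2, tax2)
  expect_false(any(disc0$discriminated))
})
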