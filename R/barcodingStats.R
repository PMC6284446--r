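## Barcoding-gap statistics.
##
## The headline statistic follows the strict "minimal" convention: for
## every species the MAXIMUM intraspecific distance, for every species
## the MINIMUM distance to a congeneric heterospecific specimen; the gap
## is the ratio of the averages of the two (interspecific over
## intraspecific). A ratio of at least 10 is the conventional evidence
## for a usable barcoding gap.

.alignTaxonomy <- function(d, tax) {
  if (is(tax, "BarcodeAlignment")) tax <- taxonomyTable(tax)
  idx <- match(rownames(d), tax$specimen_id)
  if (anyNA(idx))
    stop("specimens missing from taxonomy: ",
         paste(rownames(d)[is.na(idx)], collapse = ", "))
  tax[idx, , drop = FALSE]
}

#' Classify every specimen pair by taxonomic relationship
#'
#' Each unordered pair is assigned its most specific class:
#' `intraspecific` (same species), `congeneric` (same genus, different
#' species), `within_subfamily` (same subfamily, different genus) or
#' `other` (different subfamilies). The three within-subfamily
#' interspecific classes used in summaries are built from these:
#' "interspecific within subfamily" is the union of `congeneric` and
#' `within_subfamily`.
#'
#' @param d A distance matrix from [k2pDistanceMatrix()].
#' @param tax A taxonomy `data.frame` or [BarcodeAlignment-class].
#' @return A `data.frame` with columns `id1`, `id2`, `distance` (NA when
#'   undefined), `class` (factor), `species1`, `species2`, `genus`,
#'   `subfamily` (taxon of the pair where shared, else NA).
#' @export
pairClasses <- function(d, tax) {
  tax <- .alignTaxonomy(d, tax)
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  sp <- tax$species; gen <- tax$genus; sf <- tax$subfamily
  cls <- ifelse(sp[i] == sp[j], "intraspecific",
         ifelse(gen[i] == gen[j], "congeneric",
         ifelse(sf[i] == sf[j], "within_subfamily", "other")))
  data.frame(
    id1 = rownames(d)[i], id2 = rownames(d)[j],
    distance = d[ut],
    class = factor(cls, levels = c("intraspecific", "congeneric",
                                   "within_subfamily", "other")),
    species1 = sp[i], species2 = sp[j],
    genus = ifelse(gen[i] == gen[j], gen[i], NA_character_),
    subfamily = ifelse(sf[i] == sf[j], sf[i], NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Per-species gap statistics
#'
#' For every species: the number of specimens, the maximum intraspecific
#' distance (defined only with >= 2 specimens), the minimum distance to a
#' congeneric heterospecific specimen (defined only when the genus holds
#' >= 2 sampled species), and — when `criterion` is not `NULL` — the
#' discrimination verdict from [assessDiscrimination()].
#'
#' Undefined distance entries are skipped; if a species' statistic has no
#' defined pair at all it is reported as `NA` and excluded from the
#' averages downstream.
#'
#' @inheritParams pairClasses
#' @param criterion Discrimination criterion passed to
#'   [assessDiscrimination()], or `NULL` to skip that column.
#' @return A `data.frame` with one row per species: `species`, `genus`,
#'   `subfamily`, `n_specimens`, `max_intra`, `min_inter_congeneric`
#'   (substitutions/site), and optionally `discriminated`,
#'   `failure_partners`.
#' @export
speciesGapTable <- function(d, tax, criterion = "both") {
  tax <- .alignTaxonomy(d, tax)
  species <- unique(tax$species)
  rows <- lapply(species, function(s) {
    idx <- which(tax$species == s)
    genus <- tax$genus[idx[1]]
    max_intra <- NA_real_
    if (length(idx) >= 2) {
      dd <- d[idx, idx][upper.tri(d[idx, idx])]
      if (any(!is.na(dd))) max_intra <- max(dd, na.rm = TRUE)
    }
    cong <- which(tax$genus == genus & tax$species != s)
    min_inter <- NA_real_
    if (length(cong) >= 1) {
      dd <- d[idx, cong, drop = FALSE]
      if (any(!is.na(dd))) min_inter <- min(dd, na.rm = TRUE)
    }
    data.frame(species = s, genus = genus, subfamily = tax$subfamily[idx[1]],
               n_specimens = length(idx), max_intra = max_intra,
               min_inter_congeneric = min_inter, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(criterion)) {
    disc <- assessDiscrimination(d, tax, criterion = criterion)
    out$discriminated <- disc$discriminated[match(out$species, disc$species)]
    out$failure_partners <-
      disc$failure_partners[match(out$species, disc$species)]
  }
  out
}

#' The barcoding-gap report
#'
#' Averages the per-species maxima and minima of [speciesGapTable()]
#' (over species where they are defined) and forms the gap ratio
#' `avg_min_inter_congeneric / avg_max_intra` from the unrounded means.
#' The conventional criterion for a usable gap — interspecific average at
#' least 10 times the intraspecific average — is evaluated alongside.
#'
#' @param gap_table Output of [speciesGapTable()], or a distance matrix
#'   (in which case `tax` must be supplied and the table is computed).
#' @inheritParams pairClasses
#' @return An object of class `gap_report`: a list with
#'   `avg_max_intra_pct`, `avg_min_inter_congeneric_pct` (percent),
#'   `gap_ratio`, `n_species_intra`, `n_species_inter`,
#'   `gap_criterion_met` (ratio >= 10) and `infinite_gap` (TRUE when the
#'   intraspecific average is exactly zero, leaving the ratio undefined).
#' @export
barcodingGapReport <- function(gap_table, tax = NULL) {
  if (is.matrix(gap_table)) {
    stopifnot(!is.null(tax))
    gap_table <- speciesGapTable(gap_table, tax, criterion = NULL)
  }
  mi <- gap_table$max_intra[!is.na(gap_table$max_intra)]
  ii <- gap_table$min_inter_congeneric[!is.na(gap_table$min_inter_congeneric)]
  avg_intra <- if (length(mi)) mean(mi) else NA_real_
  avg_inter <- if (length(ii)) mean(ii) else NA_real_
  infinite_gap <- isTRUE(avg_intra == 0)
  ratio <- if (infinite_gap || is.na(avg_intra) || is.na(avg_inter))
    NA_real_ else avg_inter / avg_intra
  structure(list(
    avg_max_intra_pct = 100 * avg_intra,
    avg_min_inter_congeneric_pct = 100 * avg_inter,
    gap_ratio = ratio,
    n_species_intra = length(mi),
    n_species_inter = length(ii),
    gap_criterion_met = isTRUE(infinite_gap) || isTRUE(ratio >= 10),
    infinite_gap = infinite_gap
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Barcoding gap report\n")
  cat(sprintf("  avg max intraspecific distance:        %.1f%%  (%d species)\n",
              x$avg_max_intra_pct, x$n_species_intra))
  cat(sprintf("  avg min congeneric interspecific dist: %.1f%%  (%d species)\n",
              x$avg_min_inter_congeneric_pct, x$n_species_inter))
  if (x$infinite_gap) cat("  gap ratio: infinite (intraspecific average is 0)\n")
  else cat(sprintf("  gap ratio: %.1f (about %d times)  [>= 10: %s]\n",
                   x$gap_ratio, round(x$gap_ratio),
                   if (x$gap_criterion_met) "yes" else "no"))
  invisible(x)
}

#' Write a gap report as JSON
#'
#' Full-precision values plus paper-style rounded display strings, so
#' that rounding never compounds downstream.
#'
#' @param report A `gap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGapReport <- function(report, path) {
  out <- unclass(report)
  out$display <- list(
    avg_max_intra = sprintf("%.1f%%", report$avg_max_intra_pct),
    avg_min_inter_congeneric = sprintf("%.1f%%",
                                       report$avg_min_inter_congeneric_pct),
    gap_ratio = if (report$infinite_gap) "Inf"
                else sprintf("about %d times", round(report$gap_ratio))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.classSummary <- function(dd, level, group) {
  dd <- dd[!is.na(dd)]
  n <- length(dd)
  data.frame(level = level, group = group,
             mean_pct = if (n) 100 * mean(dd) else NA_real_,
             min_pct = if (n) 100 * min(dd) else NA_real_,
             max_pct = if (n) 100 * max(dd) else NA_real_,
             n_pairs = n, stringsAsFactors = FALSE)
}

#' Distance summaries at each taxonomic level
#'
#' Mean, minimum and maximum K2P distance (percent) over all pairs in
#' each class: intraspecific, interspecific among congeners, and
#' interspecific within subfamily (which includes the congeneric pairs —
#' that class is a superset). The within-subfamily class is additionally
#' broken down per subfamily.
#'
#' @inheritParams pairClasses
#' @return A `data.frame` of `LevelSummary` rows: `level`, `group`
#'   (taxon name or `"overall"`), `mean_pct`, `min_pct`, `max_pct`,
#'   `n_pairs`. Empty classes get `n_pairs = 0` and `NA` statistics.
#' @export
levelSummaries <- function(d, tax) {
  pc <- pairClasses(d, tax)
  intra <- pc$distance[pc$class == "intraspecific"]
  cong <- pc$distance[pc$class == "congeneric"]
  insf <- pc$class %in% c("congeneric", "within_subfamily")
  out <- rbind(
    .classSummary(intra, "intraspecific", "overall"),
    .classSummary(cong, "interspecific_congeneric", "overall"),
    .classSummary(pc$distance[insf], "interspecific_within_subfamily",
                  "overall")
  )
  for (sf in sort(unique(pc$subfamily[insf]))) {
    out <- rbind(out, .classSummary(
      pc$distance[insf & !is.na(pc$subfamily) & pc$subfamily == sf],
      "interspecific_within_subfamily", sf))
  }
  rownames(out) <- NULL
  out
}

#' Pooled distance means for a subset of species
#'
#' Mean intraspecific distance over all conspecific pairs within the
#' listed species, and mean interspecific distance over all pairs
#' between different listed species — the comparison used to
#' characterise a cluster of problem species against the rest of its
#' genus.
#'
#' @inheritParams pairClasses
#' @param species Character vector of species names (>= 1, all present).
#' @return A list with `mean_intra_pct` and `mean_inter_pct` (percent;
#'   `NA` when the corresponding pair set is empty, e.g. a single
#'   species has no interspecific pairs).
#' @export
subsetStats <- function(d, tax, species) {
  tax <- .alignTaxonomy(d, tax)
  if (!length(species)) stop("species list is empty")
  absent <- setdiff(species, tax$species)
  if (length(absent))
    stop("species not in dataset: ", paste(absent, collapse = ", "))
  pc <- pairClasses(d, tax)
  both <- pc$species1 %in% species & pc$species2 %in% species
  intra <- pc$distance[both & pc$class == "intraspecific"]
  inter <- pc$distance[both & pc$class != "intraspecific"]
  mn <- function(v) { v <- v[!is.na(v)]; if (length(v)) 100 * mean(v) else NA_real_ }
  list(mean_intra_pct = mn(intra), mean_inter_pct = mn(inter))
}

#' Per-species discrimination assessment
#'
#' Flags the species a COI barcode cannot reliably separate, under two
#' criteria that can be combined:
#' \describe{
#'   \item{`nearest-neighbor`}{a species fails if any of its specimens
#'     has a heterospecific specimen at a distance less than or equal to
#'     its nearest conspecific; a single-specimen species fails only if
#'     some heterospecific specimen sits at distance 0.}
#'   \item{`local-gap`}{a species fails if its maximum intraspecific
#'     distance is greater than or equal to its minimum distance to any
#'     heterospecific specimen; for single-specimen species the verdict
#'     is based on the zero-distance rule alone.}
#'   \item{`both`}{(default) a species is discriminated only if it passes
#'     both criteria.}
#' }
#' Heterospecific specimens at distance 0 (shared haplotypes) always fail
#' a species regardless of criterion. Undefined distances are ignored.
#'
#' @inheritParams pairClasses
#' @param criterion One of `"both"`, `"nearest-neighbor"`, `"local-gap"`.
#' @return A `data.frame` with `species`, `n_specimens`, `discriminated`
#'   (logical; `NA` when not assessable, i.e. no defined heterospecific
#'   comparison exists), `failure_partners` (comma-separated species
#'   sharing or overlapping barcodes; empty string when none).
#' @export
assessDiscrimination <- function(d, tax,
                                 criterion = c("both", "nearest-neighbor",
                                               "local-gap")) {
  criterion <- match.arg(criterion)
  tax <- .alignTaxonomy(d, tax)
  species <- unique(tax$species)
  rows <- lapply(species, function(s) {
    idx <- which(tax$species == s)
    het <- which(tax$species != s)
    partners <- character(0)
    if (!length(het) || all(is.na(d[idx, het])))
      return(data.frame(species = s, n_specimens = length(idx),
                        discriminated = NA, failure_partners = "",
                        stringsAsFactors = FALSE))
    dhet <- d[idx, het, drop = FALSE]
    # shared haplotypes: automatic failure under every criterion
    zero <- which(dhet == 0, arr.ind = TRUE)
    if (nrow(zero)) partners <- tax$species[het[zero[, 2]]]
    fail_zero <- nrow(zero) > 0
    fail_nn <- FALSE
    fail_gap <- FALSE
    if (length(idx) >= 2) {
      dintra <- d[idx, idx, drop = FALSE]
      diag(dintra) <- NA
      if (criterion %in% c("both", "nearest-neighbor")) {
        for (k in seq_along(idx)) {
          nearest_con <- suppressWarnings(min(dintra[k, ], na.rm = TRUE))
          offending <- which(dhet[k, ] <= nearest_con)
          if (length(offending)) {
            fail_nn <- TRUE
            partners <- c(partners, tax$species[het[offending]])
          }
        }
      }
      if (criterion %in% c("both", "local-gap")) {
        max_intra <- suppressWarnings(max(dintra, na.rm = TRUE))
        if (is.finite(max_intra)) {
          offending <- which(apply(dhet, 2, function(col)
            any(col <= max_intra, na.rm = TRUE)))
          if (length(offending)) {
            fail_gap <- TRUE
            partners <- c(partners, tax$species[het[offending]])
          }
        }
      }
    }
    fails <- switch(criterion,
      "nearest-neighbor" = fail_zero || fail_nn,
      "local-gap" = fail_zero || fail_gap,
      "both" = fail_zero || fail_nn || fail_gap)
    data.frame(species = s, n_specimens = length(idx),
               discriminated = !fails,
               failure_partners = paste(sort(unique(partners)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
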