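## Synthetic barcode datasets under the Kimura 2-parameter substitution
## process. Specimens hang from a four-level taxonomy tree
## (root -> subfamily -> genus -> species -> specimen); every configured
## divergence is an expected K2P distance between two nodes of the same
## level and is split equally across the two connecting branches, so the
## K2P estimate between two simulated sequences is an estimate of their
## path length. Sites evolve independently and homogeneously from a
## uniform-base root sequence — exactly the regime in which the K2P
## estimator is consistent, which is what makes parameter recovery a
## clean test of the pipeline.

#' K2P transition-probability matrix
#'
#' Closed-form 4x4 matrix of substitution probabilities after a branch
#' of `t` expected substitutions per site, with transition/transversion
#' rate ratio `kappa`. Rates are scaled so the total substitution rate
#' per site is 1 per unit branch length; the stationary distribution is
#' uniform. Row/column order is A, C, G, T.
#'
#' @param t Branch length in expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0), i.e. alpha /
#'   beta for transition rate alpha and per-target transversion rate
#'   beta.
#' @return A 4x4 row-stochastic matrix.
#' @export
k2pProbMatrix <- function(t, kappa = 2) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (t < 0) stop("branch length must be >= 0")
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  bases <- c("A", "C", "G", "T")
  P <- matrix(p_tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- p_ts
  P
}

# sequences are integer vectors over 1:4 = A,C,G,T during simulation
.evolveInt <- function(parent, t, kappa) {
  if (t == 0) return(parent)
  P <- k2pProbMatrix(t, kappa)
  child <- integer(length(parent))
  for (b in 1:4) {
    idx <- which(parent == b)
    if (length(idx))
      child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
  }
  child
}

#' Evolve a sequence along a branch under the K2P process
#'
#' Each site is substituted independently according to the exact
#' transition probabilities of [k2pProbMatrix()] at time `t =
#' branch_length`.
#'
#' @param parent A character scalar / `DNAString` over A,C,G,T, or an
#'   integer vector over 1:4.
#' @param branch_length Expected substitutions per site.
#' @param kappa Transition/transversion rate ratio.
#' @return A child sequence of the same type and length as `parent`.
#' @export
evolveSequence <- function(parent, branch_length, kappa = 2) {
  if (is.integer(parent)) return(.evolveInt(parent, branch_length, kappa))
  bases <- c("A", "C", "G", "T")
  v <- match(strsplit(toupper(as.character(parent)), "")[[1]], bases)
  if (anyNA(v)) stop("parent sequence must contain only A, C, G, T")
  paste(bases[.evolveInt(v, branch_length, kappa)], collapse = "")
}

#' Simulation configuration
#'
#' Defaults emulate a regional COI barcode survey of a diverse insect
#' family: 7 subfamilies, around 120 species sampled at about 2.2
#' specimens per species, conspecific specimens roughly 0.2% divergent,
#' congeneric species around 11% and genera within a subfamily around
#' 19% divergent. `lumped_trio` adds the classic failure mode: three
#' congeneric species sharing a haplotype (with extra specimens
#' scattered around it at `lumped_spread`), so that barcodes cannot
#' separate them.
#'
#' @param n_subfamilies Number of subfamilies.
#' @param genera_per_subfamily Single count or `c(lo, hi)` range sampled
#'   uniformly per subfamily.
#' @param species_per_genus Single count or `c(lo, hi)` range.
#' @param specimens_per_species Vector of possible specimen counts per
#'   species, sampled with `specimen_probs` (defaults give a mean of
#'   2.2).
#' @param specimen_probs Sampling probabilities for
#'   `specimens_per_species`.
#' @param seq_length Alignment length in sites (>= 100; default 658, the
#'   standard COI barcode fragment).
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process.
#' @param intra_divergence Expected K2P distance between conspecific
#'   specimens (substitutions/site).
#' @param congener_divergence Expected K2P distance between congeneric
#'   species ancestors.
#' @param subfamily_divergence Expected K2P distance between genus
#'   ancestors of the same subfamily.
#' @param cross_subfamily_divergence Expected K2P distance between
#'   subfamily ancestors.
#' @param lumped_trio Logical; plant three haplotype-sharing congeneric
#'   species in the largest genus.
#' @param lumped_spread Expected K2P distance among the non-shared
#'   specimens of the lumped trio (their elevated "intraspecific"
#'   spread).
#' @param seed Integer seed; the same configuration and seed always
#'   reproduce the identical dataset.
#' @return A validated list of class `sim_config`.
#' @export
simulationConfig <- function(n_subfamilies = 7,
                             genera_per_subfamily = c(2, 6),
                             species_per_genus = c(2, 7),
                             specimens_per_species = 1:4,
                             specimen_probs = c(0.25, 0.45, 0.15, 0.15),
                             seq_length = 658,
                             kappa = 2,
                             intra_divergence = 0.002,
                             congener_divergence = 0.11,
                             subfamily_divergence = 0.19,
                             cross_subfamily_divergence = 0.25,
                             lumped_trio = FALSE,
                             lumped_spread = 0.016,
                             seed = 1) {
  cfg <- list(n_subfamilies = n_subfamilies,
              genera_per_subfamily = genera_per_subfamily,
              species_per_genus = species_per_genus,
              specimens_per_species = specimens_per_species,
              specimen_probs = specimen_probs,
              seq_length = seq_length, kappa = kappa,
              intra_divergence = intra_divergence,
              congener_divergence = congener_divergence,
              subfamily_divergence = subfamily_divergence,
              cross_subfamily_divergence = cross_subfamily_divergence,
              lumped_trio = lumped_trio, lumped_spread = lumped_spread,
              seed = as.integer(seed))
  counts <- c(cfg$n_subfamilies, cfg$genera_per_subfamily,
              cfg$species_per_genus, cfg$specimens_per_species)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$seq_length < 100) stop("seq_length must be >= 100")
  if (cfg$kappa <= 0) stop("kappa must be > 0")
  if (!(cfg$intra_divergence < cfg$congener_divergence &&
        cfg$congener_divergence < cfg$subfamily_divergence))
    stop("divergences must satisfy intra < congener < subfamily")
  if (length(cfg$specimen_probs) != length(cfg$specimens_per_species) ||
      any(cfg$specimen_probs < 0) || sum(cfg$specimen_probs) <= 0)
    stop("specimen_probs must be nonnegative and match specimens_per_species")
  if (cfg$lumped_trio && max(cfg$species_per_genus) < 3)
    stop("lumped_trio requires a genus with at least 3 species")
  class(cfg) <- "sim_config"
  cfg
}

.drawCount <- function(spec) {
  if (length(spec) == 1) return(as.integer(spec))
  if (length(spec) == 2) return(sample(seq(spec[1], spec[2]), 1L))
  stop("count specification must be a single value or c(lo, hi)")
}

#' Simulate a taxonomy-structured barcode dataset
#'
#' Grows the taxonomy tree described by `cfg`, evolves sequences along
#' it under the K2P process, and returns the dataset together with a
#' record of the generating truth. With `lumped_trio = TRUE` the three
#' lumped species each contribute one exact copy of a shared haplotype
#' plus any further specimens at `lumped_spread` around it.
#'
#' @param cfg A [simulationConfig()] object (or arguments to build one,
#'   passed via `...`).
#' @param ... Convenience: configuration fields forwarded to
#'   [simulationConfig()] when `cfg` is missing.
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{`alignment`}{a [BarcodeAlignment-class];}
#'     \item{`truth`}{the configuration plus the generating quantities:
#'       per-level true divergences, the names of the lumped species (if
#'       any), the true per-species maximum intraspecific and minimum
#'       congeneric interspecific path lengths, and the true gap ratio
#'       these imply.}
#'   }
#' @examples
#' sim <- simulateBarcodes(simulationConfig(n_subfamilies = 1,
#'   genera_per_subfamily = 2, species_per_genus = 2,
#'   specimens_per_species = 2, specimen_probs = 1, seed = 7))
#' sim$alignment
#' @export
simulateBarcodes <- function(cfg = simulationConfig(...), ...) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  root <- sample.int(4L, cfg$seq_length, replace = TRUE)
  ids <- character(0); sps <- character(0); gens <- character(0)
  sfs <- character(0)
  seqs <- list()
  # true path lengths bookkeeping, per species
  sp_names <- character(0); sp_true_intra <- numeric(0)
  sp_true_inter <- numeric(0); sp_genus <- character(0)
  lumped_species <- character(0)
  genus_sizes <- list()
  plan <- list()
  for (s in seq_len(cfg$n_subfamilies)) {
    ngen <- .drawCount(cfg$genera_per_subfamily)
    plan[[s]] <- lapply(seq_len(ngen), function(g) {
      nsp <- .drawCount(cfg$species_per_genus)
      vapply(seq_len(nsp), function(x) {
        if (length(cfg$specimens_per_species) == 1L)
          as.integer(cfg$specimens_per_species)
        else sample(cfg$specimens_per_species, 1L,
                    prob = cfg$specimen_probs)
      }, 1L)
    })
  }
  # place the lumped trio in the genus with most species
  trio_loc <- NULL
  if (cfg$lumped_trio) {
    sizes <- do.call(rbind, lapply(seq_along(plan), function(s)
      data.frame(s = s, g = seq_along(plan[[s]]),
                 nsp = vapply(plan[[s]], length, 1L))))
    sizes <- sizes[sizes$nsp >= 3, , drop = FALSE]
    if (!nrow(sizes))
      stop("no genus with >= 3 species was drawn; cannot place lumped trio")
    trio_loc <- sizes[which.max(sizes$nsp), c("s", "g")]
  }
  gcount <- 0L; spcount <- 0L
  for (s in seq_along(plan)) {
    sf_name <- sprintf("Subfam%02d", s)
    sf_anc <- .evolveInt(root, cfg$cross_subfamily_divergence / 2, cfg$kappa)
    for (g in seq_along(plan[[s]])) {
      gcount <- gcount + 1L
      g_name <- sprintf("Genus%03d", gcount)
      g_anc <- .evolveInt(sf_anc, cfg$subfamily_divergence / 2, cfg$kappa)
      nspec_per_sp <- plan[[s]][[g]]
      is_trio_genus <- !is.null(trio_loc) && trio_loc$s == s && trio_loc$g == g
      trio_anc <- if (is_trio_genus)
        .evolveInt(g_anc, cfg$congener_divergence / 2, cfg$kappa)
      for (sp in seq_along(nspec_per_sp)) {
        spcount <- spcount + 1L
        sp_name <- sprintf("%s sp%03d", g_name, spcount)
        in_trio <- is_trio_genus && sp <= 3L
        sp_anc <- if (in_trio) trio_anc
                  else .evolveInt(g_anc, cfg$congener_divergence / 2,
                                  cfg$kappa)
        if (in_trio) lumped_species <- c(lumped_species, sp_name)
        nind <- nspec_per_sp[sp]
        for (ind in seq_len(nind)) {
          ids <- c(ids, sprintf("%s_%02d", gsub(" ", "_", sp_name), ind))
          sps <- c(sps, sp_name); gens <- c(gens, g_name)
          sfs <- c(sfs, sf_name)
          br <- if (in_trio) {
            if (ind == 1L) 0 else cfg$lumped_spread / 2
          } else cfg$intra_divergence / 2
          seqs[[length(seqs) + 1L]] <- .evolveInt(sp_anc, br, cfg$kappa)
        }
        # true (path-length) statistics for this species
        sp_names <- c(sp_names, sp_name); sp_genus <- c(sp_genus, g_name)
        true_intra <- if (nind >= 2) {
          if (in_trio) {
            if (nind == 2) cfg$lumped_spread / 2 else cfg$lumped_spread
          } else cfg$intra_divergence
        } else NA_real_
        sp_true_intra <- c(sp_true_intra, true_intra)
      }
      genus_sizes[[g_name]] <- length(nspec_per_sp)
    }
  }
  # true minimum congeneric interspecific path length per species
  for (i in seq_along(sp_names)) {
    gsp <- sp_names[sp_genus == sp_genus[i] & sp_names != sp_names[i]]
    sp_true_inter[i] <- if (!length(gsp)) NA_real_
    else if (sp_names[i] %in% lumped_species &&
             any(gsp %in% lumped_species)) 0
    else cfg$congener_divergence + cfg$intra_divergence
  }
  bases <- c("A", "C", "G", "T")
  dna <- Biostrings::DNAStringSet(vapply(seqs, function(v)
    paste(bases[v], collapse = ""), ""))
  names(dna) <- ids
  tax <- data.frame(specimen_id = ids, species = sps, genus = gens,
                    subfamily = sfs, stringsAsFactors = FALSE)
  true_gap_ratio <- mean(sp_true_inter[!is.na(sp_true_intra) &
                                       !is.na(sp_true_inter)]) /
                    mean(sp_true_intra, na.rm = TRUE)
  truth <- list(config = unclass(cfg),
                n_specimens = length(ids),
                n_species = length(sp_names),
                lumped_species = lumped_species,
                species = data.frame(species = sp_names, genus = sp_genus,
                                     true_max_intra = sp_true_intra,
                                     true_min_inter = sp_true_inter,
                                     stringsAsFactors = FALSE),
                configured_gap_ratio =
                  cfg$congener_divergence / cfg$intra_divergence,
                true_gap_ratio = true_gap_ratio)
  structure(list(alignment = BarcodeAlignment(dna, tax), truth = truth),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits the FASTA alignment, the taxonomy TSV and a JSON file of the
#' generating truth, in the formats the reading functions consume.
#'
#' @param sim A `sim_dataset` from [simulateBarcodes()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "alignment.fasta"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  writeAlignment(sim$alignment, paths[["fasta"]])
  writeTaxonomy(sim$alignment, paths[["taxonomy"]])
  truth <- sim$truth
  truth$species <- NULL  # per-species truth table stays in-memory only
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
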