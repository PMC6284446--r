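#' Read an aligned FASTA barcode file
#'
#' Reads a multiple sequence alignment from FASTA, normalises to
#' uppercase, and validates that all records share one length, that IDs
#' are unique and that no character falls outside the IUPAC nucleotide
#' alphabet plus the gap character `-`.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], file order preserved.
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw strings first: the DNA reader silently drops letters
  # outside its alphabet, which would hide data corruption
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  txt <- toupper(as.character(raw))
  # FASTA description lines may carry annotation after the ID token
  names(txt) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(txt)))
    stop("duplicated sequence IDs in ", path, ": ",
         paste(unique(names(txt)[duplicated(names(txt))]), collapse = ", "))
  bad <- setdiff(unique(strsplit(paste(txt, collapse = ""), "")[[1]]),
                 .ALLOWED_LETTERS)
  if (length(bad))
    stop("sequences contain characters outside IUPAC+gap: ",
         paste(bad, collapse = ", "))
  w <- nchar(txt)
  if (length(unique(w)) > 1)
    stop("sequences are not aligned (unequal lengths); offending IDs: ",
         paste(names(txt)[w != w[1]], collapse = ", "))
  Biostrings::DNAStringSet(txt)
}

#' Write an alignment to FASTA
#'
#' @param seqs A named `DNAStringSet` or a `BarcodeAlignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(seqs, path) {
  if (is(seqs, "BarcodeAlignment")) seqs <- barcodeSequences(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Reads a tab-separated table with header columns `specimen_id`,
#' `species`, `genus`, `subfamily` (extra columns are kept) and validates
#' hierarchy consistency: every species belongs to exactly one genus and
#' every genus to exactly one subfamily.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of taxonomy records.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tax <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  msgs <- .checkTaxonomyFrame(tax)
  if (length(msgs)) stop("invalid taxonomy table: ", paste(msgs, collapse = "; "))
  tax
}

#' Write a taxonomy table to TSV
#'
#' @param tax A taxonomy `data.frame` or a `BarcodeAlignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(tax, path) {
  if (is(tax, "BarcodeAlignment")) tax <- taxonomyTable(tax)
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment and taxonomy into a BarcodeAlignment
#'
#' Convenience wrapper joining [readAlignment()] and [readTaxonomy()];
#' errors if any specimen in the alignment lacks a taxonomy record or
#' vice versa.
#'
#' @param fasta Path to the aligned FASTA file.
#' @param taxonomy Path to the taxonomy TSV. If `NULL`, taxonomy is
#'   parsed from the FASTA headers with [parseHeaderTaxonomy()].
#' @return A [BarcodeAlignment-class].
#' @export
readBarcodeAlignment <- function(fasta, taxonomy = NULL) {
  seqs <- readAlignment(fasta)
  tax <- if (is.null(taxonomy)) parseHeaderTaxonomy(names(seqs))
         else readTaxonomy(taxonomy)
  BarcodeAlignment(seqs, tax)
}

#' Parse taxonomy from Genus_species_voucher FASTA headers
#'
#' Fallback for alignments whose record IDs follow the common
#' `Genus_species_voucher` convention (e.g. `Apolygus_lucorum_CNU001`).
#' The subfamily cannot be recovered from such headers and is set to
#' `"Unknown"`; a proper taxonomy TSV should be preferred whenever one
#' exists.
#'
#' @param ids Character vector of record IDs.
#' @return A taxonomy `data.frame` with the four standard columns.
#' @export
parseHeaderTaxonomy <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- ids[vapply(parts, length, 1L) < 2L]
  if (length(bad))
    stop("cannot parse Genus_species from header(s): ",
         paste(bad, collapse = ", "))
  genus <- vapply(parts, `[`, "", 1L)
  species <- paste(genus, vapply(parts, `[`, "", 2L))
  data.frame(specimen_id = ids, species = species, genus = genus,
             subfamily = "Unknown", stringsAsFactors = FALSE)
}

.newickQuote <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.|/-]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a phylogenetic tree in Newick format
#'
#' Serialises an `ape` `phylo` tree with branch lengths at full
#' precision (15 significant digits). Labels containing characters
#' outside the safe Newick alphabet are single-quoted with internal
#' quotes doubled, so any standard parser recovers them verbatim.
#'
#' @param tree A `phylo` object with >= 2 tips.
#' @param path Output path, or `NULL` to return the Newick string only.
#' @return The Newick string, invisibly when written to a file.
#' @seealso [readNewick()]
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- .newickQuote(tree$tip.label)
  fmt <- function(len) {
    if (is.null(len) || is.na(len)) "" else sprintf(":%.15g", len)
  }
  recurse <- function(node, len) {
    if (node <= ntip) return(paste0(lab[node], fmt(len)))
    rows <- kids[[as.character(node)]]
    inner <- vapply(rows, function(r)
      recurse(tree$edge[r, 2], tree$edge.length[r]), "")
    paste0("(", paste(inner, collapse = ","), ")", fmt(len))
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  txt <- paste0(recurse(root, NA), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that additionally strips the
#' single quotes `ape` leaves around quoted labels and un-doubles
#' embedded quotes, so [writeNewick()] round-trips arbitrary specimen
#' IDs.
#'
#' @param path Path to a Newick file, or `NULL` when `text` is given.
#' @param text A Newick string.
#' @return A `phylo` object.
#' @export
readNewick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
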