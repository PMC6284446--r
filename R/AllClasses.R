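#' BarcodeAlignment: an annotated COI barcode alignment
#'
#' Container joining an equal-length, indel-free-or-gapped DNA alignment
#' (a [Biostrings::DNAStringSet] named by specimen ID) with a taxonomy
#' table assigning every specimen to a species, genus and subfamily.
#' Validity enforces the invariants every downstream computation relies
#' on: equal sequence widths, unique specimen IDs, a one-to-one join
#' between sequences and taxonomy, and a consistent taxonomic hierarchy
#' (each species in exactly one genus, each genus in exactly one
#' subfamily).
#'
#' @slot sequences A named `DNAStringSet`, all of equal width.
#' @slot taxonomy A `data.frame` with character columns `specimen_id`,
#'   `species`, `genus`, `subfamily`, one row per sequence.
#'
#' @seealso [BarcodeAlignment()] for the user constructor,
#'   [readBarcodeAlignment()] to build one from files.
#' @exportClass BarcodeAlignment
setClass("BarcodeAlignment",
  representation(sequences = "DNAStringSet", taxonomy = "data.frame")
)

.TAXONOMY_COLS <- c("specimen_id", "species", "genus", "subfamily")

# Letters tolerated in an aligned barcode: the four bases, IUPAC
# ambiguity codes, N and the gap character.
.ALLOWED_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                      "V", "H", "D", "B", "N", "-")

.checkTaxonomyFrame <- function(tax) {
  msgs <- character(0)
  missing_cols <- setdiff(.TAXONOMY_COLS, colnames(tax))
  if (length(missing_cols))
    return(paste("taxonomy is missing column(s):",
                 paste(missing_cols, collapse = ", ")))
  for (cl in .TAXONOMY_COLS) {
    v <- tax[[cl]]
    if (!is.character(v) || anyNA(v) || any(!nzchar(v)))
      msgs <- c(msgs, sprintf(
        "taxonomy column '%s' must be character with no missing/empty values", cl))
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(tax$specimen_id))
    msgs <- c(msgs, paste("duplicated specimen_id in taxonomy:",
      paste(unique(tax$specimen_id[duplicated(tax$specimen_id)]), collapse = ", ")))
  # hierarchy consistency: species -> genus and genus -> subfamily are functions
  sp2gen <- unique(tax[, c("species", "genus")])
  bad_sp <- sp2gen$species[duplicated(sp2gen$species)]
  if (length(bad_sp))
    msgs <- c(msgs, paste("species mapped to more than one genus:",
                          paste(unique(bad_sp), collapse = ", ")))
  gen2sf <- unique(tax[, c("genus", "subfamily")])
  bad_gen <- gen2sf$genus[duplicated(gen2sf$genus)]
  if (length(bad_gen))
    msgs <- c(msgs, paste("genus mapped to more than one subfamily:",
                          paste(unique(bad_gen), collapse = ", ")))
  msgs
}

setValidity("BarcodeAlignment", function(object) {
  msgs <- character(0)
  seqs <- object@sequences
  tax <- object@taxonomy
  if (length(seqs) < 2)
    msgs <- c(msgs, "a dataset needs at least 2 specimens")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))))
    msgs <- c(msgs, "all sequences must be named by specimen ID")
  else if (anyDuplicated(names(seqs)))
    msgs <- c(msgs, paste("duplicated specimen IDs:",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1) {
    off <- names(seqs)[w != w[1]]
    msgs <- c(msgs, paste("unequal sequence lengths (not an alignment); offending IDs:",
                          paste(off, collapse = ", ")))
  }
  cm <- Biostrings::consensusMatrix(seqs)
  bad_letters <- setdiff(rownames(cm)[rowSums(cm) > 0], .ALLOWED_LETTERS)
  if (length(bad_letters))
    msgs <- c(msgs, paste("sequences contain characters outside IUPAC+gap:",
                          paste(bad_letters, collapse = ", ")))
  msgs <- c(msgs, .checkTaxonomyFrame(tax))
  if (!length(msgs)) {
    miss <- setdiff(names(seqs), tax$specimen_id)
    extra <- setdiff(tax$specimen_id, names(seqs))
    if (length(miss))
      msgs <- c(msgs, paste("specimens in alignment but not in taxonomy:",
                            paste(miss, collapse = ", ")))
    if (length(extra))
      msgs <- c(msgs, paste("specimens in taxonomy but not in alignment:",
                            paste(extra, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BarcodeAlignment
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of aligned, equal-length barcode sequences. Lowercase input is
#'   normalised to uppercase.
#' @param taxonomy A `data.frame` with columns `specimen_id`, `species`,
#'   `genus`, `subfamily` covering exactly the sequence names.
#' @return A validated [BarcodeAlignment-class] object. The taxonomy rows
#'   are reordered to match the sequence order.
#' @examples
#' seqs <- c(s1 = "ACGTACGT", s2 = "ACGAACGT", s3 = "TCGAACGA")
#' tax <- data.frame(
#'   specimen_id = c("s1", "s2", "s3"),
#'   species = c("Genus alpha", "Genus alpha", "Genus beta"),
#'   genus = "Genus", subfamily = "Subfam"
#' )
#' ba <- BarcodeAlignment(seqs, tax)
#' ba
#' @export
BarcodeAlignment <- function(sequences, taxonomy) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  for (cl in intersect(.TAXONOMY_COLS, colnames(taxonomy)))
    taxonomy[[cl]] <- as.character(taxonomy[[cl]])
  obj <- new("BarcodeAlignment", sequences = sequences, taxonomy = taxonomy)
  # keep taxonomy in sequence order so row i always describes sequence i
  obj@taxonomy <- taxonomy[match(names(sequences), taxonomy$specimen_id), ,
                           drop = FALSE]
  rownames(obj@taxonomy) <- NULL
  obj
}
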