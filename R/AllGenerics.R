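#' @rdname BarcodeAlignment-accessors
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @rdname BarcodeAlignment-accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname BarcodeAlignment-accessors
#' @export
setGeneric("barcodeSequences", function(x) standardGeneric("barcodeSequences"))

#' @rdname BarcodeAlignment-accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' Accessors for BarcodeAlignment objects
#'
#' `specimenIds()` returns the specimen IDs in alignment order;
#' `barcodeSequences()` the underlying `DNAStringSet`; `taxonomyTable()`
#' the taxonomy `data.frame` in the same order; `alignmentWidth()` the
#' common sequence length; `length()` the number of specimens.
#'
#' @param x A [BarcodeAlignment-class] object.
#' @return See details above.
#' @name BarcodeAlignment-accessors
#' @aliases specimenIds taxonomyTable barcodeSequences alignmentWidth
NULL

#' @rdname BarcodeAlignment-accessors
setMethod("specimenIds", "BarcodeAlignment", function(x) names(x@sequences))

#' @rdname BarcodeAlignment-accessors
setMethod("taxonomyTable", "BarcodeAlignment", function(x) x@taxonomy)

#' @rdname BarcodeAlignment-accessors
setMethod("barcodeSequences", "BarcodeAlignment", function(x) x@sequences)

#' @rdname BarcodeAlignment-accessors
setMethod("alignmentWidth", "BarcodeAlignment",
          function(x) Biostrings::width(x@sequences)[1])

#' @rdname BarcodeAlignment-accessors
#' @export
setMethod("length", "BarcodeAlignment", function(x) length(x@sequences))

#' @describeIn BarcodeAlignment-accessors Subset specimens by index, ID or
#'   logical vector; taxonomy follows.
#' @param i index vector (integer, logical, or specimen IDs)
#' @param j,...,drop ignored
#' @export
setMethod("[", "BarcodeAlignment", function(x, i, j, ..., drop = FALSE) {
  BarcodeAlignment(x@sequences[i], x@taxonomy[match(names(x@sequences[i]),
                   x@taxonomy$specimen_id), , drop = FALSE])
})

setMethod("show", "BarcodeAlignment", function(object) {
  tax <- object@taxonomy
  cat(sprintf(
    "BarcodeAlignment: %d specimens x %d sites\n  %d species, %d genera, %d subfamilies\n",
    length(object@sequences), alignmentWidth(object),
    length(unique(tax$species)), length(unique(tax$genus)),
    length(unique(tax$subfamily))))
  ids <- names(object@sequences)
  shown <- utils::head(ids, 4)
  cat("  specimens: ", paste(shown, collapse = ", "),
      if (length(ids) > 4) ", ..." else "", "\n", sep = "")
})

#' Summarise a BarcodeAlignment
#'
#' Counts specimens, species, genera and subfamilies, and the mean number
#' of specimens per species (sampling depth), for a
#' [BarcodeAlignment-class] or a bare taxonomy `data.frame`.
#'
#' @param x A `BarcodeAlignment` or a taxonomy `data.frame` with columns
#'   `specimen_id`, `species`, `genus`, `subfamily`.
#' @return A list with `n_specimens`, `n_species`, `n_genera`,
#'   `n_subfamilies`, `specimens_per_species`.
#' @examples
#' tax <- data.frame(specimen_id = as.character(1:11),
#'                   species = rep(c("a", "b", "c", "d", "e"), c(3, 2, 2, 2, 2)),
#'                   genus = "g", subfamily = "s")
#' datasetSummary(tax)$specimens_per_species
#' @export
datasetSummary <- function(x) {
  tax <- if (is(x, "BarcodeAlignment")) taxonomyTable(x) else x
  list(
    n_specimens = nrow(tax),
    n_species = length(unique(tax$species)),
    n_genera = length(unique(tax$genus)),
    n_subfamilies = length(unique(tax$subfamily)),
    specimens_per_species = nrow(tax) / length(unique(tax$species))
  )
}
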