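## Kimura 2-parameter distances.
##
## Sites are compared pairwise; a site contributes only when both
## sequences carry an unambiguous base (A, C, G or T). Mismatches are
## transitions (A<->G, C<->T) or transversions (everything else), and the
## distance is Kimura's closed form
##   d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]
## with P and Q the transition and transversion proportions over the L
## compared sites. Saturated pairs (either log argument <= 0) and pairs
## with L = 0 are undefined and flagged as NA, never silently clamped.

# integer encoding: A=1, C=2, G=3, T=4, anything else (gap, N, IUPAC
# ambiguity) = 0 and excluded from comparison. Transitions connect bases
# of equal parity (A=1/G=3 odd purines, C=2/T=4 even pyrimidines).
.encodeAlignment <- function(seqs) {
  m <- as.matrix(seqs)  # nseq x width character matrix
  enc <- match(m, c("A", "C", "G", "T"))
  enc[is.na(enc)] <- 0L
  dim(enc) <- dim(m)
  rownames(enc) <- rownames(m)
  enc
}

#' Classify the compared sites of one sequence pair
#'
#' Applies pairwise deletion (sites with a gap, `N` or IUPAC ambiguity in
#' either sequence are excluded), then counts transitions and
#' transversions among the remaining mismatches.
#'
#' @param a,b Two aligned sequences of equal length: character scalars,
#'   `DNAString`s, or integer encodings from the same alignment.
#' @return A list with `L` (compared sites), `transitions`,
#'   `transversions`, and the proportions `P = transitions/L`,
#'   `Q = transversions/L` (both `NaN` when `L = 0`).
#' @examples
#' countSitePairs("ACGT", "GCGA")  # one transition (A/G), one transversion (T/A)
#' @seealso [k2pFromCounts()], [k2pDistanceMatrix()]
#' @export
countSitePairs <- function(a, b) {
  tovec <- function(x) {
    if (is.integer(x)) return(x)
    x <- toupper(as.character(x))
    v <- match(strsplit(x, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    v[is.na(v)] <- 0L
    v
  }
  va <- tovec(a); vb <- tovec(b)
  if (length(va) != length(vb))
    stop("sequences have different lengths (", length(va), " vs ",
         length(vb), ")")
  ok <- va > 0L & vb > 0L
  va <- va[ok]; vb <- vb[ok]
  L <- length(va)
  diff <- va != vb
  ts <- sum(diff & (va %% 2L) == (vb %% 2L))
  tv <- sum(diff) - ts
  list(L = L, transitions = ts, transversions = tv, P = ts / L, Q = tv / L)
}

#' K2P distance from site-pair counts
#'
#' Evaluates `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, in
#' substitutions per site. Returns `NA` when the pair is undefined: no
#' compared sites (`L = 0`) or divergence beyond the model's saturation
#' point (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#'
#' @param counts A list as returned by [countSitePairs()], or `P`/`Q`
#'   proportions given directly.
#' @param P,Q Transition and transversion proportions (used when
#'   `counts` is missing).
#' @return Numeric distance in substitutions/site, or `NA_real_`.
#' @examples
#' k2pFromCounts(countSitePairs("ACGT", "GCGA"))
#' k2pFromCounts(P = 0.10, Q = 0.05)
#' @export
k2pFromCounts <- function(counts, P, Q) {
  if (!missing(counts)) {
    if (counts$L == 0) return(NA_real_)
    P <- counts$P; Q <- counts$Q
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix
#'
#' Computes the Kimura 2-parameter distance for every specimen pair.
#' Undefined pairs (no shared unambiguous sites, or saturation) are
#' stored as `NA`; their count is reported with a message and a warning
#' names any specimen whose comparisons are all undefined.
#'
#' @param x A [BarcodeAlignment-class], a named `DNAStringSet`, or a
#'   named character vector of equal-length sequences.
#' @param deletion `"pairwise"` (default; each pair uses its own set of
#'   clean sites) or `"complete"` (columns containing any gap/ambiguity
#'   in any sequence are removed once, before comparison).
#' @return A symmetric numeric matrix (substitutions/site) with zero
#'   diagonal, specimen IDs as dimnames, and attribute `n_undefined`
#'   giving the number of undefined off-diagonal pairs (unordered).
#' @examples
#' d <- k2pDistanceMatrix(c(a = "ACGTACGTAC", b = "ACGAACGTAC", c = "GCTTACGAAC"))
#' round(d, 4)
#' @export
k2pDistanceMatrix <- function(x, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (is(x, "BarcodeAlignment")) x <- barcodeSequences(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  n <- length(x)
  if (n < 2) stop("need at least 2 sequences")
  if (is.null(names(x))) stop("sequences must be named by specimen ID")
  enc <- .encodeAlignment(x)
  if (deletion == "complete") {
    keep <- colSums(enc == 0L) == 0L
    enc <- enc[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1)) {
    ai <- enc[i, ]
    for (j in (i + 1):n) {
      dij <- k2pFromCounts(countSitePairs(ai, enc[j, ]))
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0) {
    message("k2pDistanceMatrix: ", n_undef, " undefined pair(s) flagged as NA")
    allna <- vapply(seq_len(n), function(i) all(is.na(d[i, -i])), TRUE)
    if (any(allna))
      warning("specimen(s) with no defined comparison: ",
              paste(rownames(d)[allna], collapse = ", "))
  }
  attr(d, "n_undefined") <- n_undef
  d
}

#' Write / read a distance matrix as TSV
#'
#' Square tab-separated layout with specimen IDs as the first row and
#' column; undefined entries are written as `NA`.
#'
#' @param d A symmetric distance matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(specimen_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
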