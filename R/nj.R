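## Neighbor joining (Saitou & Nei), in the Studier-Keppler formulation:
## at each step join the pair minimising
##   Q(i,j) = (n - 2) d(i,j) - R(i) - R(j),   R = row sums,
## with branch lengths from the standard split formula and distances to
## the new node d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2. Ties take the
## smallest (i,j) index pair in current matrix order, so a given matrix
## always yields the same tree. Negative branch lengths are clamped to
## zero and the deficit moved onto the sister branch of the same join,
## preserving the path length through the joined pair.

.resolveUndefined <- function(d, undefined) {
  if (!anyNA(d)) return(d)
  if (undefined == "strict") {
    ut <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
    stop("undefined distance entries with policy 'strict': ",
         paste(sprintf("(%s,%s)", rownames(d)[ut[, 1]], rownames(d)[ut[, 2]]),
               collapse = ", "))
  }
  # drop-specimen: greedily remove the specimen involved in the most
  # undefined pairs until none remain
  dropped <- character(0)
  while (anyNA(d)) {
    na_deg <- rowSums(is.na(d))
    worst <- which.max(na_deg)
    dropped <- c(dropped, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
  }
  message("njTree: dropped specimen(s) with undefined distances: ",
          paste(dropped, collapse = ", "))
  if (nrow(d) < 2) stop("fewer than 2 specimens remain after dropping")
  d
}

# clamp a negative branch length, shifting the deficit to its sister so
# that li + lj is preserved
.clampPair <- function(li, lj) {
  if (li < 0) { lj <- lj - li; li <- 0 }
  if (lj < 0) { li <- li - lj; lj <- 0 }
  c(li, lj)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the unrooted NJ tree. Deterministic: ties in the Q criterion
#' are broken toward the smallest index pair, so equal inputs give
#' bit-identical trees. Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sister branch.
#'
#' @param d A symmetric distance matrix with specimen IDs as dimnames;
#'   `NA` entries are handled according to `undefined`.
#' @param undefined `"drop-specimen"` (default): greedily remove the
#'   specimens covering all undefined pairs; `"strict"`: error, naming
#'   the undefined pairs.
#' @return An unrooted `ape` `phylo` object (arbitrarily represented
#'   with a trifurcating root node for n >= 3 leaves; a 2-leaf tree is
#'   split at the midpoint of its single edge).
#' @examples
#' d <- matrix(c(0, .4, .6, .4, 0, .8, .6, .8, 0), 3,
#'             dimnames = list(c("a","b","c"), c("a","b","c")))
#' tr <- njTree(d)
#' tr$edge.length  # 0.1, 0.3, 0.5
#' @export
njTree <- function(d, undefined = c("drop-specimen", "strict")) {
  undefined <- match.arg(undefined)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must have specimen IDs as dimnames")
  d <- .resolveUndefined(d, undefined)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 specimens")
  tips <- rownames(d)
  if (n == 2) {
    tree <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = tips, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  # ape numbering: tips 1..n; internal nodes n+1..2n-2 with the root
  # (the last node created) at n+1, so internals are numbered in
  # reverse creation order
  n_internal <- n - 2L
  apeId <- function(k) n + n_internal - k + 1L
  nodes <- seq_len(n)            # current active node ids (ape numbering)
  D <- unname(d)
  edge <- matrix(0L, 2L * n - 3L, 2L)
  elen <- numeric(2L * n - 3L)
  ne <- 0L
  k <- 0L
  addEdge <- function(parent, child, len) {
    ne <<- ne + 1L
    edge[ne, ] <<- c(parent, child)
    elen[ne] <<- len
  }
  while (length(nodes) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    lens <- .clampPair(li, lj)
    k <- k + 1L
    u <- apeId(k)
    addEdge(u, nodes[i], lens[1])
    addEdge(u, nodes[j], lens[2])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], u)
  }
  # final 3-way join at the (trifurcating) root
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  x <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  if (any(x < 0)) {
    deficit <- sum(x[x < 0])
    x[x < 0] <- 0
    longest <- which.max(x)
    x[longest] <- max(x[longest] + deficit, 0)
  }
  k <- k + 1L
  root <- apeId(k)   # == n + 1
  for (t in 1:3) addEdge(root, nodes[t], x[t])
  tree <- list(edge = edge, edge.length = elen, tip.label = tips,
               Nnode = n_internal)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Is a set of leaves monophyletic on an unrooted tree?
#'
#' A label set is monophyletic when some edge of the unrooted tree
#' bipartitions the leaves into exactly that set versus everything else;
#' the answer is therefore invariant under rerooting. Singletons and the
#' full leaf set are trivially monophyletic.
#'
#' @param tree A `phylo` object.
#' @param labels Character vector of tip labels (subset of the leaf set).
#' @return `TRUE` or `FALSE`.
#' @export
isMonophyletic <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  target <- match(unique(labels), tree$tip.label)
  if (anyNA(target))
    stop("unknown label(s): ",
         paste(setdiff(labels, tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(target) %in% c(1L, ntip - 1L, ntip)) return(TRUE)
  target <- sort(target)
  other <- setdiff(seq_len(ntip), target)
  # clades of the arbitrarily rooted representation, one per internal
  # node, cover all internal-edge bipartitions (as the set or its
  # complement)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    if (identical(as.integer(p), target) || identical(as.integer(p), other))
      return(TRUE)
  }
  FALSE
}

#' Monophyly of every species, genus and subfamily on a tree
#'
#' @param tree A `phylo` whose tips are specimen IDs.
#' @param tax A taxonomy `data.frame` or [BarcodeAlignment-class]
#'   covering all tips.
#' @return A `data.frame` with `level` (species/genus/subfamily),
#'   `taxon`, `n_specimens`, `monophyletic`. Taxa with a single sampled
#'   specimen are trivially monophyletic.
#' @export
taxonMonophylyTable <- function(tree, tax) {
  if (is(tax, "BarcodeAlignment")) tax <- taxonomyTable(tax)
  idx <- match(tree$tip.label, tax$specimen_id)
  if (anyNA(idx))
    stop("tips missing from taxonomy: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  tax <- tax[idx, , drop = FALSE]
  one_level <- function(level) {
    groups <- split(tree$tip.label, tax[[level]])
    data.frame(level = if (level == "species") "species"
                       else level,
               taxon = names(groups),
               n_specimens = vapply(groups, length, 1L),
               monophyletic = vapply(groups, function(g)
                 isMonophyletic(tree, g), TRUE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_level("species"), one_level("genus"),
               one_level("subfamily"))
  rownames(out) <- NULL
  out
}
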