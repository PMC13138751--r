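#' Read a set of phylogenetic trees
#'
#' Reads one or more rooted, branch-length trees from a Newick or NEXUS
#' file.  Tip labels are whitespace-normalized: surrounding whitespace is
#' stripped and internal spaces are converted to underscores, so labels
#' written either way compare equal.
#'
#' @param path Path to the tree file.
#' @param format Either `"newick"` (default; one or more `;`-terminated
#'   trees) or `"nexus"`.
#' @return A list of `phylo` objects in file order.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' tr <- read_trees(f)[[1]]
#' @export
read_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "nexus") {
    trees <- tryCatch(ape::read.nexus(path),
                      error = function(e) stop("failed to parse NEXUS file '",
                                               path, "': ", conditionMessage(e)))
    if (inherits(trees, "phylo")) trees <- list(trees)
    trees <- unclass(trees)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    chunks <- strsplit(txt, ";", fixed = TRUE)[[1]]
    chunks <- chunks[nzchar(gsub("[[:space:]]", "", chunks))]
    if (length(chunks) == 0) stop("empty tree file: ", path)
    trees <- vector("list", length(chunks))
    for (i in seq_along(chunks)) {
      tr <- tryCatch(
        suppressWarnings(ape::read.tree(text = paste0(chunks[i], ";"))),
        error = function(e) NULL)
      if (is.null(tr) || !inherits(tr, "phylo"))
        stop("failed to parse tree ", i, " in '", path, "'")
      trees[[i]] <- tr
    }
  }
  lapply(trees, function(tr) {
    tr$tip.label <- normalize_labels(tr$tip.label)
    if (anyDuplicated(tr$tip.label))
      stop("duplicate tip labels after normalization")
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      stop("negative branch lengths")
    tr
  })
}

#' Normalize taxon labels
#'
#' Trims whitespace and replaces internal whitespace with underscores so
#' that `"Homo sapiens"` and `"Homo_sapiens"` are treated as the same tip.
#'
#' @param x Character vector of labels.
#' @return Normalized character vector.
#' @export
normalize_labels <- function(x) {
  gsub("[[:space:]]+", "_", trimws(as.character(x)))
}

#' Root-to-tip depths
#'
#' @param tree A `phylo` object.
#' @return Named vector of root-to-tip path lengths.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Phylogenetic correlation matrix
#'
#' Builds the species-by-species matrix of shared root-to-MRCA path lengths
#' divided by the maximum root-to-tip depth.  For an ultrametric tree the
#' diagonal is all ones and the matrix is the expected trait correlation
#' under Brownian motion; for trees carrying fossil tips the corresponding
#' diagonal entries are < 1 (less time for variance to accrue).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param taxa Optional ordered subset of tip labels; defaults to all tips
#'   in tree order.
#' @param scale Divide by the maximum root-to-tip depth (default `TRUE`).
#'   With `scale = FALSE` the raw shared path lengths are returned.
#' @return A symmetric matrix with `taxa` as dimnames.
#' @export
phylo_corr <- function(tree, taxa = NULL, scale = TRUE) {
  V <- ape::vcv(tree)
  rownames(V) <- colnames(V) <- normalize_labels(rownames(V))
  if (scale) V <- V / max(diag(V))
  if (is.null(taxa)) return(V)
  taxa <- normalize_labels(taxa)
  missing <- setdiff(taxa, rownames(V))
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  V[taxa, taxa, drop = FALSE]
}

.clade_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  vapply(pp, function(ix) paste(sort(tree$tip.label[ix]), collapse = "|"), "")
}

#' Maximum clade credibility tree
#'
#' Scores every member of a tree set by the sum of log clade frequencies
#' (clade support estimated from the set itself) and returns the
#' highest-scoring member; ties are broken by the lowest input index.
#'
#' @param trees List of `phylo` objects over an identical tip set.
#' @return The selected `phylo`, with attributes `"mcc_index"` and
#'   `"mcc_score"`.
#' @export
mcc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), tips))
      stop("trees have heterogeneous tip sets")
  keys <- lapply(trees, .clade_keys)
  freq <- table(unlist(keys)) / length(trees)
  score <- vapply(keys, function(k) sum(log(freq[k])), 0)
  i <- which.max(score)
  out <- trees[[i]]
  attr(out, "mcc_index") <- i
  attr(out, "mcc_score") <- score[i]
  out
}

#' Graft a calibrated subtree onto a base phylogeny
#'
#' Replaces the clade of `base` spanned by `shared_taxa` with `addon`
#' (typically a calibrated fossil-bearing tree containing the shared extant
#' taxa plus extinct tips).  The addon's branch lengths are rescaled so the
#' shared extant taxa keep their depths in `base`; fossil tips end at
#' proportionally shallower depths, so the result is generally
#' non-ultrametric.
#'
#' @param base Rooted `phylo`; `shared_taxa` must form a clade in it, not
#'   spanning the root.
#' @param addon Rooted `phylo` whose tips are a superset of `shared_taxa`,
#'   ultrametric over the shared taxa.
#' @param shared_taxa Tip labels present in both trees.
#' @return A `phylo` combining `base` (outside the clade, depths preserved
#'   exactly) with the rescaled `addon`.
#' @export
graft_clade <- function(base, addon, shared_taxa) {
  shared_taxa <- normalize_labels(shared_taxa)
  base$tip.label <- normalize_labels(base$tip.label)
  addon$tip.label <- normalize_labels(addon$tip.label)
  if (!all(shared_taxa %in% base$tip.label))
    stop("shared taxa missing from base tree")
  if (!all(shared_taxa %in% addon$tip.label))
    stop("shared taxa missing from addon tree")

  nb <- length(base$tip.label)
  if (length(shared_taxa) < 2)
    stop("need at least two shared taxa to define the base clade")
  m <- ape::getMRCA(base, shared_taxa)
  if (m == nb + 1)
    stop("shared taxa straddle the base root; not a proper clade")
  clade_tips <- ape::extract.clade(base, m)$tip.label
  if (!setequal(clade_tips, shared_taxa))
    stop("shared taxa are not monophyletic in the base tree")

  depth_b <- ape::node.depth.edgelength(base)
  tip_ix <- match(clade_tips, base$tip.label)
  h_tips <- depth_b[tip_ix] - depth_b[m]
  h_b <- max(h_tips)
  if (diff(range(h_tips)) > 1e-6 * max(depth_b))
    warning("base clade is not ultrametric; using its maximum tip depth")

  depth_a <- ape::node.depth.edgelength(addon)
  sh_ix <- match(shared_taxa, addon$tip.label)
  h_a <- max(depth_a[sh_ix])
  f <- h_b / h_a
  if (!is.finite(f) || f <= 0) stop("non-positive depth rescale factor")

  addon$edge.length <- addon$edge.length * f
  addon$root.edge <- NULL

  keep <- clade_tips[1]
  keep_below <- depth_b[match(keep, base$tip.label)] - depth_b[m]
  base2 <- if (length(clade_tips) > 1)
    ape::drop.tip(base, setdiff(clade_tips, keep)) else base
  ti <- match(keep, base2$tip.label)
  ei <- which(base2$edge[, 2] == ti)
  # after pruning, the terminal edge runs from the clade's parent to `keep`;
  # shorten it so the addon root sits at the original clade-root depth
  base2$edge.length[ei] <- base2$edge.length[ei] - keep_below
  if (base2$edge.length[ei] < -1e-9) stop("negative stem after rescale")
  base2$edge.length[ei] <- max(base2$edge.length[ei], 0)
  out <- ape::bind.tree(base2, addon, where = ti, position = 0)
  out
}

#' Is a tree ultrametric?
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance on tip-depth agreement.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}
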