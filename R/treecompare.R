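#' Rewrite bracketed bootstrap supports into node labels
#'
#' Some ML tools emit gene trees with supports in square brackets after
#' the branch length (\code{():0.1[87]}); standard newick readers expect
#' the support as an internal node label (\code{()87:0.1}). This
#' relocates every bracketed support without altering the topology,
#' lengths or semantics, and parses the result.
#'
#' @param newick a newick string (or path to a file containing one).
#' @return an \code{ape::phylo} with supports in \code{node.label}.
#' @export
reformatSupportNewick <- function(newick) {
  if (length(newick) == 1L && !grepl("\\(", newick) &&
      file.exists(newick))
    newick <- paste(readLines(newick), collapse = "")
  chars <- strsplit(newick, "", fixed = TRUE)[[1]]
  n_open <- sum(chars %in% c("(", "["))
  n_close <- sum(chars %in% c(")", "]"))
  if (n_open != n_close)
    stop("unbalanced parentheses/brackets in newick (", n_open,
         " open vs ", n_close, " close)")
  fixed <- gsub("\\):([^,()\\[\\]]+)\\[([^\\]]+)\\]", ")\\2:\\1",
                newick, perl = TRUE)
  fixed <- gsub("\\)\\[([^\\]]+)\\]", ")\\1", fixed,
                perl = TRUE)                     # no-length form
  tr <- ape::read.tree(text = fixed)
  if (is.null(tr)) stop("newick parse failure")
  tr
}

# numeric supports from node labels, auto-detecting the scale:
# values all <= 1 are read as proportions and rescaled to percent
nodeSupports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  finite <- sup[!is.na(sup)]
  if (length(finite) && all(finite <= 1)) sup <- sup * 100
  sup
}

#' Collapse poorly supported internal nodes into polytomies
#'
#' Internal edges whose child node carries a support strictly below the
#' threshold (percent; proportions are auto-detected and rescaled) are
#' contracted. Nodes without a numeric support are never collapsed, and
#' the leaf set is untouched. Collapsing is idempotent.
#'
#' @param tree an \code{ape::phylo} with supports in \code{node.label}.
#' @param threshold_percent strict collapsing threshold (default 10).
#' @return the collapsed \code{ape::phylo}.
#' @export
collapseLowSupport <- function(tree, threshold_percent = 10) {
  ntip <- length(tree$tip.label)
  sup <- nodeSupports(tree)
  root <- ntip + 1L
  kill <- which(!is.na(sup) & sup < threshold_percent) + ntip
  kill <- setdiff(kill, root)
  if (!length(kill)) return(tree)

  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  lens <- if (has_len)
    setNames(tree$edge.length, tree$edge[, 2L]) else NULL
  lab <- tree$node.label

  # recursively splice collapsed internal nodes into their parent's
  # child list (handles chains of collapsed nodes)
  splice <- function(k) {
    if (k > ntip && k %in% kill)
      unlist(lapply(kids[[as.character(k)]], splice))
    else k
  }
  wr <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    children <- unlist(lapply(kids[[as.character(node)]], splice))
    parts <- vapply(children, wrEdge, character(1))
    paste0("(", paste(parts, collapse = ","), ")",
           if (!is.null(lab) && !is.na(lab[node - ntip]))
             lab[node - ntip] else "")
  }
  wrEdge <- function(k) {
    s <- wr(k)
    if (has_len && !is.null(lens[[as.character(k)]]))
      paste0(s, ":", format(lens[[as.character(k)]],
                            scientific = FALSE)) else s
  }
  ape::read.tree(text = paste0(wr(root), ";"))
}

# canonical nontrivial bipartitions of a tree: each internal clade is
# encoded by the side not containing the reference (first sorted) leaf
canonicalBipartitions <- function(tree, leaves = NULL) {
  if (is.null(leaves)) leaves <- sort(tree$tip.label)
  refleaf <- leaves[1]
  n <- length(leaves)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(idx) {
    side <- sort(labs[idx])
    if (refleaf %in% side) side <- sort(setdiff(leaves, side))
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  unique(out[!is.na(out)])
}

#' Robinson-Foulds distance between two trees
#'
#' Raw RF counts the bipartitions unique to either tree; the normalized
#' value divides by the total number of nontrivial bipartitions present
#' in the two trees, which handles polytomous (collapsed) trees and
#' reads as the proportion of unique nodes.
#'
#' @param treeA,treeB \code{ape::phylo} objects on the same leaf set.
#' @return list(raw, normalized, shared, unique_a, unique_b).
#' @export
rfDistance <- function(treeA, treeB) {
  la <- sort(treeA$tip.label); lb <- sort(treeB$tip.label)
  if (!identical(la, lb))
    stop("leaf sets differ; symmetric difference: ",
         paste(c(setdiff(la, lb), setdiff(lb, la)), collapse = ", "))
  ba <- canonicalBipartitions(treeA, la)
  bb <- canonicalBipartitions(treeB, la)
  shared <- length(intersect(ba, bb))
  ua <- length(setdiff(ba, bb))
  ub <- length(setdiff(bb, ba))
  denom <- length(ba) + length(bb)
  list(raw = ua + ub,
       normalized = if (denom == 0L) 0 else (ua + ub) / denom,
       shared = shared, unique_a = ua, unique_b = ub)
}

#' Concordance test against a bootstrap null distribution
#'
#' The null is the set of normalized RF distances between the best tree
#' and its bootstrap replicate trees (topological uncertainty of one
#' inference); an observed inter-method distance larger than the null
#' maximum indicates disagreement beyond chance.
#'
#' @param best_tree the best-scoring \code{ape::phylo}.
#' @param replicate_trees list (or \code{multiPhylo}) of replicate trees.
#' @param observed named numeric vector of observed inter-method
#'   normalized RF distances (may be empty).
#' @return list(null = c(min, max, mean, sd), n_replicates, observed =
#'   data.frame(comparison, rf, exceeds_null_max, percentile)).
#' @export
rfNullTest <- function(best_tree, replicate_trees, observed = numeric(0)) {
  if (length(replicate_trees) < 2L)
    stop("need at least 2 replicate trees for a null distribution")
  null_d <- vapply(replicate_trees, function(tr)
    rfDistance(best_tree, tr)$normalized, numeric(1))
  obs <- data.frame(comparison = names(observed) %||%
                      paste0("obs", seq_along(observed)),
                    rf = unname(observed),
                    exceeds_null_max = unname(observed) > max(null_d),
                    percentile = vapply(unname(observed), function(x)
                      100 * mean(null_d < x), numeric(1)),
                    stringsAsFactors = FALSE)
  list(null = c(min = min(null_d), max = max(null_d),
                mean = mean(null_d), sd = sd(null_d)),
       n_replicates = length(null_d), observed = obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neighbor-joining tree from a distance matrix
#'
#' A self-contained fallback for external inference engines: standard
#' neighbor joining on any symmetric zero-diagonal distance matrix
#' (e.g. 100 - PNS).
#'
#' @param d symmetric numeric matrix with zero diagonal.
#' @return an \code{ape::phylo}.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  ape::nj(d)
}

#' Write a set of trees as a one-tree-per-line multi-tree file
#'
#' @param trees list of \code{ape::phylo} (or a \code{multiPhylo}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMultiPhylo <- function(trees, path) {
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Export the supermatrix as NEXUS with a taxon partition
#'
#' DATA block with the concatenated alignment plus a SETS block mapping
#' genomes to species, the input layout quartet-based coalescent tools
#' expect.
#'
#' @param sm a \code{\link{Supermatrix}}.
#' @param assignment a \code{\link{SpeciesAssignment}} (optional).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNexusSupermatrix <- function(sm, assignment = NULL, path) {
  seqs <- supermatrixSequences(sm)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(seqs), nchar(seqs[[1]])), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=N GAP=-;", con)
  writeLines("  MATRIX", con)
  writeLines(paste0("    ", names(seqs), "  ", seqs), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  if (!is.null(assignment)) {
    sp <- speciesOf(assignment)
    writeLines("BEGIN SETS;", con)
    parts <- vapply(unique(sp), function(s)
      paste0("    ", s, " : ",
             paste(names(sp)[sp == s], collapse = " ")),
      character(1))
    writeLines(paste0("  TAXPARTITION species =\n",
                      paste(parts, collapse = ",\n"), ";"), con)
    writeLines("END;", con)
  }
  invisible(path)
}
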