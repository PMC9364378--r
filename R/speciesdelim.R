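#' Percentage nucleotide similarity between two aligned rows
#'
#' PNS is the percentage of identical positions among the positions
#' where both rows carry an unambiguous base: gaps, Ns and other
#' ambiguity codes are excluded from the denominator.
#'
#' @param seqA,seqB equal-length aligned nucleotide strings.
#' @return list(percent, n_compared).
#' @export
computePNS <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    stop("sequences must be aligned to equal length")
  a <- charToRaw(toupper(seqA))
  b <- charToRaw(toupper(seqB))
  good <- charToRaw("ACGT")
  ok <- (a %in% good) & (b %in% good)
  n <- sum(ok)
  if (n == 0L) stop("zero comparable positions")
  list(percent = 100 * sum(a[ok] == b[ok]) / n, n_compared = n)
}

#' Pairwise PNS matrix over a supermatrix
#'
#' @param sm a \code{\link{Supermatrix}} (or a named character vector of
#'   equal-length aligned rows).
#' @return symmetric numeric matrix of PNS percentages (diagonal 100)
#'   with an \code{"n_compared"} attribute holding the per-pair count of
#'   compared positions.
#' @export
pnsMatrix <- function(sm) {
  seqs <- if (is(sm, "Supermatrix")) supermatrixSequences(sm) else sm
  ids <- names(seqs)
  raws <- lapply(seqs, function(s) charToRaw(toupper(s)))
  good <- charToRaw("ACGT")
  oks <- lapply(raws, function(r) r %in% good)
  n <- length(ids)
  P <- matrix(100, n, n, dimnames = list(ids, ids))
  NC <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(NC) <- vapply(oks, sum, numeric(1))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- oks[[i]] & oks[[j]]
    cmp <- sum(ok)
    if (cmp == 0L) stop("zero comparable positions between ",
                        ids[i], " and ", ids[j])
    p <- 100 * sum(raws[[i]][ok] == raws[[j]][ok]) / cmp
    P[i, j] <- P[j, i] <- p
    NC[i, j] <- NC[j, i] <- cmp
  }
  attr(P, "n_compared") <- NC
  P
}

#' Delimit species from a PNS matrix
#'
#' Two genomes belong to the same species when their PNS meets the
#' threshold (default >= 97\%); species are the connected components of
#' the resulting graph (single linkage), so the pairwise criterion
#' propagates transitively through intermediate genomes.
#'
#' @param pns symmetric PNS matrix from \code{\link{pnsMatrix}}.
#' @param threshold PNS percentage for conspecificity (inclusive).
#' @return a \code{\link{SpeciesAssignment}} with provisional species
#'   ids; use \code{\link{labelSpecies}} to attach names and numbering.
#' @export
delimitSpecies <- function(pns, threshold = 97.0) {
  ids <- rownames(pns)
  adj <- (pns >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable ids in order of first appearance
  relabel <- setNames(seq_along(unique(comp[ids])), unique(comp[ids]))
  sp <- sprintf("sp%03d", relabel[as.character(comp[ids])])
  names(sp) <- ids
  tab <- data.frame(species = unique(sp),
                    name = NA_character_, status = "candidate",
                    group = NA_character_,
                    n_genomes = as.integer(table(sp)[unique(sp)]),
                    stringsAsFactors = FALSE)
  new("SpeciesAssignment", genomeSpecies = sp, speciesTable = tab)
}

#' Label delimited species as described or numbered candidates
#'
#' Clusters containing at least one type strain inherit the
#' alphabetically first published name (several names in one cluster are
#' recorded and warned about); the remaining clusters become numbered
#' candidates, zero-padded and blocked by group in the supplied group
#' order, then by within-group species order.
#'
#' @param assignment a \code{\link{SpeciesAssignment}}.
#' @param type_strains data.frame(genome_id, species_name); may be empty.
#' @param group_labels named character: genome id -> group label.
#' @param species_order optional character vector of species ids fixing
#'   the within-group (tree) order; defaults to first-appearance order.
#' @param group_order optional group label order; defaults to sorted.
#' @param candidate_prefix prefix for candidate names.
#' @return the relabeled \code{SpeciesAssignment}.
#' @export
labelSpecies <- function(assignment, type_strains = NULL,
                         group_labels = NULL, species_order = NULL,
                         group_order = NULL,
                         candidate_prefix = "sp. ") {
  sp <- speciesOf(assignment)
  tab <- speciesTable(assignment)
  members <- split(names(sp), sp)

  # majority group label per species
  if (!is.null(group_labels)) {
    tab$group <- vapply(tab$species, function(s) {
      g <- group_labels[members[[s]]]
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_character_)
      names(sort(table(g), decreasing = TRUE))[1]
    }, character(1))
  }

  tab$name <- NA_character_
  tab$status <- "candidate"
  tab$synonyms <- NA_character_
  if (!is.null(type_strains) && nrow(type_strains)) {
    for (k in seq_len(nrow(tab))) {
      hit <- type_strains$genome_id %in% members[[tab$species[k]]]
      if (!any(hit)) next
      nm <- sort(unique(type_strains$species_name[hit]))
      tab$name[k] <- nm[1]
      tab$status[k] <- "described"
      if (length(nm) > 1L) {
        tab$synonyms[k] <- paste(nm[-1], collapse = "; ")
        warning("species ", tab$species[k], " merges type strains: ",
                paste(nm, collapse = ", "), "; named by priority ",
                nm[1])
      }
    }
  }

  cand <- tab$species[tab$status == "candidate"]
  if (length(cand)) {
    if (is.null(species_order)) species_order <- tab$species
    if (is.null(group_order))
      group_order <- sort(unique(stats::na.omit(tab$group)))
    ordered <- unlist(lapply(c(group_order, NA), function(g) {
      in_g <- if (is.na(g)) cand[is.na(tab$group[match(cand, tab$species)])]
        else cand[!is.na(tab$group[match(cand, tab$species)]) &
                    tab$group[match(cand, tab$species)] == g]
      in_g[order(match(in_g, species_order))]
    }))
    ordered <- ordered[!is.na(ordered)]
    nums <- setNames(seq_along(ordered), ordered)
    idx <- tab$status == "candidate"
    tab$name[idx] <- sprintf("%s%03d", candidate_prefix,
                             nums[tab$species[idx]])
  }
  new("SpeciesAssignment", genomeSpecies = sp, speciesTable = tab)
}
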