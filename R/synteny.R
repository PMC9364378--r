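#' Extract core-gene adjacency links from ordered scaffolds
#'
#' Each core gene is paired with its immediate neighbors within a
#' scaffold. Under \code{circular}, the scaffolds are read as one
#' circular sequence in the given order and orientation: junction pairs
#' between consecutive scaffolds and the closing first/last pair are
#' included. Without \code{circular}, only within-scaffold adjacencies
#' are returned.
#'
#' @param scaffolds list of character vectors: ordered core genes per
#'   scaffold (already oriented), or a single character vector.
#' @param circular treat the concatenation as a circular chromosome.
#' @param genome_id genome identifier for the result.
#' @return a \code{\link{LinkSet}}.
#' @export
extractLinks <- function(scaffolds, circular = TRUE,
                         genome_id = "genome") {
  if (is.character(scaffolds)) scaffolds <- list(scaffolds)
  genes <- unlist(scaffolds, use.names = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate core gene in genome ", genome_id, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(genes) < 2L)
    stop("need at least 2 core genes to extract links")
  links <- if (circular) orderLinks(genes, circular = TRUE)
  else unlist(lapply(scaffolds, orderLinks, circular = FALSE))
  new("LinkSet", genomeId = genome_id,
      links = unique(as.character(links)))
}

#' Synteny index between two link sets
#'
#' SI = |A intersect B| / max(|A|, |B|): the proportion of adjacency
#' links conserved between two genomes, from 0 (no link conserved) to 1
#' (fully conserved synteny). The maximum denominator keeps SI(x, x) = 1
#' while preventing missing data from inflating similarity.
#'
#' @param linksA,linksB \code{\link{LinkSet}} objects or canonical link
#'   character vectors.
#' @return SI in [0, 1].
#' @export
syntenyIndex <- function(linksA, linksB) {
  a <- if (is(linksA, "LinkSet")) linkStrings(linksA) else linksA
  b <- if (is(linksB, "LinkSet")) linkStrings(linksB) else linksB
  if (!length(a) || !length(b)) stop("empty link set")
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Pairwise synteny-index matrix
#'
#' @param link_sets named list of \code{\link{LinkSet}} objects.
#' @return symmetric SI matrix (diagonal 1).
#' @export
siMatrix <- function(link_sets) {
  ids <- names(link_sets)
  n <- length(ids)
  S <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    S[i, j] <- S[j, i] <- syntenyIndex(link_sets[[i]], link_sets[[j]])
  S
}

#' Ordered core genes per scaffold for one genome
#'
#' Restricts a genome's gene calls to panel genes scored present for it
#' and returns, per scaffold, the gene ids ordered by start coordinate.
#' Scaffolds without core genes are dropped.
#'
#' @param genecalls gene-call data.frame.
#' @param panel a \code{\link{CoreGenePanel}}.
#' @param genome_id genome to extract.
#' @return named list of character vectors (scaffold -> ordered genes).
#' @export
coreScaffoldOrders <- function(genecalls, panel, genome_id) {
  pres <- presenceCalls(panel)
  mine <- genecalls[genecalls$genome_id == genome_id &
                      genecalls$func %in% geneIds(panel) &
                      !genecalls$partial, , drop = FALSE]
  if (genome_id %in% rownames(pres)) {
    ok <- geneIds(panel)[pres[genome_id, ] == "present"]
    mine <- mine[mine$func %in% ok, , drop = FALSE]
  }
  mine <- mine[!duplicated(paste(mine$func)), , drop = FALSE]
  sc <- split(mine, mine$scaffold_id)
  out <- lapply(sc, function(s) s$func[order(s$start)])
  out[vapply(out, length, integer(1)) > 0L]
}

#' Score and order draft scaffolds against a reference gene order
#'
#' Each scaffold scores the mean rank of its core genes in the
#' reference order, taken on the circle (circular mean of ranks), so
#' that a scaffold spanning the arbitrary linearization origin of the
#' reference chromosome still scores at its true arc midpoint; for
#' scaffolds that do not wrap the origin this equals the plain mean
#' rank. Scaffolds are sorted by ascending score (ties broken by
#' scaffold id); scaffolds with no gene shared with the reference are
#' flagged and excluded from the inferred order.
#'
#' @param scaffold_orders named list (scaffold -> ordered core genes).
#' @param reference_order character: the reference circular gene order.
#' @return data.frame(scaffold, score, n_core, has_core) sorted by score.
#' @export
scoreScaffolds <- function(scaffold_orders, reference_order) {
  n <- length(reference_order)
  ranks <- setNames(seq_along(reference_order), reference_order)
  circMean <- function(r) {
    th <- 2 * pi * (r - 1) / n
    s <- mean(sin(th)); c <- mean(cos(th))
    if (sqrt(s^2 + c^2) < 1e-8) return(mean(r))  # degenerate spread
    (atan2(s, c) / (2 * pi) * n) %% n + 1
  }
  tab <- data.frame(
    scaffold = names(scaffold_orders),
    score = vapply(scaffold_orders, function(g) {
      r <- ranks[intersect(g, reference_order)]
      if (!length(r)) NA_real_ else circMean(r)
    }, numeric(1)),
    n_core = vapply(scaffold_orders, length, integer(1)),
    stringsAsFactors = FALSE)
  tab$has_core <- !is.na(tab$score)
  tab[order(tab$score, tab$scaffold, na.last = TRUE), , drop = FALSE]
}

# junction score of an oriented scaffold arrangement: number of
# junction adjacencies (including the circular closure) found in the
# reference link set
junctionScore <- function(orders, reversed, ref_links) {
  m <- length(orders)
  if (m < 2L) return(0L)
  firsts <- character(m); lasts <- character(m)
  for (k in seq_len(m)) {
    g <- if (reversed[k]) rev(orders[[k]]) else orders[[k]]
    firsts[k] <- g[1L]; lasts[k] <- g[length(g)]
  }
  junc <- canonicalLink(lasts, firsts[c(seq(2L, m), 1L)])
  sum(junc %in% ref_links)
}

#' Orient ordered scaffolds to maximize reference junction pairing
#'
#' A greedy left-to-right sweep (plus one refinement pass) flips
#' scaffolds, without touching within-scaffold gene order, so that as
#' many scaffold-junction adjacencies as possible (including the
#' circular closure) exist in the reference link set. Ties keep the
#' forward orientation.
#'
#' @param ordered_scaffolds named list (scaffold -> ordered genes), in
#'   final scaffold order.
#' @param reference_links \code{\link{LinkSet}} or canonical link
#'   vector of the reference.
#' @return logical vector: TRUE where a scaffold is reversed.
#' @export
orientScaffolds <- function(ordered_scaffolds, reference_links) {
  ref <- if (is(reference_links, "LinkSet"))
    linkStrings(reference_links) else reference_links
  m <- length(ordered_scaffolds)
  rev_flags <- rep(FALSE, m)
  if (m < 2L) return(rev_flags)
  for (pass in 1:2) for (k in seq_len(m)) {
    keep <- rev_flags
    flip <- rev_flags; flip[k] <- !flip[k]
    if (junctionScore(ordered_scaffolds, flip, ref) >
        junctionScore(ordered_scaffolds, keep, ref))
      rev_flags <- flip
  }
  rev_flags
}

# assemble a SyntenyConfiguration from ordered+oriented scaffolds
buildConfiguration <- function(genome_id, scaffold_orders, score_tab,
                               rev_flags, best_reference = "",
                               si = NA_real_) {
  used <- score_tab$scaffold[score_tab$has_core]
  ord <- data.frame(scaffold = score_tab$scaffold,
                    orientation = "forward",
                    has_core = score_tab$has_core,
                    stringsAsFactors = FALSE)
  ord$orientation[match(used, ord$scaffold)] <-
    ifelse(rev_flags, "reverse", "forward")
  gene_order <- unlist(lapply(seq_along(used), function(k) {
    g <- scaffold_orders[[used[k]]]
    if (rev_flags[k]) rev(g) else g
  }), use.names = FALSE)
  new("SyntenyConfiguration", genomeId = genome_id,
      scaffoldOrder = ord, geneOrder = as.character(gene_order),
      bestReference = best_reference, si = si)
}

#' Reorder and reorient a draft genome against a reference pool
#'
#' For every reference in the pool, the draft's scaffolds are ordered by
#' mean reference rank and oriented by junction pairing; the candidate
#' configuration's circular link set is compared with the reference by
#' synteny index, and the configuration with the highest SI is kept
#' (ties broken by reference id order).
#'
#' @param scaffold_orders named list (scaffold -> ordered core genes)
#'   of the draft.
#' @param reference_pool named list of circular gene orders (character
#'   vectors) or \code{\link{SyntenyConfiguration}} objects.
#' @param genome_id draft genome id.
#' @return the chosen \code{\link{SyntenyConfiguration}}.
#' @export
reorderDraft <- function(scaffold_orders, reference_pool,
                         genome_id = "draft") {
  if (!length(reference_pool)) stop("reference pool is empty")
  if (!length(scaffold_orders))
    stop("draft ", genome_id, " has no core genes")
  best <- NULL
  for (rid in sort(names(reference_pool))) {
    refc <- reference_pool[[rid]]
    ref_order <- if (is(refc, "SyntenyConfiguration")) geneOrder(refc)
      else refc
    ref_links <- orderLinks(ref_order, circular = TRUE)
    tab <- scoreScaffolds(scaffold_orders, ref_order)
    used <- tab$scaffold[tab$has_core]
    if (!length(used)) next
    ordered <- scaffold_orders[used]
    rev_flags <- orientScaffolds(ordered, ref_links)
    cfg <- buildConfiguration(genome_id, scaffold_orders, tab,
                              rev_flags, best_reference = rid)
    si <- syntenyIndex(orderLinks(geneOrder(cfg), circular = TRUE),
                       ref_links)
    cfg@si <- si
    if (is.null(best) || si > referenceSI(best)) best <- cfg
  }
  if (is.null(best))
    stop("draft ", genome_id, " shares no core genes with any reference")
  best
}

#' Reorder all draft genomes against a growing reference pool
#'
#' Complete genomes seed the pool; drafts are processed in decreasing
#' completeness (descending N50, ties by fewer scaffolds, then genome
#' id) and each accepted configuration joins the pool before the next
#' draft, so highly fragmented genomes see the most references.
#'
#' @param draft_orders named list: genome id -> scaffold-order list.
#' @param complete_orders named list: genome id -> circular gene order.
#' @param completeness data.frame(genome_id, n50, n_scaffolds) covering
#'   the drafts.
#' @return named list of \code{\link{SyntenyConfiguration}} objects for
#'   all genomes (complete genomes wrapped with SI = NA).
#' @export
reorderAll <- function(draft_orders, complete_orders, completeness) {
  if (!length(complete_orders)) stop("no complete genomes in pool")
  pool <- complete_orders
  configs <- list()
  for (gid in names(complete_orders)) {
    g <- complete_orders[[gid]]
    configs[[gid]] <- new("SyntenyConfiguration", genomeId = gid,
                          scaffoldOrder = data.frame(
                            scaffold = "scf_1", orientation = "forward",
                            has_core = TRUE, stringsAsFactors = FALSE),
                          geneOrder = as.character(g),
                          bestReference = "", si = NA_real_)
  }
  if (length(draft_orders)) {
    cm <- completeness[match(names(draft_orders),
                             completeness$genome_id), , drop = FALSE]
    ord <- order(-cm$n50, cm$n_scaffolds, cm$genome_id)
    for (gid in names(draft_orders)[ord]) {
      cfg <- reorderDraft(draft_orders[[gid]], pool, genome_id = gid)
      configs[[gid]] <- cfg
      pool[[gid]] <- geneOrder(cfg)
    }
  }
  configs
}

#' Link sets for a collection of synteny configurations
#'
#' @param configs named list of \code{\link{SyntenyConfiguration}}.
#' @return named list of \code{\link{LinkSet}} (circular closure
#'   included).
#' @export
configurationLinkSets <- function(configs) {
  out <- lapply(names(configs), function(gid)
    extractLinks(geneOrder(configs[[gid]]), circular = TRUE,
                 genome_id = gid))
  names(out) <- names(configs)
  out
}

#' Binary link-occurrence matrix over genomes
#'
#' @param link_sets named list of \code{\link{LinkSet}}.
#' @return binary integer matrix (genomes x links).
#' @export
linkOccurrenceMatrix <- function(link_sets) {
  all_links <- sort(unique(unlist(lapply(link_sets, linkStrings))))
  m <- t(vapply(link_sets, function(ls)
    as.integer(all_links %in% linkStrings(ls)),
    integer(length(all_links))))
  dimnames(m) <- list(names(link_sets), all_links)
  m
}

#' Species-level link occurrence
#'
#' A link is scored present in a species when at least one member
#' genome carries it.
#'
#' @param link_matrix genome x link binary matrix.
#' @param assignment a \code{\link{SpeciesAssignment}}.
#' @return binary integer matrix (species x links).
#' @export
speciesLinkOccurrence <- function(link_matrix, assignment) {
  sp <- speciesOf(assignment)
  groups <- split(rownames(link_matrix), sp[rownames(link_matrix)])
  m <- t(vapply(groups, function(g)
    as.integer(colSums(link_matrix[g, , drop = FALSE]) >= 1L),
    integer(ncol(link_matrix))))
  colnames(m) <- colnames(link_matrix)
  m
}

#' Majority-rule consensus architecture network
#'
#' A link is retained when its species frequency strictly exceeds the
#' majority threshold in at least one group. Edges carry the per-group
#' frequency vector and the gene pair.
#'
#' @param species_links species x link binary matrix.
#' @param species_groups named character: species id -> group label.
#' @param majority strict frequency threshold (default 0.50).
#' @return data.frame(link, gene_a, gene_b, freq_<group>..., kept
#'   groups) of retained edges; discarded count in attribute
#'   \code{"n_discarded"}.
#' @export
consensusNetwork <- function(species_links, species_groups,
                             majority = 0.50) {
  groups <- sort(unique(species_groups))
  freq <- vapply(groups, function(g) {
    spp <- intersect(names(species_groups)[species_groups == g],
                     rownames(species_links))
    colMeans(species_links[spp, , drop = FALSE])
  }, numeric(ncol(species_links)))
  if (is.null(dim(freq)))
    freq <- matrix(freq, ncol = length(groups),
                   dimnames = list(colnames(species_links), groups))
  keep <- apply(freq, 1L, function(f) any(f > majority))
  links <- colnames(species_links)[keep]
  pairs <- strsplit(links, "--", fixed = TRUE)
  out <- data.frame(link = links,
                    gene_a = vapply(pairs, `[`, character(1), 1L),
                    gene_b = vapply(pairs, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("freq_", g)]] <- freq[keep, g]
  out$dominant_groups <- apply(
    freq[keep, , drop = FALSE], 1L,
    function(f) paste(groups[f > majority], collapse = ","))
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Conserved-link profile along a reference chromosome
#'
#' The reference is the genome with the highest mean SI to all others
#' (ties: lexicographically smallest id). Its links are listed in
#' chromosomal order with per-species presence and per-group frequency.
#'
#' @param si symmetric SI matrix over genomes.
#' @param configs named list of \code{\link{SyntenyConfiguration}}.
#' @param species_links species x link binary matrix.
#' @param species_groups named character: species id -> group label.
#' @return list(reference, table): table has one row per reference link
#'   in chromosome order with freq_<group> columns.
#' @export
conservedLinkProfile <- function(si, configs, species_links,
                                 species_groups) {
  mean_si <- (rowSums(si) - 1) / (nrow(si) - 1)
  best <- sort(names(mean_si)[mean_si == max(mean_si)])[1]
  ord <- geneOrder(configs[[best]])
  ref_links <- orderLinks(ord, circular = TRUE)
  groups <- sort(unique(species_groups))
  tab <- data.frame(position = seq_along(ref_links), link = ref_links,
                    stringsAsFactors = FALSE)
  for (g in groups) {
    spp <- intersect(names(species_groups)[species_groups == g],
                     rownames(species_links))
    hit <- ref_links %in% colnames(species_links)
    f <- rep(0, length(ref_links))
    f[hit] <- colMeans(species_links[spp, ref_links[hit], drop = FALSE])
    tab[[paste0("freq_", g)]] <- f
  }
  tab$n_species <- rowSums(vapply(
    rownames(species_links),
    function(s) ref_links %in%
      colnames(species_links)[species_links[s, ] == 1L],
    logical(length(ref_links))))
  list(reference = best, table = tab)
}

#' Dot-plot coordinates for a pairwise synteny comparison
#'
#' @param configA,configB \code{\link{SyntenyConfiguration}} objects.
#' @return data.frame(gene, pos_a, pos_b) over the shared core genes.
#' @export
dotplotCoordinates <- function(configA, configB) {
  a <- geneOrder(configA); b <- geneOrder(configB)
  shared <- intersect(a, b)
  data.frame(gene = shared,
             pos_a = match(shared, a) / length(a),
             pos_b = match(shared, b) / length(b),
             stringsAsFactors = FALSE)
}
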