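#' Select candidate core genes by single-copy occupancy
#'
#' A gene qualifies as a candidate core gene when the fraction of
#' genomes carrying it in exactly one copy is at least the occupancy
#' threshold (default 90\%).
#'
#' @param matrix an \code{AnnotationMatrix}.
#' @param occupancy_threshold proportion in (0, 1].
#' @return character vector of candidate gene ids (column order).
#' @export
selectCandidates <- function(matrix, occupancy_threshold = 0.90) {
  if (!(occupancy_threshold > 0 && occupancy_threshold <= 1))
    stop("occupancy_threshold must be in (0, 1]")
  m <- countsMatrix(matrix)
  if (!length(m)) stop("empty annotation matrix")
  frac_single <- colMeans(m == 1L)
  colnames(m)[frac_single >= occupancy_threshold]
}

#' Expected per-gene nucleotide sizes from complete genomes
#'
#' For each candidate gene, the arithmetic mean length (bp) over its
#' single-copy occurrences in complete genomes. Candidates never seen in
#' single copy in any complete genome cannot be sized and are dropped
#' with a warning.
#'
#' @param genecalls gene-call data.frame (all genomes).
#' @param complete_genome_ids ids of complete (reference) genomes.
#' @param candidates candidate gene ids.
#' @return named numeric vector of expected sizes (unsizeable dropped).
#' @export
expectedGeneSizes <- function(genecalls, complete_genome_ids, candidates) {
  cc <- genecalls[genecalls$genome_id %in% complete_genome_ids &
                    genecalls$func %in% candidates, , drop = FALSE]
  sizes <- vapply(candidates, function(g) {
    sub <- cc[cc$func == g, , drop = FALSE]
    per_gen <- table(sub$genome_id)
    single <- names(per_gen)[per_gen == 1L]
    if (!length(single)) return(NA_real_)
    mean(nchar(sub$sequence[sub$genome_id %in% single]))
  }, numeric(1))
  names(sizes) <- candidates
  bad <- candidates[is.na(sizes)]
  if (length(bad))
    warning("unsizeable candidate(s) dropped (absent in single copy ",
            "from all complete genomes): ", paste(bad, collapse = ", "))
  sizes[!is.na(sizes)]
}

#' Apply normalized-size filters to candidate core genes
#'
#' Copy lengths are normalized by the expected size from complete
#' genomes, then three filters run in sequence: (i) a gene with two or
#' more copies each of normalized size > \code{dup_threshold} in any
#' genome is a true duplicate and leaves the panel; (ii) per genome,
#' copies below \code{lower} are discarded as fragments; a surviving
#' single copy above \code{upper} is scored missing; exactly one
#' surviving copy within [lower, upper] scores present; two or more
#' surviving copies (necessarily all <= dup_threshold) are ambiguous and
#' score missing; (iii) genes missing in at least
#' \code{max_missing_genomes} genomes leave the panel.
#'
#' @param candidates candidate gene ids.
#' @param genecalls gene-call data.frame (all genomes).
#' @param expected_sizes named numeric from
#'   \code{\link{expectedGeneSizes}}.
#' @param dup_threshold,upper,lower normalized-size thresholds
#'   (0 < lower < dup_threshold < upper).
#' @param max_missing_genomes missing-genome count triggering removal.
#' @param genome_ids genome universe (default: all in genecalls).
#' @return a \code{\link{CoreGenePanel}}.
#' @export
applySizeFilters <- function(candidates, genecalls, expected_sizes,
                             dup_threshold = 0.75, upper = 1.3,
                             lower = 0.7, max_missing_genomes = 4L,
                             genome_ids = NULL) {
  if (!(0 < lower && lower < dup_threshold && dup_threshold < upper))
    stop("thresholds must satisfy 0 < lower < dup_threshold < upper")
  if (is.null(genome_ids)) genome_ids <- sort(unique(genecalls$genome_id))
  candidates <- intersect(candidates, names(expected_sizes))
  if (!length(candidates))
    stop("no sizeable candidates to filter")
  gc <- genecalls[genecalls$func %in% candidates, , drop = FALSE]
  gc$nsize <- nchar(gc$sequence) / expected_sizes[gc$func]
  by_gene <- split(gc, factor(gc$func, levels = candidates))

  presence <- matrix("missing", nrow = length(genome_ids),
                     ncol = length(candidates),
                     dimnames = list(genome_ids, candidates))
  seqs <- setNames(vector("list", length(candidates)), candidates)
  decisions <- character(length(candidates))
  names(decisions) <- candidates

  for (g in candidates) {
    sub <- by_gene[[g]]
    seqs[[g]] <- character(0)
    if (is.null(sub) || nrow(sub) == 0L) {
      decisions[g] <- "absent everywhere"
      next
    }
    dup <- FALSE
    for (gid in unique(sub$genome_id)) {
      rows <- sub[sub$genome_id == gid, , drop = FALSE]
      if (sum(rows$nsize > dup_threshold) >= 2L) { dup <- TRUE; break }
    }
    if (dup) {
      decisions[g] <- "removed: true duplicate"
      next
    }
    for (gid in intersect(genome_ids, unique(sub$genome_id))) {
      rows <- sub[sub$genome_id == gid, , drop = FALSE]
      surv <- rows[rows$nsize >= lower, , drop = FALSE]
      if (nrow(surv) == 1L && surv$nsize <= upper) {
        presence[gid, g] <- "present"
        seqs[[g]][[gid]] <- surv$sequence
      }
      # 0 survivors, an oversized single copy, or >=2 surviving
      # sub-threshold copies all score missing
    }
    decisions[g] <- "kept after size filters"
  }

  kept1 <- candidates[!startsWith(decisions, "removed") &
                        decisions != "absent everywhere"]
  n_missing <- colSums(presence[, kept1, drop = FALSE] == "missing")
  final <- kept1[n_missing < max_missing_genomes]
  decisions[setdiff(kept1, final)] <- "removed: missing in too many genomes"

  prov <- data.frame(gene = candidates, decision = unname(decisions),
                     stringsAsFactors = FALSE)
  new("CoreGenePanel", geneIds = final,
      expectedSize = expected_sizes[final],
      presence = presence[, final, drop = FALSE],
      sequences = seqs[final], provenance = prov)
}

#' Define the core-gene panel from an annotation matrix and gene calls
#'
#' Convenience wrapper chaining \code{\link{selectCandidates}},
#' \code{\link{expectedGeneSizes}} and \code{\link{applySizeFilters}}.
#'
#' @param matrix an \code{AnnotationMatrix}.
#' @param genecalls gene-call data.frame.
#' @param complete_genome_ids reference (complete) genome ids.
#' @param occupancy_threshold,dup_threshold,upper,lower,max_missing_genomes
#'   filter thresholds; see the component functions.
#' @return a \code{\link{CoreGenePanel}}.
#' @export
defineCorePanel <- function(matrix, genecalls, complete_genome_ids,
                            occupancy_threshold = 0.90,
                            dup_threshold = 0.75, upper = 1.3,
                            lower = 0.7, max_missing_genomes = 4L) {
  cand <- selectCandidates(matrix, occupancy_threshold)
  sizes <- expectedGeneSizes(genecalls, complete_genome_ids, cand)
  applySizeFilters(cand, genecalls, sizes, dup_threshold, upper, lower,
                   max_missing_genomes,
                   genome_ids = rownames(countsMatrix(matrix)))
}
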