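#' Round an average gene occurrence to 0, 1 or 2 copies
#'
#' Breaks: 0 when n < 0.5, 1 when 0.5 <= n < 1.5, 2 when n >= 1.5 (the
#' last break closes the gap between 1.5 and 2 conservatively upward).
#'
#' @param n numeric average occurrence(s).
#' @return integer vector of rounded copies in \{0, 1, 2\}.
#' @export
roundOccurrence <- function(n) {
  ifelse(n < 0.5, 0L, ifelse(n < 1.5, 1L, 2L))
}

#' Species-averaged gene occurrence profiles
#'
#' For each species, the mean copy count of every annotation across its
#' member genomes, rounded to 0/1/2 via \code{\link{roundOccurrence}}.
#'
#' @param matrix an \code{AnnotationMatrix} (genomes x functions).
#' @param assignment a \code{\link{SpeciesAssignment}}.
#' @return integer matrix species x functions of rounded occurrences.
#' @export
speciesOccurrenceProfile <- function(matrix, assignment) {
  m <- countsMatrix(matrix)
  sp <- speciesOf(assignment)
  if (!all(rownames(m) %in% names(sp)))
    stop("unassigned genome(s): ",
         paste(setdiff(rownames(m), names(sp)), collapse = ", "))
  groups <- split(rownames(m), sp[rownames(m)])
  out <- t(vapply(groups, function(g)
    roundOccurrence(colMeans(m[g, , drop = FALSE])),
    integer(ncol(m))))
  colnames(out) <- colnames(m)
  out
}

#' Bray-Curtis dissimilarity between two occurrence profiles
#'
#' BC = sum|x - y| / sum(x + y), optionally after a per-profile
#' Hellinger transformation (square root of relative abundances), which
#' damps the influence of inflated copy numbers from fragmented
#' assemblies.
#'
#' @param profileA,profileB non-negative numeric vectors over the same
#'   gene universe.
#' @param hellinger apply the Hellinger transformation first.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(profileA, profileB, hellinger = TRUE) {
  if (length(profileA) != length(profileB))
    stop("profiles must share the same gene universe")
  if (sum(profileA) == 0 && sum(profileB) == 0)
    stop("both profiles are all-zero")
  m <- rbind(profileA, profileB)
  if (hellinger) m <- vegan::decostand(m, method = "hellinger")
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param profiles numeric matrix (units x genes): genome counts or
#'   species occurrence profiles, or an \code{AnnotationMatrix}.
#' @param hellinger apply the Hellinger transformation per row.
#' @return symmetric dissimilarity matrix with unit names.
#' @export
brayCurtisMatrix <- function(profiles, hellinger = TRUE) {
  if (is(profiles, "AnnotationMatrix")) profiles <- countsMatrix(profiles)
  m <- profiles
  if (hellinger) m <- vegan::decostand(m, method = "hellinger")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

# one random genome per species for the given species ids
drawGenomesPerSpecies <- function(species_ids, members) {
  vapply(species_ids, function(s) {
    g <- members[[s]]
    if (length(g) == 1L) g else sample(g, 1L)
  }, character(1))
}

#' Pan/core rarefaction with one-genome-per-species resampling
#'
#' Per group and replicate: a random species order is drawn, one random
#' genome per species is sampled, and genomes are accumulated 1..N
#' (nested within the replicate, so each replicate's pan curve is
#' non-decreasing and its core curve non-increasing). Pan counts genes
#' present in at least one copy in at least one accumulated genome;
#' core counts genes present in exactly one copy in every accumulated
#' genome. Means and standard deviations are taken across replicates.
#'
#' @param matrix an \code{AnnotationMatrix}.
#' @param assignment a \code{\link{SpeciesAssignment}}.
#' @param species_groups named character: species id -> group label.
#' @param n_max maximum number of species to accumulate (truncated with
#'   a warning to the species count of each group).
#' @param replicates number of resampling replicates.
#' @param seed integer seed.
#' @return data.frame(group, n, pan_mean, pan_sd, core_mean, core_sd).
#' @export
rarefyPanCore <- function(matrix, assignment, species_groups,
                          n_max = NULL, replicates = 100L, seed = 1L) {
  m <- countsMatrix(matrix)
  sp <- speciesOf(assignment)
  members <- split(names(sp), sp)
  set.seed(seed)
  out <- list()
  for (grp in unique(species_groups)) {
    spp <- names(species_groups)[species_groups == grp]
    spp <- intersect(spp, names(members))
    if (!length(spp)) next
    N <- if (is.null(n_max)) length(spp) else n_max
    if (N > length(spp)) {
      warning("group ", grp, ": n_max truncated to ", length(spp),
              " species")
      N <- length(spp)
    }
    pan <- matrix(0L, replicates, N)
    core <- matrix(0L, replicates, N)
    for (r in seq_len(replicates)) {
      ord <- if (length(spp) == 1L) spp else sample(spp)
      picks <- drawGenomesPerSpecies(ord, members)
      sub <- m[picks, , drop = FALSE]
      any_cum <- rep(FALSE, ncol(m))
      one_cum <- rep(TRUE, ncol(m))
      for (k in seq_len(N)) {
        row <- sub[k, ]
        any_cum <- any_cum | (row >= 1L)
        one_cum <- one_cum & (row == 1L)
        pan[r, k] <- sum(any_cum)
        core[r, k] <- sum(one_cum)
      }
    }
    out[[grp]] <- data.frame(
      group = grp, n = seq_len(N),
      pan_mean = colMeans(pan), pan_sd = apply(pan, 2L, sd),
      core_mean = colMeans(core), core_sd = apply(core, 2L, sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# exclusive Venn regions over a list of per-group gene sets
vennRegions <- function(sets) {
  gl <- names(sets)
  subsets <- unlist(lapply(seq_along(gl), function(k)
    utils::combn(gl, k, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(subsets, function(s) {
    inside <- Reduce(intersect, sets[s])
    outside <- unique(unlist(sets[setdiff(gl, s)]))
    length(setdiff(inside, outside))
  }, numeric(1))
  names(counts) <- vapply(subsets, paste, character(1), collapse = "&")
  counts
}

#' Venn-region gene-content overlap among groups at fixed species depth
#'
#' Per replicate, a fixed number of species (default 15) is sampled per
#' group; each group's pan set (genes with rounded occurrence >= 1 in at
#' least one sampled species) and core set (rounded occurrence exactly 1
#' in every sampled species) are intersected into all exclusive Venn
#' regions (15 regions for 4 groups). Groups with fewer species than
#' requested contribute their full species set, with a warning.
#'
#' @param matrix an \code{AnnotationMatrix}.
#' @param assignment a \code{\link{SpeciesAssignment}}.
#' @param species_groups named character: species id -> group label.
#' @param species_per_group species sampled per group and replicate.
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @return list(pan, core): data.frames (region, mean, sd).
#' @export
vennOverlap <- function(matrix, assignment, species_groups,
                        species_per_group = 15L, replicates = 100L,
                        seed = 1L) {
  groups <- unique(species_groups)
  if (length(groups) < 2L) stop("vennOverlap needs at least 2 groups")
  prof <- speciesOccurrenceProfile(matrix, assignment)
  genes <- colnames(prof)
  set.seed(seed)
  by_group <- lapply(groups, function(g) {
    spp <- intersect(names(species_groups)[species_groups == g],
                     rownames(prof))
    if (length(spp) < species_per_group)
      warning("group ", g, " has only ", length(spp),
              " species; using all of them")
    spp
  })
  names(by_group) <- groups
  pan_acc <- list(); core_acc <- list()
  for (r in seq_len(replicates)) {
    pan_sets <- list(); core_sets <- list()
    for (g in groups) {
      spp <- by_group[[g]]
      take <- if (length(spp) > species_per_group)
        sample(spp, species_per_group) else spp
      sub <- prof[take, , drop = FALSE]
      pan_sets[[g]] <- genes[colSums(sub >= 1L) >= 1L]
      core_sets[[g]] <- genes[colSums(sub == 1L) == nrow(sub)]
    }
    pan_acc[[r]] <- vennRegions(pan_sets)
    core_acc[[r]] <- vennRegions(core_sets)
  }
  summarize <- function(acc) {
    m <- do.call(rbind, acc)
    data.frame(region = colnames(m), mean = colMeans(m),
               sd = apply(m, 2L, sd), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  list(pan = summarize(pan_acc), core = summarize(core_acc))
}

#' Export a binary occurrence matrix as pseudo-FASTA
#'
#' One record per unit (genome or species) whose "sequence" is the 0/1
#' presence string over a fixed gene order, suitable as input for an
#' external binary-model tree search; the column order is written to a
#' sidecar file so the matrix round-trips.
#'
#' @param occurrence matrix (units x genes) of counts or presence; any
#'   value >= 1 encodes presence.
#' @param path pseudo-FASTA output path.
#' @param sidecar column-map output path (default: path + ".columns").
#' @return invisibly, list(path, sidecar).
#' @export
exportBinaryMatrix <- function(occurrence, path,
                               sidecar = paste0(path, ".columns")) {
  if (is(occurrence, "AnnotationMatrix"))
    occurrence <- countsMatrix(occurrence)
  bin <- ifelse(occurrence >= 1L, "1", "0")
  rows <- apply(bin, 1L, paste, collapse = "")
  con <- file(path, "w")
  writeLines(paste0(">", rownames(occurrence), "\n", rows, collapse = "\n"),
             con)
  close(con)
  writeLines(colnames(occurrence), sidecar)
  invisible(list(path = path, sidecar = sidecar))
}

#' Re-import a pseudo-FASTA binary matrix written by
#' \code{\link{exportBinaryMatrix}}
#'
#' @param path pseudo-FASTA path.
#' @param sidecar column-map path.
#' @return binary integer matrix (units x genes).
#' @export
readBinaryMatrix <- function(path, sidecar = paste0(path, ".columns")) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  rows <- lines[!hdr]
  genes <- readLines(sidecar)
  m <- t(vapply(rows, function(r)
    as.integer(seqChars(r)), integer(length(genes))))
  dimnames(m) <- list(ids, genes)
  m
}
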