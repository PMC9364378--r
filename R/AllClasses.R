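#' @import methods
#' @importFrom stats sd setNames rbinom rpois runif
#' @importFrom utils read.delim write.table head tail
NULL

#' AnnotationMatrix: genome-by-function copy-count matrix
#'
#' Rows are genomes, columns are unique annotation (function) strings,
#' cells are copy counts. Function strings matching the exclusion
#' patterns (case-insensitive) are removed at construction.
#'
#' @slot counts integer matrix, genomes x functions.
#' @slot exclusions character, patterns excluded from the columns.
#' @exportClass AnnotationMatrix
setClass("AnnotationMatrix",
  representation(counts = "matrix", exclusions = "character"))

setValidity("AnnotationMatrix", function(object) {
  m <- object@counts
  if (length(m) && (any(m < 0) || any(m != round(m))))
    return("cell values must be non-negative integers")
  if (length(colnames(m)) &&
      any(tolower(colnames(m)) %in% tolower(object@exclusions)))
    return("an excluded function appears as a column")
  TRUE
})

#' @describeIn AnnotationMatrix copy-count matrix accessor
#' @param x an AnnotationMatrix
#' @export
countsMatrix <- function(x) x@counts

#' @describeIn AnnotationMatrix exclusion patterns accessor
#' @export
exclusionPatterns <- function(x) x@exclusions

setMethod("show", "AnnotationMatrix", function(object) {
  cat("AnnotationMatrix:", nrow(object@counts), "genomes x",
      ncol(object@counts), "functions\n")
  cat("  exclusions:", paste(object@exclusions, collapse = "; "), "\n")
})

#' CoreGenePanel: the filtered single-copy core-gene set
#'
#' @slot geneIds ordered character vector of function strings in the panel.
#' @slot expectedSize named numeric, per-gene mean nucleotide length (bp)
#'   among complete genomes.
#' @slot presence character matrix genomes x genes with values
#'   "present"/"missing".
#' @slot sequences list (per gene) of named character vectors of the
#'   retained full-length nucleotide sequences (names = genome ids).
#' @slot provenance data.frame of per-gene filter decisions.
#' @exportClass CoreGenePanel
setClass("CoreGenePanel",
  representation(geneIds = "character", expectedSize = "numeric",
                 presence = "matrix", sequences = "list",
                 provenance = "data.frame"))

setValidity("CoreGenePanel", function(object) {
  if (length(object@geneIds) &&
      !identical(sort(object@geneIds), sort(colnames(object@presence))))
    return("presence columns must match geneIds")
  if (length(object@presence) &&
      !all(object@presence %in% c("present", "missing")))
    return("presence calls must be 'present' or 'missing'")
  TRUE
})

#' @describeIn CoreGenePanel panel gene identifiers
#' @param x a CoreGenePanel
#' @export
geneIds <- function(x) x@geneIds

#' @describeIn CoreGenePanel expected per-gene sizes (bp)
#' @export
expectedSizes <- function(x) x@expectedSize

#' @describeIn CoreGenePanel genomes x genes presence matrix
#' @export
presenceCalls <- function(x) x@presence

#' @describeIn CoreGenePanel per-gene named sequence vectors
#' @export
panelSequences <- function(x) x@sequences

setMethod("show", "CoreGenePanel", function(object) {
  cat("CoreGenePanel:", length(object@geneIds), "core genes across",
      nrow(object@presence), "genomes\n")
  if (length(object@presence)) {
    miss <- sum(object@presence == "missing")
    cat("  missing calls:", miss, "of", length(object@presence), "\n")
  }
})

#' GeneAlignment: codon-respecting nucleotide alignment of one core gene
#'
#' @slot geneId gene (function string) identifier.
#' @slot sequences named character vector of aligned nucleotide rows
#'   (equal length, multiple of 3; gaps "-" in whole codons).
#' @slot missingGenomes genomes with no usable sequence for this gene.
#' @exportClass GeneAlignment
setClass("GeneAlignment",
  representation(geneId = "character", sequences = "character",
                 missingGenomes = "character"))

setValidity("GeneAlignment", function(object) {
  if (length(object@sequences)) {
    w <- unique(nchar(object@sequences))
    if (length(w) != 1L) return("aligned rows must have equal length")
    if (w %% 3L != 0L) return("alignment length must be a codon multiple")
  }
  TRUE
})

#' @describeIn GeneAlignment aligned rows (named character vector)
#' @param x a GeneAlignment
#' @export
alignedSequences <- function(x) x@sequences

#' @describeIn GeneAlignment genomes missing from the alignment
#' @export
missingGenomes <- function(x) x@missingGenomes

setMethod("show", "GeneAlignment", function(object) {
  cat("GeneAlignment", object@geneId, ":", length(object@sequences),
      "rows x", if (length(object@sequences))
        nchar(object@sequences[[1]]) else 0L, "columns\n")
})

#' Supermatrix: N-filled concatenation of trimmed core-gene alignments
#'
#' @slot sequences named character vector, one concatenated row per genome.
#' @slot partitions data.frame(gene, start, end): 1-based inclusive column
#'   ranges of each gene in the concatenation.
#' @exportClass Supermatrix
setClass("Supermatrix",
  representation(sequences = "character", partitions = "data.frame"))

setValidity("Supermatrix", function(object) {
  if (length(object@sequences)) {
    w <- unique(nchar(object@sequences))
    if (length(w) != 1L) return("rows must have equal length")
    if (nrow(object@partitions) &&
        w != sum(object@partitions$end - object@partitions$start + 1L))
      return("row length must equal total partition length")
  }
  TRUE
})

#' @describeIn Supermatrix concatenated rows
#' @param x a Supermatrix
#' @export
supermatrixSequences <- function(x) x@sequences

#' @describeIn Supermatrix per-gene partition table
#' @export
partitionTable <- function(x) x@partitions

setMethod("show", "Supermatrix", function(object) {
  cat("Supermatrix:", length(object@sequences), "genomes x",
      if (length(object@sequences)) nchar(object@sequences[[1]]) else 0L,
      "bp in", nrow(object@partitions), "gene partitions\n")
})

#' SpeciesAssignment: PNS-delimited species and their labels
#'
#' @slot genomeSpecies named character: genome id -> species id.
#' @slot speciesTable data.frame(species, name, status, group, n_genomes).
#' @exportClass SpeciesAssignment
setClass("SpeciesAssignment",
  representation(genomeSpecies = "character", speciesTable = "data.frame"))

setValidity("SpeciesAssignment", function(object) {
  if (length(object@genomeSpecies) && nrow(object@speciesTable) &&
      !all(object@genomeSpecies %in% object@speciesTable$species))
    return("every genome's species must appear in the species table")
  TRUE
})

#' @describeIn SpeciesAssignment genome -> species map
#' @param x a SpeciesAssignment
#' @export
speciesOf <- function(x) x@genomeSpecies

#' @describeIn SpeciesAssignment species summary table
#' @export
speciesTable <- function(x) x@speciesTable

setMethod("show", "SpeciesAssignment", function(object) {
  st <- object@speciesTable
  cat("SpeciesAssignment:", length(object@genomeSpecies), "genomes in",
      nrow(st), "species")
  if (nrow(st) && "status" %in% names(st))
    cat(" (", sum(st$status == "described"), "described,",
        sum(st$status == "candidate"), "candidate)")
  cat("\n")
})

#' LinkSet: unordered core-gene adjacencies of one genome
#'
#' Links are canonical "geneA--geneB" strings with the two gene ids in
#' sorted order, so identical adjacencies compare equal across genomes.
#'
#' @slot genomeId genome identifier.
#' @slot links character vector of canonical link strings.
#' @exportClass LinkSet
setClass("LinkSet",
  representation(genomeId = "character", links = "character"))

setValidity("LinkSet", function(object) {
  if (anyDuplicated(object@links)) return("duplicate links")
  parts <- strsplit(object@links, "--", fixed = TRUE)
  if (length(parts) && any(vapply(parts, function(p)
        length(p) != 2L || p[1] >= p[2], logical(1))))
    return("links must be canonical 'a--b' with a < b and no self-pairs")
  TRUE
})

#' @describeIn LinkSet canonical link strings
#' @param x a LinkSet
#' @export
linkStrings <- function(x) x@links

#' @describeIn LinkSet number of links (N)
#' @export
nLinks <- function(x) length(x@links)

setMethod("show", "LinkSet", function(object) {
  cat("LinkSet", object@genomeId, ":", length(object@links), "links\n")
})

#' SyntenyConfiguration: ordered, oriented scaffolds of a draft genome
#'
#' @slot genomeId genome identifier.
#' @slot scaffoldOrder data.frame(scaffold, orientation) with orientation
#'   "forward"/"reverse"; scaffolds without core genes are flagged in a
#'   `has_core` column and excluded from the inferred order.
#' @slot geneOrder character: implied circular core-gene order.
#' @slot bestReference id of the reference the configuration was chosen
#'   against ("" for complete genomes).
#' @slot si synteny index against the best reference (NA for complete).
#' @exportClass SyntenyConfiguration
setClass("SyntenyConfiguration",
  representation(genomeId = "character", scaffoldOrder = "data.frame",
                 geneOrder = "character", bestReference = "character",
                 si = "numeric"))

setValidity("SyntenyConfiguration", function(object) {
  if (anyDuplicated(object@geneOrder))
    return("circular gene order must be a permutation (no duplicates)")
  TRUE
})

#' @describeIn SyntenyConfiguration implied circular core-gene order
#' @param x a SyntenyConfiguration
#' @export
geneOrder <- function(x) x@geneOrder

#' @describeIn SyntenyConfiguration scaffold order/orientation table
#' @export
scaffoldOrder <- function(x) x@scaffoldOrder

#' @describeIn SyntenyConfiguration chosen reference genome id
#' @export
bestReference <- function(x) x@bestReference

#' @describeIn SyntenyConfiguration synteny index vs the best reference
#' @export
referenceSI <- function(x) x@si

setMethod("show", "SyntenyConfiguration", function(object) {
  cat("SyntenyConfiguration", object@genomeId, ":",
      length(object@geneOrder), "core genes on",
      nrow(object@scaffoldOrder), "scaffolds")
  if (nzchar(object@bestReference))
    cat("; best reference", object@bestReference,
        sprintf("(SI = %.3f)", object@si))
  cat("\n")
})
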