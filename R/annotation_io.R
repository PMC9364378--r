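#' Default annotation exclusion patterns
#'
#' Function strings removed before building abundance matrices and
#' summary statistics: hypothetical proteins, repeat regions and mobile
#' element proteins (matched case-insensitively).
#' @export
defaultExclusions <- function() {
  c("hypothetical protein", "repeat region", "mobile element protein")
}

# Case-insensitive exclusion match. `substring_match` relaxes to a
# substring test (annotation services vary in suffixes/whitespace).
isExcluded <- function(funcs, exclusions, substring_match = FALSE) {
  f <- tolower(trimws(funcs))
  e <- tolower(trimws(exclusions))
  if (!substring_match) return(f %in% e)
  Reduce(`|`, lapply(e, function(p) grepl(p, f, fixed = TRUE)),
         rep(FALSE, length(f)))
}

#' Read a RAST-dialect tab-separated annotation table
#'
#' Expects the columns contig_id, feature_id, type, start, stop, strand,
#' function and nucleotide_sequence (header required). Minus-strand rows
#' exported with start > stop are normalized to start <= stop. Rows
#' lacking a nucleotide sequence are retained with an empty sequence and
#' flagged \code{partial}.
#'
#' @param path path to the table.
#' @param genome_id genome identifier to attach (default: file stem).
#' @return gene-call data.frame (genome_id, scaffold_id, feature_id,
#'   type, start, stop, strand, func, sequence, partial).
#' @export
readRastTable <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.rast\\.tsv$|\\.tsv$", "", basename(path))
  tab <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("contig_id", "feature_id", "type", "start", "stop",
              "strand", "function", "nucleotide_sequence")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("annotation table has a header but no rows: ", path)
    return(data.frame(genome_id = character(0),
                      scaffold_id = character(0),
                      feature_id = character(0), type = character(0),
                      start = integer(0), stop = integer(0),
                      strand = character(0), func = character(0),
                      sequence = character(0), partial = logical(0),
                      stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.integer(tab$start))
  stop_ <- suppressWarnings(as.integer(tab$stop))
  bad <- which(is.na(start) | is.na(stop_))
  if (length(bad))
    stop("malformed coordinates at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  seqs <- tab$nucleotide_sequence
  seqs[is.na(seqs)] <- ""
  data.frame(genome_id = genome_id, scaffold_id = tab$contig_id,
             feature_id = tab$feature_id, type = tab$type,
             start = pmin(start, stop_), stop = pmax(start, stop_),
             strand = tab$strand, func = tab[["function"]],
             sequence = seqs, partial = !nzchar(seqs),
             stringsAsFactors = FALSE)
}

#' Build a genome-by-function annotation abundance matrix
#'
#' Cell (g, f) counts the calls with function f in genome g, after
#' removing functions matching the exclusion patterns (case-insensitive
#' exact match by default).
#'
#' @param genecalls gene-call data.frame (one or many genomes).
#' @param exclusions character patterns; see
#'   \code{\link{defaultExclusions}}.
#' @param substring_match relax exclusion matching to substrings.
#' @return an \code{AnnotationMatrix}.
#' @export
buildAnnotationMatrix <- function(genecalls,
                                  exclusions = defaultExclusions(),
                                  substring_match = FALSE) {
  if (is.null(genecalls) || nrow(genecalls) == 0L)
    return(new("AnnotationMatrix",
               counts = matrix(integer(0), 0, 0),
               exclusions = exclusions))
  keep <- !isExcluded(genecalls$func, exclusions, substring_match)
  gc <- genecalls[keep, , drop = FALSE]
  genomes <- unique(genecalls$genome_id)
  funcs <- sort(unique(gc$func))
  m <- table(factor(gc$genome_id, levels = genomes),
             factor(gc$func, levels = funcs))
  counts <- matrix(as.integer(m), nrow = length(genomes),
                   dimnames = list(genomes, funcs))
  new("AnnotationMatrix", counts = counts, exclusions = exclusions)
}

#' Per-genome summary statistics from gene calls
#'
#' Coding genome size, annotation counts, unique annotation count, mean
#' copy number and GC content. Copy number and unique counts exclude the
#' configured patterns; GC is computed over the concatenated coding
#' sequences of all calls; the mobile-element count tallies the excluded
#' "Mobile element protein" rows.
#'
#' @param genecalls gene calls of a single genome.
#' @param exclusions exclusion patterns.
#' @return list (GenomeStats): coding_size, n_annotations,
#'   n_unique_annotations, mean_copy_number, n_mobile_elements,
#'   gc_content.
#' @export
genomeSummary <- function(genecalls, exclusions = defaultExclusions()) {
  if (length(unique(genecalls$genome_id)) > 1L)
    stop("genomeSummary expects calls from a single genome")
  seqs <- genecalls$sequence
  if (!any(nzchar(seqs))) stop("all sequences empty")
  excl <- isExcluded(genecalls$func, exclusions)
  kept <- genecalls$func[!excl]
  nt <- sum(nchar(seqs))
  gc_n <- sum(vapply(seqs, function(s)
    sum(seqChars(s) %in% c("G", "C", "g", "c")), numeric(1)))
  list(coding_size = nt,
       n_annotations = nrow(genecalls),
       n_unique_annotations = length(unique(kept)),
       mean_copy_number = if (length(kept))
         length(kept) / length(unique(kept)) else NA_real_,
       n_mobile_elements = sum(isExcluded(genecalls$func,
                                          "mobile element protein")),
       gc_content = 100 * gc_n / nt)
}

#' Identify complete genomes by assembly contiguity
#'
#' A genome qualifies as complete when its N50 exceeds the threshold
#' (default 3 Mb) or its metadata status is already "complete".
#'
#' @param metadata data.frame with genome_id, n50 and optionally status.
#' @param n50_min minimum N50 in bp.
#' @return character vector of complete genome ids.
#' @export
completeGenomes <- function(metadata, n50_min = 3e6) {
  ok <- metadata$n50 > n50_min
  if ("status" %in% names(metadata))
    ok <- ok | metadata$status == "complete"
  metadata$genome_id[ok]
}
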