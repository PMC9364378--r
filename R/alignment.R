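# Needleman-Wunsch global alignment of two residue strings.
# Linear gap penalty; deterministic traceback (diagonal > up > left).
needlemanWunsch <- function(a, b, match = 2L, mismatch = -1L,
                            gap = -2L) {
  av <- seqChars(a); bv <- seqChars(b)
  n <- length(av); m <- length(bv)
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- gap * 0:n
  S[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m))
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j], S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
  }
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] +
          (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  c(paste(ra, collapse = ""), paste(rb, collapse = ""))
}

#' Bundled deterministic toy protein aligner
#'
#' A star alignment around the longest input sequence (ties broken by
#' input order): every other sequence is aligned to the reference by
#' Needleman-Wunsch and insertion columns are merged into a common
#' coordinate system. Deterministic, dependency-free, and adequate for
#' the near-identical sequences this package aligns; any external
#' protein MSA tool can be plugged in through the same contract
#' (named character vector of residues in, equal-length aligned named
#' character vector out).
#'
#' @param aa named character vector of amino-acid sequences.
#' @return named character vector of aligned rows (equal length).
#' @export
toyAligner <- function(aa) {
  if (length(aa) <= 1L) return(aa)
  if (length(unique(nchar(aa))) == 1L) return(aa)  # no indels
  ref_i <- which.max(nchar(aa))
  ref <- aa[[ref_i]]
  L <- nchar(ref)
  others <- setdiff(seq_along(aa), ref_i)
  # ins[k]: insertion columns before reference position k (k = 1..L+1)
  ins_master <- integer(L + 1L)
  pw <- list()
  for (i in others) {
    al <- needlemanWunsch(ref, aa[[i]])
    pw[[as.character(i)]] <- al
    aref <- seqChars(al[1])
    pos <- 0L; run <- 0L; ins <- integer(L + 1L)
    for (ch in aref) {
      if (ch == "-") run <- run + 1L
      else { ins[pos + 1L] <- run; run <- 0L; pos <- pos + 1L }
    }
    ins[L + 1L] <- run
    ins_master <- pmax(ins_master, ins)
  }
  pad <- function(chars_by_slot) {
    # chars_by_slot: list of L+1 insertion blocks + L residue slots
    paste(unlist(chars_by_slot), collapse = "")
  }
  buildRow <- function(aref, aseq) {
    arefv <- seqChars(aref); aseqv <- seqChars(aseq)
    slots <- vector("list", 2L * L + 1L)
    pos <- 0L; buf <- character(0)
    for (k in seq_along(arefv)) {
      if (arefv[k] == "-") buf <- c(buf, aseqv[k])
      else {
        slots[[2L * pos + 1L]] <-
          c(buf, rep("-", ins_master[pos + 1L] - length(buf)))
        slots[[2L * pos + 2L]] <- aseqv[k]
        buf <- character(0); pos <- pos + 1L
      }
    }
    slots[[2L * L + 1L]] <-
      c(buf, rep("-", ins_master[L + 1L] - length(buf)))
    pad(slots)
  }
  out <- character(length(aa))
  names(out) <- names(aa)
  out[ref_i] <- buildRow(ref, ref)
  for (i in others) {
    al <- pw[[as.character(i)]]
    out[i] <- buildRow(al[1], al[2])
  }
  out
}

#' Codon alignment of one core gene via translate-align-back-translate
#'
#' Terminal stop codons are removed, sequences are translated, amino
#' acids are aligned by the supplied aligner (default: the bundled
#' deterministic \code{\link{toyAligner}}), and the alignment is
#' threaded back onto the nucleotide codons (gaps in whole triplets,
#' stop codons excluded). Sequences with internal stop codons or lengths
#' not divisible by three are flagged and scored missing.
#'
#' @param sequences named character vector of nucleotide sequences
#'   (names = genome ids).
#' @param genome_ids full genome universe; absentees are listed missing.
#' @param aligner function implementing the aligner contract.
#' @return a \code{\link{GeneAlignment}}.
#' @param gene_id gene identifier carried into the result.
#' @export
alignGene <- function(sequences, genome_ids = names(sequences),
                      aligner = toyAligner, gene_id = "gene") {
  if (anyDuplicated(names(sequences)))
    stop("duplicate genome id in gene sequences")
  flagged <- character(0)
  nts <- list()
  for (gid in names(sequences)) {
    s <- toupper(sequences[[gid]])
    if (nchar(s) >= 3L &&
        substr(s, nchar(s) - 2L, nchar(s)) %in% STOP_CODONS)
      s <- substr(s, 1L, nchar(s) - 3L)
    if (nchar(s) %% 3L != 0L || nchar(s) == 0L) {
      flagged <- c(flagged, gid); next
    }
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (any(cods %in% STOP_CODONS)) {          # internal stop
      flagged <- c(flagged, gid); next
    }
    nts[[gid]] <- s
  }
  if (length(flagged))
    warning("sequence(s) flagged missing (internal stop or frame): ",
            paste(flagged, collapse = ", "))
  if (!length(nts))
    return(new("GeneAlignment", geneId = gene_id,
               sequences = character(0),
               missingGenomes = sort(unique(c(genome_ids, flagged)))))
  nts_v <- unlist(nts)
  if (length(unique(nchar(nts_v))) == 1L) {
    # equal-length stop-free sequences: the codon alignment is the
    # identity; no translation round trip needed
    rows <- nts_v
  } else {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nts_v)))
    names(aa) <- names(nts_v)
    aligned_aa <- aligner(aa)
    if (length(unique(nchar(aligned_aa))) != 1L)
      stop("aligner failure: rows of unequal length returned")
    rows <- vapply(names(nts), function(gid) {
      cods <- substring(nts[[gid]], seq(1L, nchar(nts[[gid]]), 3L),
                        seq(3L, nchar(nts[[gid]]), 3L))
      av <- seqChars(aligned_aa[[gid]])
      out <- character(length(av)); k <- 0L
      for (i in seq_along(av)) {
        if (av[i] == "-") out[i] <- "---"
        else { k <- k + 1L; out[i] <- cods[k] }
      }
      paste(out, collapse = "")
    }, character(1))
    names(rows) <- names(nts)
  }
  new("GeneAlignment", geneId = gene_id, sequences = rows,
      missingGenomes = sort(setdiff(unique(c(genome_ids, flagged)),
                                    names(rows))))
}

# fraction of rows whose codon at column (3c-2..3c) contains a gap or N
codonMissingFraction <- function(rows, c) {
  cod <- substr(rows, 3L * c - 2L, 3L * c)
  mean(grepl("[-N]", cod))
}

#' Trim poorly covered terminal codon columns from a gene alignment
#'
#' Leading and trailing codon columns are removed while the fraction of
#' rows whose terminal codon contains a gap or an N strictly exceeds
#' \code{max_missing} (default 90\%); interior columns are never
#' touched. Trimming is idempotent.
#'
#' @param aln a \code{\link{GeneAlignment}}.
#' @param max_missing strict missing-fraction threshold.
#' @return the trimmed \code{GeneAlignment}.
#' @export
trimAlignmentEnds <- function(aln, max_missing = 0.90) {
  rows <- alignedSequences(aln)
  if (!length(rows)) return(aln)
  n_cod <- nchar(rows[[1]]) %/% 3L
  from <- 1L; to <- n_cod
  while (from <= to && codonMissingFraction(rows, from) > max_missing)
    from <- from + 1L
  while (to >= from && codonMissingFraction(rows, to) > max_missing)
    to <- to - 1L
  if (from > to) stop("trimming would empty the alignment")
  trimmed <- substr(rows, 3L * from - 2L, 3L * to)
  names(trimmed) <- names(rows)
  new("GeneAlignment", geneId = aln@geneId, sequences = trimmed,
      missingGenomes = aln@missingGenomes)
}

#' Concatenate gene alignments into an N-filled supermatrix
#'
#' Genes are concatenated in the given order; a genome missing a gene
#' receives a run of Ns spanning exactly that gene's partition. The
#' partition table records 1-based inclusive column ranges.
#'
#' @param alignments list of \code{\link{GeneAlignment}} objects.
#' @param genome_ids genome universe (row set of the supermatrix).
#' @return a \code{\link{Supermatrix}}.
#' @export
concatenateAlignments <- function(alignments, genome_ids) {
  if (!length(alignments)) stop("no alignments to concatenate")
  pieces <- matrix("", nrow = length(genome_ids),
                   ncol = length(alignments),
                   dimnames = list(genome_ids, NULL))
  part <- data.frame(gene = character(length(alignments)),
                     start = integer(length(alignments)),
                     end = integer(length(alignments)),
                     stringsAsFactors = FALSE)
  at <- 1L
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    rows <- alignedSequences(aln)
    if (anyDuplicated(names(rows)))
      stop("duplicate genome id in gene ", aln@geneId)
    w <- if (length(rows)) nchar(rows[[1]]) else 0L
    nfill <- paste(rep("N", w), collapse = "")
    col <- rep(nfill, length(genome_ids))
    names(col) <- genome_ids
    hit <- intersect(genome_ids, names(rows))
    col[hit] <- rows[hit]
    pieces[, k] <- col
    part$gene[k] <- aln@geneId
    part$start[k] <- at
    part$end[k] <- at + w - 1L
    at <- at + w
  }
  seqs <- apply(pieces, 1L, paste, collapse = "")
  new("Supermatrix", sequences = seqs, partitions = part)
}

#' Extract one gene's columns back out of a supermatrix
#'
#' @param sm a \code{\link{Supermatrix}}.
#' @param gene gene id present in the partition table.
#' @return named character vector of that gene's aligned columns.
#' @export
sliceSupermatrix <- function(sm, gene) {
  p <- partitionTable(sm)
  row <- p[p$gene == gene, , drop = FALSE]
  if (nrow(row) != 1L) stop("gene not in partition table: ", gene)
  substr(supermatrixSequences(sm), row$start, row$end)
}

#' Write a RAxML-style partition file
#'
#' One line per gene: \code{DNA, <gene sanitized> = <start>-<end>}.
#'
#' @param sm a \code{\link{Supermatrix}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePartitionFile <- function(sm, path) {
  p <- partitionTable(sm)
  lab <- gsub("[^A-Za-z0-9]+", "_", p$gene)
  writeLines(sprintf("DNA, %s = %d-%d", lab, p$start, p$end), path)
  invisible(path)
}

#' Write the supermatrix as FASTA or relaxed PHYLIP
#'
#' @param sm a \code{\link{Supermatrix}}.
#' @param path output path.
#' @param format "fasta" or "phylip".
#' @return invisibly, the path.
#' @export
writeSupermatrix <- function(sm, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- supermatrixSequences(sm)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- names(seqs)
    Biostrings::writeXStringSet(ss, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%d %d", length(seqs), nchar(seqs[[1]])), con)
    writeLines(paste(names(seqs), seqs), con)
  }
  invisible(path)
}
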