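# Internal helpers shared across modules.

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Derive a stage-specific seed from a master seed
#'
#' A single pipeline seed fans out to per-stage seeds by stable string
#' hashing, so toggling one stage does not perturb another's randomness.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 1299709) %% 2147483647)
}

# Canonical unordered link string for a pair of gene ids.
canonicalLink <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

# Links of a gene order: adjacent pairs, plus the closing first--last
# pair when circular. Returns a canonical character vector (de-duplicated).
orderLinks <- function(genes, circular = TRUE) {
  g <- length(genes)
  if (g < 2L) return(character(0))
  a <- genes[-g]; b <- genes[-1L]
  if (circular && g >= 3L) { a <- c(a, genes[g]); b <- c(b, genes[1L]) }
  unique(canonicalLink(a, b))
}

# Random coding sequence of n_codons codons with no stop codons.
randomCodingSequence <- function(n_codons, gc = 0.68) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  repeat {
    s <- sample(NUCS, 3L * n_codons, replace = TRUE, prob = p)
    cod <- paste0(s[c(TRUE, FALSE, FALSE)], s[c(FALSE, TRUE, FALSE)],
                  s[c(FALSE, FALSE, TRUE)])
    bad <- which(cod %in% STOP_CODONS)
    if (!length(bad)) return(paste(s, collapse = ""))
    # resample offending codons only
    for (i in bad) {
      repeat {
        c3 <- sample(NUCS, 3L, replace = TRUE, prob = p)
        if (!(paste(c3, collapse = "") %in% STOP_CODONS)) break
      }
      s[(3L * i - 2L):(3L * i)] <- c3
    }
    cod <- paste0(s[c(TRUE, FALSE, FALSE)], s[c(FALSE, TRUE, FALSE)],
                  s[c(FALSE, FALSE, TRUE)])
    if (!any(cod %in% STOP_CODONS)) return(paste(s, collapse = ""))
  }
}

# Per-lineage substitution probability realizing a target pairwise
# divergence d between two lineages that each mutate independently from
# their common ancestor (uniform replacement among the 3 other bases):
#   P(identical) = (1-p)^2 + p^2/3  ==  1 - d
pairwiseToLineageRate <- function(d) {
  if (d <= 0) return(0)
  0.75 * (1 - sqrt(1 - 4 * d / 3))
}

# Mutate a character-vector sequence: each site substituted with
# probability p to a uniformly chosen different base. Avoids creating
# stop codons so translation stays clean (codon-structured input).
mutateSequence <- function(chars, p) {
  if (p <= 0) return(chars)
  n <- length(chars)
  hit <- which(runif(n) < p)
  if (!length(hit)) return(chars)
  for (i in hit) {
    alt <- NUCS[NUCS != chars[i]]
    new <- sample(alt, 1L)
    cod <- (i - 1L) %/% 3L
    idx <- (3L * cod + 1L):(3L * cod + 3L)
    trial <- chars[idx]
    trial[i - 3L * cod] <- new
    if (!(paste(trial, collapse = "") %in% STOP_CODONS)) chars[i] <- new
  }
  chars
}

# Fraction of identical positions between two equal-length char vectors.
identityFraction <- function(a, b) mean(a == b)

# Rotate a vector so it starts at position k (circular order helper).
rotateVector <- function(x, k) {
  n <- length(x)
  if (n == 0L || k == 1L) return(x)
  x[c(k:n, seq_len(k - 1L))]
}

# Split a string sequence into a character vector.
seqChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Assembly N50 from scaffold lengths.
assemblyN50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.double(s)) >= sum(as.double(s)) / 2)[1]]
}

#' Percentage of panel genes involved in a set of links
#'
#' Counts the distinct core genes appearing in at least one link of the
#' given set and reports them as a percentage of the panel size. Used to
#' summarize how much of the core genome a set of conserved links covers.
#'
#' @param links character vector of canonical "a--b" link strings.
#' @param panel_genes character vector of panel gene ids (the universe).
#' @return list(n_genes, percent).
#' @export
linkGeneCoverage <- function(links, panel_genes) {
  genes <- unique(unlist(strsplit(links, "--", fixed = TRUE)))
  genes <- intersect(genes, panel_genes)
  list(n_genes = length(genes),
       percent = 100 * length(genes) / length(panel_genes))
}
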