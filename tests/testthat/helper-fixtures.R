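# Shared fixture builders for the test suite. Everything is generated
# in code; no data files.

# gene-call data.frame with head-to-tail coordinates on one scaffold
makeCalls <- function(genome_id, funcs, seqs = NULL, scaffold = "scf_1",
                      strand = NULL) {
  if (is.null(seqs)) seqs <- strrep("ATGC", 25)[rep(1, length(funcs))]
  if (is.null(strand)) strand <- rep("+", length(funcs))
  stops <- cumsum(nchar(seqs))
  data.frame(genome_id = genome_id, scaffold_id = scaffold,
             feature_id = sprintf("fig|%s.peg.%d", genome_id,
                                  seq_along(funcs)),
             type = "peg", start = c(1L, head(stops, -1L) + 1L),
             stop = stops, strand = strand, func = funcs,
             sequence = seqs, partial = !nzchar(seqs),
             stringsAsFactors = FALSE)
}

# calls for one gene across genomes with specified copy lengths:
# copies[[genome]] = integer vector of copy lengths (bp)
makeGeneCopies <- function(gene, copies) {
  do.call(rbind, lapply(names(copies), function(gid) {
    lens <- copies[[gid]]
    if (!length(lens)) return(NULL)
    makeCalls(gid, rep(gene, length(lens)),
              vapply(lens, function(l) strrep("A", l), character(1)))
  }))
}

annMatrix <- function(counts) {
  new("AnnotationMatrix", counts = counts,
      exclusions = defaultExclusions())
}

# small simulated dataset shared by several tests (computed once)
tinyDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateDataset(simConfig(
        n_groups = 2, species_per_group = 2, genomes_per_species = 2,
        core_panel_size = 25, accessory_pool_size = 40,
        mean_gene_length_codons = 100, seed = 42))
    cache
  }
})

simMetadata <- function(ds) {
  data.frame(
    genome_id = names(ds$genomes),
    group = vapply(ds$genomes, `[[`, character(1), "group"),
    species = vapply(ds$genomes, `[[`, character(1), "species"),
    status = vapply(ds$genomes, `[[`, character(1), "status"),
    n50 = vapply(ds$genomes, `[[`, numeric(1), "n50"),
    n_scaffolds = vapply(ds$genomes, function(g)
      length(g$scaffold_lengths), integer(1)),
    stringsAsFactors = FALSE)
}

# alignment fixture: n_rows rows of codon sequences; rows listed in
# `missing_first` carry a gap codon in the first column, rows in
# `missing_last` in the last column
makeAlignment <- function(n_rows, n_codons, missing_first = integer(0),
                          missing_last = integer(0), gene = "g") {
  base <- strrep("ATG", n_codons)
  rows <- rep(base, n_rows)
  for (i in missing_first)
    rows[i] <- paste0("---", substr(rows[i], 4, nchar(rows[i])))
  for (i in missing_last)
    rows[i] <- paste0(substr(rows[i], 1, nchar(rows[i]) - 3), "---")
  names(rows) <- sprintf("g%03d", seq_len(n_rows))
  new("GeneAlignment", geneId = gene, sequences = rows,
      missingGenomes = character(0))
}

# aligned sequence pair with an exact number of mismatches
mismatchPair <- function(n_pos, n_mismatch) {
  a <- rep("A", n_pos)
  b <- a
  if (n_mismatch > 0) b[seq_len(n_mismatch)] <- "C"
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# two circular permutations of `genes` with disjoint adjacency sets,
# found by seeded randomized search
disjointOrders <- function(n_genes, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  l1 <- orderLinksT(genes)
  repeat {
    cand <- sample(genes)
    if (!length(intersect(l1, orderLinksT(cand))))
      return(list(genes, cand))
  }
}
orderLinksT <- function(g) {
  a <- c(g, g[1]); paste(pmin(head(a, -1), tail(a, -1)),
                         pmax(head(a, -1), tail(a, -1)), sep = "--")
}
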