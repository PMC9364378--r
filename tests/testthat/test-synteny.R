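test_that("link extraction pairs neighbors with circular closure", {
  ls1 <- extractLinks(c("A", "B", "C", "D", "E"), circular = TRUE,
                      genome_id = "g1")
  expect_identical(nLinks(ls1), 5L)
  expect_setequal(linkStrings(ls1),
                  c("A--B", "B--C", "C--D", "D--E", "A--E"))

  ls2 <- extractLinks(list(s1 = c("A", "B"), s2 = c("C", "D")),
                      circular = FALSE, genome_id = "g2")
  expect_setequal(linkStrings(ls2), c("A--B", "C--D"))

  expect_error(extractLinks(c("A", "B", "A")), "duplicate")
  expect_error(extractLinks("A"), "at least 2")
})

test_that("a complete genome carrying the whole panel yields one link per gene", {
  genes <- sprintf("Core conserved protein CG%04d", 1:384)
  set.seed(1)
  ls <- extractLinks(sample(genes), circular = TRUE)
  expect_identical(nLinks(ls), 384L)
})

test_that("synteny index matches hand-enumerated and boundary cases", {
  a <- extractLinks(c("A", "B", "C", "D", "E"))
  expect_equal(syntenyIndex(a, a), 1)
  b <- extractLinks(c("A", "B", "D", "C", "E"))
  # shared: A--B, C--D, A--E
  expect_equal(syntenyIndex(a, b), 0.6)
  expect_error(syntenyIndex(character(0), linkStrings(a)), "empty")
})

test_that("disjoint circular orders score a synteny index of zero", {
  ords <- disjointOrders(50, seed = 3)
  l1 <- extractLinks(ords[[1]]); l2 <- extractLinks(ords[[2]])
  expect_identical(length(intersect(linkStrings(l1),
                                    linkStrings(l2))), 0L)
  expect_equal(syntenyIndex(l1, l2), 0)
})

test_that("SI is symmetric with unit diagonal over a genome collection", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:30)
  sets <- lapply(1:5, function(i) extractLinks(sample(genes),
                                               genome_id = paste0("G", i)))
  names(sets) <- paste0("G", 1:5)
  S <- siMatrix(sets)
  expect_true(all(diag(S) == 1))
  expect_identical(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("scaffold scoring orders by mean reference rank with id tie-breaks", {
  ref <- paste0("g", 1:6)
  tab <- scoreScaffolds(list(S1 = c("g4", "g5"),
                             S2 = c("g1", "g2", "g3")), ref)
  expect_identical(tab$scaffold, c("S2", "S1"))
  expect_equal(tab$score, c(2, 4.5))

  one <- scoreScaffolds(list(S1 = c("g2", "g3")), ref)
  expect_identical(one$scaffold, "S1")

  tie <- scoreScaffolds(list(Sb = "g2", Sa = "g2"), ref)
  expect_identical(tie$scaffold, c("Sa", "Sb"))

  nohit <- scoreScaffolds(list(S1 = "g1", S2 = "zz"), ref)
  expect_false(nohit$has_core[nohit$scaffold == "S2"])
})

test_that("orientation recovers junction links when fragmenting a reference", {
  set.seed(5)
  for (trial in 1:5) {
    genes <- sprintf("g%03d", sample(40))
    ref_links <- orderLinks(genes, circular = TRUE)
    cuts <- sort(sample(40, 4))
    segs <- lapply(seq_along(cuts), function(i) {
      to <- if (i < length(cuts)) cuts[i + 1] - 1 else cuts[1] - 1 + 40
      genes[((cuts[i]:to - 1) %% 40) + 1]
    })
    names(segs) <- paste0("S", seq_along(segs))
    flip <- runif(4) < 0.5
    shuffled <- lapply(seq_along(segs), function(i)
      if (flip[i]) rev(segs[[i]]) else segs[[i]])
    names(shuffled) <- names(segs)
    cfg <- reorderDraft(shuffled, list(ref = genes), genome_id = "d")
    expect_equal(referenceSI(cfg), 1)
  }
})

test_that("palindromic single-gene scaffolds keep forward orientation", {
  ref_links <- orderLinks(c("a", "b", "c"), circular = TRUE)
  rv <- orientScaffolds(list(S1 = "a", S2 = "b", S3 = "c"), ref_links)
  expect_identical(rv, rep(FALSE, 3))
})

test_that("the best-SI reference wins and ties break lexicographically", {
  set.seed(11)
  genes <- sprintf("g%03d", 1:30)
  refA <- genes
  refB <- sample(genes)    # rearranged alternative
  draft <- list(S1 = genes[1:10], S2 = genes[11:20],
                S3 = genes[21:30])
  cfg <- reorderDraft(draft, list(zz = refB, aa = refA),
                      genome_id = "d")
  expect_identical(bestReference(cfg), "aa")
  expect_equal(referenceSI(cfg), 1)
  # pool of one: that reference's configuration comes back
  cfg1 <- reorderDraft(draft, list(only = refA))
  expect_identical(bestReference(cfg1), "only")
})

test_that("reorderAll grows the pool in completeness order deterministically", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:25)
  draft1 <- list(S1 = genes[1:12], S2 = genes[13:25])
  draft2 <- list(S1 = genes[1:5], S2 = genes[6:18],
                 S3 = genes[19:25])
  cm <- data.frame(genome_id = c("d1", "d2"), n50 = c(5000, 9000),
                   n_scaffolds = c(2L, 3L))
  run1 <- reorderAll(list(d1 = draft1, d2 = draft2),
                     list(ref = genes), cm)
  run2 <- reorderAll(list(d1 = draft1, d2 = draft2),
                     list(ref = genes), cm)
  expect_identical(names(run1), names(run2))
  expect_identical(lapply(run1, geneOrder), lapply(run2, geneOrder))
  expect_equal(referenceSI(run1$d1), 1)
  expect_equal(referenceSI(run1$d2), 1)
  # complete-only input is a no-op wrap
  cc <- reorderAll(list(), list(ref = genes), cm[0, ])
  expect_identical(geneOrder(cc$ref), genes)
  expect_error(reorderAll(list(d1 = draft1), list(), cm), "complete")
})

test_that("fragmentations of pool genomes recover SI = 1 end to end", {
  ds <- tinyDataset()
  am <- buildAnnotationMatrix(ds$genecalls)
  md <- simMetadata(ds)
  panel <- defineCorePanel(am, ds$genecalls, completeGenomes(md))
  complete <- intersect(md$genome_id, completeGenomes(md))
  gid <- complete[1]
  gc <- ds$genecalls[ds$genecalls$genome_id == gid, ]
  fr <- fragmentAssembly(ds$genomes[[gid]], gc, 6, seed = 9)
  draft_orders <- coreScaffoldOrders(fr$genecalls, panel, gid)
  ref_order <- unlist(coreScaffoldOrders(gc, panel, gid),
                      use.names = FALSE)
  cfg <- reorderDraft(draft_orders, list(ref = ref_order),
                      genome_id = gid)
  expect_equal(referenceSI(cfg), 1)
})

test_that("link occurrence columns sum to carrier counts and round-trip", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:12)
  sets <- list(a = extractLinks(genes, genome_id = "a"),
               b = extractLinks(sample(genes), genome_id = "b"),
               c = extractLinks(sample(genes), genome_id = "c"))
  m <- linkOccurrenceMatrix(sets)
  for (l in colnames(m))
    expect_identical(sum(m[, l]), sum(vapply(sets, function(s)
      l %in% linkStrings(s), logical(1))))
  path <- withr::local_tempfile(fileext = ".fasta")
  exportBinaryMatrix(m, path)
  expect_identical(readBinaryMatrix(path), m)
})

test_that("consensus network applies the strict majority rule per group", {
  spp <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  sg <- setNames(rep(c("A", "B"), each = 10), spp)
  mk <- function(fA, fB) {
    m <- cbind(test = c(rep(1L, fA), rep(0L, 10 - fA),
                        rep(1L, fB), rep(0L, 10 - fB)))
    rownames(m) <- spp
    colnames(m) <- "x--y"
    m
  }
  kept <- consensusNetwork(mk(6, 4), sg)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$dominant_groups, "A")
  expect_equal(kept$freq_A, 0.6); expect_equal(kept$freq_B, 0.4)

  half <- consensusNetwork(mk(5, 5), sg)
  expect_identical(nrow(half), 0L)
  expect_identical(attr(half, "n_discarded"), 1L)

  all_in <- consensusNetwork(mk(10, 10), sg)
  expect_identical(all_in$dominant_groups, "A,B")
})

test_that("conserved-link profiles pick the max-mean-SI reference and flag inversion breakpoints", {
  genes <- sprintf("g%02d", 1:20)
  inv <- genes; inv[6:10] <- rev(inv[6:10])   # one inversion
  # species A1, A2 share `genes`; B1, B2 share `inv`
  sets <- list(A1 = extractLinks(genes, genome_id = "A1"),
               A2 = extractLinks(genes, genome_id = "A2"),
               B1 = extractLinks(inv, genome_id = "B1"),
               B2 = extractLinks(inv, genome_id = "B2"))
  si <- siMatrix(sets)
  cfgs <- lapply(names(sets), function(g)
    new("SyntenyConfiguration", genomeId = g,
        scaffoldOrder = data.frame(scaffold = "scf_1",
                                   orientation = "forward",
                                   has_core = TRUE),
        geneOrder = if (startsWith(g, "A")) genes else inv,
        bestReference = "", si = NA_real_))
  names(cfgs) <- names(sets)
  sp <- setNames(names(sets), names(sets))
  tab <- data.frame(species = names(sets), name = NA,
                    status = "candidate", group = NA, n_genomes = 1L)
  asg <- new("SpeciesAssignment", genomeSpecies = sp,
             speciesTable = tab)
  slm <- speciesLinkOccurrence(linkOccurrenceMatrix(sets), asg)
  sg <- setNames(c("A", "A", "B", "B"), names(sets))
  prof <- conservedLinkProfile(si, cfgs, slm, sg)
  expect_identical(prof$reference, "A1")   # tie with A2 -> lexicographic
  t <- prof$table
  diff_links <- t$link[t$freq_A == 1 & t$freq_B == 0]
  # exactly the two breakpoint adjacencies of the inversion differ
  expect_setequal(diff_links, c("g05--g06", "g10--g11"))

  # single-species collection: every reference link present everywhere
  one <- conservedLinkProfile(si[1:2, 1:2], cfgs[1:2],
                              slm[1:2, , drop = FALSE],
                              c(A1 = "A", A2 = "A"))
  expect_true(all(one$table$freq_A == 1))
})

test_that("dot-plot coordinates cover shared genes on the unit square", {
  genes <- sprintf("g%02d", 1:10)
  c1 <- new("SyntenyConfiguration", genomeId = "a",
            scaffoldOrder = data.frame(scaffold = "s",
                                       orientation = "forward",
                                       has_core = TRUE),
            geneOrder = genes, bestReference = "", si = NA_real_)
  c2 <- c1; c2@geneOrder <- rev(genes)
  d <- dotplotCoordinates(c1, c2)
  expect_identical(nrow(d), 10L)
  expect_true(all(d$pos_a > 0 & d$pos_a <= 1))
  expect_equal(d$pos_b, rev(d$pos_a))
})
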