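test_that("invalid configurations are rejected with the field named", {
  expect_error(simConfig(gene_gain_rate = -1), "gene_gain_rate")
  expect_error(simConfig(within_species_divergence = 0.1,
                         between_species_divergence = 0.05),
               "ordered")
  expect_error(simConfig(core_panel_size = 2), "core_panel_size")
  expect_error(simConfig(scaffolds_per_draft = c(5, 2)),
               "scaffolds_per_draft")
})

test_that("zero-rate simulation yields identical genomes, PNS 100 and SI 1", {
  ds <- simulateDataset(simConfig(
    n_groups = 2, species_per_group = 2, genomes_per_species = 1,
    core_panel_size = 10, accessory_pool_size = 10,
    within_species_divergence = 0, between_species_divergence = 0,
    between_group_divergence = 0, gene_gain_rate = 0,
    gene_loss_rate = 0, rearrangement_rate = 0,
    mean_gene_length_codons = 60, draft_fraction = 0,
    noise_annotation_rates = c(hypothetical = 0, mobile = 0,
                               `repeat` = 0), seed = 5))
  ids <- names(ds$genomes)
  ref <- ds$genecalls[ds$genecalls$genome_id == ids[1],
                      c("func", "sequence")]
  for (g in ids[-1]) {
    other <- ds$genecalls[ds$genecalls$genome_id == g,
                          c("func", "sequence")]
    expect_equal(other, ref, ignore_attr = TRUE)
  }
  # PNS = 100 for all pairs on the concatenated core sequences
  concat <- vapply(ids, function(g) {
    gc <- ds$genecalls[ds$genecalls$genome_id == g, ]
    paste(gc$sequence[match(ds$truth$core_genes, gc$func)],
          collapse = "")
  }, character(1))
  pns <- pnsMatrix(concat)
  expect_true(all(pns == 100))
  # SI = 1 for all pairs on the true circular orders
  links <- lapply(ids, function(g)
    extractLinks(ds$truth$true_gene_orders[[g]], TRUE, g))
  si <- siMatrix(setNames(links, ids))
  expect_true(all(si == 1))
})

test_that("identical seeds give identical outputs", {
  cfg <- simConfig(n_groups = 2, species_per_group = 2,
                   genomes_per_species = 1, core_panel_size = 8,
                   accessory_pool_size = 15,
                   mean_gene_length_codons = 70, seed = 99)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$genecalls, d2$genecalls)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$genomes, d2$genomes)
})

test_that("realized divergence matches the configured rate within binomial error", {
  ds <- simulateDataset(simConfig(
    n_groups = 1, species_per_group = 2, genomes_per_species = 1,
    core_panel_size = 100, accessory_pool_size = 0,
    within_species_divergence = 0, between_species_divergence = 0.05,
    between_group_divergence = 0.05, gene_gain_rate = 0,
    gene_loss_rate = 0, rearrangement_rate = 0,
    mean_gene_length_codons = 300, draft_fraction = 0,
    noise_annotation_rates = c(hypothetical = 0, mobile = 0,
                               `repeat` = 0), seed = 21))
  ids <- names(ds$genomes)
  s1 <- ds$genecalls[ds$genecalls$genome_id == ids[1], ]
  s2 <- ds$genecalls[ds$genecalls$genome_id == ids[2], ]
  a <- unlist(strsplit(paste(s1$sequence[match(ds$truth$core_genes,
                                               s1$func)],
                             collapse = ""), ""))
  b <- unlist(strsplit(paste(s2$sequence[match(ds$truth$core_genes,
                                               s2$func)],
                             collapse = ""), ""))
  n <- length(a)
  ident <- mean(a == b)
  tol <- 3 * sqrt(0.95 * 0.05 / n)
  expect_lt(abs(ident - 0.95), tol)
})

test_that("fragmentation preserves content and within-scaffold order", {
  ds <- tinyDataset()
  complete <- names(ds$genomes)[vapply(ds$genomes, `[[`, character(1),
                                       "status") == "complete"]
  gid <- complete[1]
  gc <- ds$genecalls[ds$genecalls$genome_id == gid, ]
  orig <- gc$func[order(gc$start)]

  fr1 <- fragmentAssembly(ds$genomes[[gid]], gc, 1, seed = 3)
  expect_identical(fr1$genome$status, "draft")
  expect_identical(fr1$genecalls$func[order(fr1$genecalls$start)], orig)

  fr5 <- fragmentAssembly(ds$genomes[[gid]], gc, 5, seed = 3)
  expect_identical(sort(fr5$genecalls$func), sort(gc$func))
  expect_identical(length(fr5$genome$scaffold_lengths), 5L)
  # each scaffold (in its own orientation) is a contiguous arc of the
  # original circular order
  circ2 <- c(orig, orig)
  for (scf in unique(fr5$genecalls$scaffold_id)) {
    seg <- fr5$genecalls[fr5$genecalls$scaffold_id == scf, ]
    genes <- seg$func[order(seg$start)]
    fwd <- paste(genes, collapse = "\r")
    rev_ <- paste(rev(genes), collapse = "\r")
    full <- paste(circ2, collapse = "\r")
    expect_true(grepl(fwd, full, fixed = TRUE) ||
                  grepl(rev_, full, fixed = TRUE))
  }
  expect_error(fragmentAssembly(ds$genomes[[gid]], gc, nrow(gc) + 1),
               "exceeds")
})

test_that("gene splitting emits two partials whose sizes sum to the whole", {
  ds <- tinyDataset()
  complete <- names(ds$genomes)[vapply(ds$genomes, `[[`, character(1),
                                       "status") == "complete"]
  gid <- complete[1]
  gc <- ds$genecalls[ds$genecalls$genome_id == gid, ]
  fr <- fragmentAssembly(ds$genomes[[gid]], gc, 4, split_genes = TRUE,
                         seed = 11)
  parts <- fr$genecalls[fr$genecalls$partial, ]
  expect_identical(nrow(parts), 2L)
  expect_identical(unique(parts$func), parts$func[1])
  full_len <- nchar(gc$sequence[gc$func == parts$func[1]][1])
  norm_sum <- sum(nchar(parts$sequence)) / full_len
  expect_lt(abs(norm_sum - 1), 0.02)
  # full-length copy count of every other gene unchanged
  other <- setdiff(gc$func, parts$func[1])
  expect_identical(sort(fr$genecalls$func[!fr$genecalls$partial &
                                            fr$genecalls$func %in% other]),
                   sort(gc$func[gc$func %in% other]))
})

test_that("written datasets round-trip through the annotation reader", {
  ds <- tinyDataset()
  dir <- withr::local_tempdir()
  manifest <- writeDataset(ds$genomes, ds$genecalls, ds$truth, dir)
  expect_true(all(file.exists(manifest$file)))
  cols <- c("genome_id", "scaffold_id", "feature_id", "type", "start",
            "stop", "strand", "func", "sequence")
  for (gid in names(ds$genomes)[1:3]) {
    back <- readRastTable(file.path(dir, paste0(gid, ".rast.tsv")), gid)
    orig <- ds$genecalls[ds$genecalls$genome_id == gid, ]
    rownames(orig) <- NULL
    expect_equal(back[order(back$feature_id), cols],
                 orig[order(orig$feature_id), cols],
                 ignore_attr = TRUE)
  }
  # noise rows are written but excluded from the abundance matrix
  all_back <- do.call(rbind, lapply(names(ds$genomes), function(g)
    readRastTable(file.path(dir, paste0(g, ".rast.tsv")), g)))
  expect_true(any(all_back$func == "hypothetical protein"))
  am <- buildAnnotationMatrix(all_back)
  expect_false("hypothetical protein" %in% colnames(countsMatrix(am)))
})

test_that("an empty genome set writes an empty manifest and no files", {
  dir <- withr::local_tempdir()
  m <- writeDataset(list(), NULL, NULL, file.path(dir, "empty"))
  expect_identical(nrow(m), 0L)
  expect_false(dir.exists(file.path(dir, "empty")) &&
                 length(list.files(file.path(dir, "empty"))) > 0)
})
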