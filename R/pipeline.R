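#' Pipeline configuration
#'
#' Assembles and validates the configuration for a full run: either a
#' simulation block (\code{\link{simConfig}}) or an input directory of
#' annotation tables plus metadata, the analysis thresholds (defaults:
#' occupancy 0.90, duplicate size 0.75, size window 0.7-1.3, missing 4,
#' end-trim 0.90, PNS 97, support collapse 10, consensus majority 0.50,
#' 15 Venn species, 100 replicates), stage toggles, a master seed and an
#' output directory.
#'
#' @param simulate a \code{SimConfig}, or NULL to read \code{input_dir}.
#' @param input_dir directory with RAST tables + metadata.tsv (ignored
#'   when \code{simulate} is given).
#' @param output_dir artifact directory.
#' @param stages character subset of
#'   c("annotate","core","align","species","content","synteny","trees").
#' @param occupancy,dup_threshold,lower,upper,max_missing,trim_missing,pns_threshold,collapse_support,majority,venn_species,replicates
#'   analysis thresholds.
#' @param bootstrap_replicates supermatrix column-bootstrap replicates
#'   for the RF null distribution.
#' @param seed master seed, fanned out per stage.
#' @return validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(simulate = simConfig(), input_dir = NULL,
                           output_dir = tempfile("phylocore_run_"),
                           stages = c("annotate", "core", "align",
                                      "species", "content", "synteny",
                                      "trees"),
                           occupancy = 0.90, dup_threshold = 0.75,
                           lower = 0.7, upper = 1.3, max_missing = 4L,
                           trim_missing = 0.90, pns_threshold = 97.0,
                           collapse_support = 10, majority = 0.50,
                           venn_species = 15L, replicates = 100L,
                           bootstrap_replicates = 20L, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(simulate) && is.null(input_dir))
    stop("config error: either a simulate block or input_dir is required")
  if (!is.null(input_dir) && is.null(simulate) && !dir.exists(input_dir))
    stop("config error: input_dir does not exist: ", input_dir)
  if (!(occupancy > 0 && occupancy <= 1))
    stop("config error: occupancy must be in (0,1]")
  if (!(pns_threshold >= 0 && pns_threshold <= 100))
    stop("config error: pns_threshold must be in [0,100]")
  if (!(collapse_support >= 0 && collapse_support <= 100))
    stop("config error: collapse_support must be in [0,100]")
  if (!(majority >= 0 && majority < 1))
    stop("config error: majority must be in [0,1)")
  if (!(trim_missing >= 0 && trim_missing <= 1))
    stop("config error: trim_missing must be in [0,1]")
  if (!(0 < lower && lower < dup_threshold && dup_threshold < upper))
    stop("config error: need 0 < lower < dup_threshold < upper")
  if (venn_species < 1L || replicates < 1L || bootstrap_replicates < 2L)
    stop("config error: venn_species/replicates out of range")
  bad <- setdiff(stages, c("annotate", "core", "align", "species",
                           "content", "synteny", "trees"))
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "PipelineConfig"
  cfg
}

# write a table artifact and append it to the manifest
emit <- function(state, obj, file, stage, params = "") {
  path <- file.path(state$out, file)
  if (is.matrix(obj))
    write.table(data.frame(id = rownames(obj), obj, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  else if (is.data.frame(obj))
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else writeLines(as.character(obj), path)
  state$manifest[[length(state$manifest) + 1L]] <-
    data.frame(file = file, stage = stage, params = params,
               checksum = unname(tools::md5sum(path)),
               stringsAsFactors = FALSE)
  state
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: annotation abundance matrix and
#' genome summaries; core-gene panel (occupancy + size filters);
#' per-gene codon alignments, end trimming and the N-filled
#' supermatrix; PNS species delimitation and labeling; gene-content
#' dissimilarity, rarefaction and Venn overlap; synteny (draft
#' reordering, SI matrix, consensus network, conserved-link profile);
#' and tree building/concordance (NJ lineage, content and synteny
#' trees, per-gene trees, column-bootstrap RF null). Every artifact is
#' listed in a manifest with stage, parameters and checksum; filter
#' decisions are logged.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of computed objects plus \code{manifest} (data.frame).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- do.call(pipelineConfig, config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state <- list(out = out, manifest = list())
  res <- list(config = config)
  logmsg <- function(...) message("[phylocore] ", ...)

  # ---- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    logmsg("simulating dataset (seed ", config$seed, ")")
    sim <- config$simulate
    sim$seed <- stageSeed(config$seed, "simulate")
    ds <- simulateDataset(do.call(simConfig, unclass(sim)[names(sim) != ""]))
    res$truth <- ds$truth
    genomes <- ds$genomes
    genecalls <- ds$genecalls
    metadata <- data.frame(
      genome_id = names(genomes),
      group = vapply(genomes, `[[`, character(1), "group"),
      species = vapply(genomes, `[[`, character(1), "species"),
      status = vapply(genomes, `[[`, character(1), "status"),
      n50 = vapply(genomes, `[[`, numeric(1), "n50"),
      n_scaffolds = vapply(genomes, function(g)
        length(g$scaffold_lengths), integer(1)),
      stringsAsFactors = FALSE)
  } else {
    logmsg("reading dataset from ", config$input_dir)
    metadata <- read.delim(file.path(config$input_dir, "metadata.tsv"),
                           stringsAsFactors = FALSE)
    tabs <- file.path(config$input_dir,
                      paste0(metadata$genome_id, ".rast.tsv"))
    genecalls <- do.call(rbind, c(
      Map(readRastTable, tabs, metadata$genome_id),
      list(make.row.names = FALSE)))
  }
  res$metadata <- metadata
  res$genecalls <- genecalls
  state <- emit(state, metadata, "metadata.tsv", "input")
  genome_ids <- metadata$genome_id

  # ---- annotate -----------------------------------------------------
  if ("annotate" %in% config$stages) {
    logmsg("building annotation matrix")
    res$annotation <- buildAnnotationMatrix(genecalls)
    stats <- do.call(rbind, lapply(genome_ids, function(g)
      as.data.frame(genomeSummary(
        genecalls[genecalls$genome_id == g, , drop = FALSE]))))
    stats <- cbind(genome_id = genome_ids, stats)
    res$genome_stats <- stats
    state <- emit(state, countsMatrix(res$annotation),
                  "annotation_matrix.tsv", "annotate")
    state <- emit(state, stats, "genome_stats.tsv", "annotate")
  }

  # ---- core panel ---------------------------------------------------
  if ("core" %in% config$stages) {
    complete <- completeGenomes(metadata)
    logmsg("defining core panel (", length(complete),
           " complete reference genomes)")
    res$panel <- defineCorePanel(
      res$annotation, genecalls, complete,
      occupancy_threshold = config$occupancy,
      dup_threshold = config$dup_threshold, upper = config$upper,
      lower = config$lower, max_missing_genomes = config$max_missing)
    prov <- res$panel@provenance
    logmsg(sum(startsWith(prov$decision, "removed: true")),
           " candidates removed as true duplicates; ",
           sum(prov$decision == "removed: missing in too many genomes"),
           " removed for missing data; panel size ",
           length(geneIds(res$panel)))
    state <- emit(state, prov, "core_panel_provenance.tsv", "core",
                  sprintf("occupancy=%g dup=%g window=[%g,%g] missing=%d",
                          config$occupancy, config$dup_threshold,
                          config$lower, config$upper,
                          config$max_missing))
  }

  # ---- align --------------------------------------------------------
  if ("align" %in% config$stages) {
    logmsg("aligning ", length(geneIds(res$panel)), " core genes")
    alns <- lapply(geneIds(res$panel), function(g)
      trimAlignmentEnds(
        alignGene(panelSequences(res$panel)[[g]], genome_ids,
                  gene_id = g),
        max_missing = config$trim_missing))
    res$alignments <- alns
    res$supermatrix <- concatenateAlignments(alns, genome_ids)
    fa <- file.path(out, "supermatrix.fasta")
    writeSupermatrix(res$supermatrix, fa)
    state$manifest[[length(state$manifest) + 1L]] <-
      data.frame(file = "supermatrix.fasta", stage = "align",
                 params = sprintf("trim=%g", config$trim_missing),
                 checksum = unname(tools::md5sum(fa)),
                 stringsAsFactors = FALSE)
    pf <- file.path(out, "partitions.txt")
    writePartitionFile(res$supermatrix, pf)
    state$manifest[[length(state$manifest) + 1L]] <-
      data.frame(file = "partitions.txt", stage = "align", params = "",
                 checksum = unname(tools::md5sum(pf)),
                 stringsAsFactors = FALSE)
  }

  # ---- species ------------------------------------------------------
  if ("species" %in% config$stages) {
    logmsg("computing PNS matrix and delimiting species")
    res$pns <- pnsMatrix(res$supermatrix)
    asg <- delimitSpecies(res$pns, threshold = config$pns_threshold)
    grp <- setNames(metadata$group, metadata$genome_id)
    res$species <- labelSpecies(asg, group_labels = grp)
    logmsg(nrow(speciesTable(res$species)), " species at PNS >= ",
           config$pns_threshold)
    state <- emit(state, res$pns, "pns_matrix.tsv", "species",
                  sprintf("threshold=%g", config$pns_threshold))
    sp_tab <- data.frame(genome_id = names(speciesOf(res$species)),
                         species = unname(speciesOf(res$species)),
                         stringsAsFactors = FALSE)
    state <- emit(state, sp_tab, "species_assignment.tsv", "species")
    state <- emit(state, speciesTable(res$species), "species_table.tsv",
                  "species")
  }

  # species -> group map used by content and synteny
  speciesGroupMap <- function() {
    st <- speciesTable(res$species)
    setNames(st$group, st$species)
  }

  # ---- content ------------------------------------------------------
  if ("content" %in% config$stages) {
    logmsg("gene-content profiles, dissimilarity and rarefaction")
    res$occurrence <- speciesOccurrenceProfile(res$annotation,
                                               res$species)
    res$bc <- brayCurtisMatrix(res$annotation)
    sg <- speciesGroupMap()
    res$rarefaction <- rarefyPanCore(
      res$annotation, res$species, sg,
      replicates = config$replicates,
      seed = stageSeed(config$seed, "rarefy"))
    if (length(unique(sg)) >= 2L)
      res$venn <- suppressWarnings(vennOverlap(
        res$annotation, res$species, sg,
        species_per_group = config$venn_species,
        replicates = config$replicates,
        seed = stageSeed(config$seed, "venn")))
    state <- emit(state, res$occurrence, "species_occurrence.tsv",
                  "content")
    state <- emit(state, res$bc, "bray_curtis.tsv", "content")
    state <- emit(state, res$rarefaction, "rarefaction.tsv", "content",
                  sprintf("replicates=%d", config$replicates))
    bm <- file.path(out, "gene_content_binary.fasta")
    exportBinaryMatrix(countsMatrix(res$annotation), bm)
    state$manifest[[length(state$manifest) + 1L]] <-
      data.frame(file = "gene_content_binary.fasta", stage = "content",
                 params = "", checksum = unname(tools::md5sum(bm)),
                 stringsAsFactors = FALSE)
  }

  # ---- synteny ------------------------------------------------------
  if ("synteny" %in% config$stages) {
    logmsg("reconstructing core-genome architecture")
    complete <- completeGenomes(metadata)
    orders <- lapply(genome_ids, function(g)
      coreScaffoldOrders(genecalls, res$panel, g))
    names(orders) <- genome_ids
    complete_orders <- lapply(orders[intersect(genome_ids, complete)],
                              function(o) unlist(o, use.names = FALSE))
    drafts <- setdiff(genome_ids, complete)
    res$configurations <- reorderAll(
      orders[drafts], complete_orders,
      metadata[, c("genome_id", "n50", "n_scaffolds")])
    res$link_sets <- configurationLinkSets(res$configurations)
    res$si <- siMatrix(res$link_sets)
    lm <- linkOccurrenceMatrix(res$link_sets)
    sl <- speciesLinkOccurrence(lm, res$species)
    sg <- speciesGroupMap()
    res$consensus <- consensusNetwork(sl, sg,
                                      majority = config$majority)
    res$link_profile <- conservedLinkProfile(res$si,
                                             res$configurations, sl, sg)
    logmsg(ncol(lm), " distinct links; ", nrow(res$consensus),
           " in the consensus network (reference ",
           res$link_profile$reference, ")")
    state <- emit(state, res$si, "si_matrix.tsv", "synteny")
    state <- emit(state, res$consensus, "consensus_network.tsv",
                  "synteny", sprintf("majority=%g", config$majority))
    state <- emit(state, res$link_profile$table,
                  "conserved_link_profile.tsv", "synteny")
    lb <- file.path(out, "links_binary.fasta")
    exportBinaryMatrix(lm, lb)
    state$manifest[[length(state$manifest) + 1L]] <-
      data.frame(file = "links_binary.fasta", stage = "synteny",
                 params = "", checksum = unname(tools::md5sum(lb)),
                 stringsAsFactors = FALSE)
  }

  # ---- trees --------------------------------------------------------
  if ("trees" %in% config$stages) {
    logmsg("building trees and RF concordance test")
    res$lineage_tree <- njTree(100 - res$pns)
    res$content_tree <- njTree(res$bc)
    res$synteny_tree <- njTree(1 - res$si)
    obs <- c(
      lineage_vs_content = rfDistance(res$lineage_tree,
                                      res$content_tree)$normalized,
      lineage_vs_synteny = rfDistance(res$lineage_tree,
                                      res$synteny_tree)$normalized)
    # null: NJ trees from column bootstraps of the supermatrix
    set.seed(stageSeed(config$seed, "rf_null"))
    seqs <- supermatrixSequences(res$supermatrix)
    raws <- lapply(seqs, function(s) charToRaw(toupper(s)))
    L <- length(raws[[1]])
    nb <- min(30000L, L)
    reps <- lapply(seq_len(config$bootstrap_replicates), function(r) {
      idx <- sample.int(L, nb, replace = TRUE)
      sub <- lapply(raws, function(x) rawToChar(x[idx]))
      njTree(100 - pnsMatrix(unlist(sub)))
    })
    res$rf_test <- rfNullTest(res$lineage_tree, reps, obs)
    gene_trees <- lapply(res$alignments, function(aln) {
      rows <- alignedSequences(aln)
      if (length(rows) < 3L) return(NULL)
      tryCatch(njTree(100 - pnsMatrix(rows)), error = function(e) NULL)
    })
    gene_trees <- Filter(Negate(is.null), gene_trees)
    tf <- file.path(out, "gene_trees.nwk")
    writeMultiPhylo(gene_trees, tf)
    state$manifest[[length(state$manifest) + 1L]] <-
      data.frame(file = "gene_trees.nwk", stage = "trees", params = "",
                 checksum = unname(tools::md5sum(tf)),
                 stringsAsFactors = FALSE)
    lt <- file.path(out, "lineage_tree.nwk")
    ape::write.tree(res$lineage_tree, lt)
    state$manifest[[length(state$manifest) + 1L]] <-
      data.frame(file = "lineage_tree.nwk", stage = "trees", params = "",
                 checksum = unname(tools::md5sum(lt)),
                 stringsAsFactors = FALSE)
    rf_tab <- res$rf_test$observed
    state <- emit(state, rf_tab, "rf_observed.tsv", "trees",
                  sprintf("bootstrap_replicates=%d",
                          config$bootstrap_replicates))
  }

  res$manifest <- do.call(rbind, c(state$manifest,
                                   list(make.row.names = FALSE)))
  mf <- file.path(out, "manifest.tsv")
  write.table(res$manifest, mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  res
}
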