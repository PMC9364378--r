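#' Configuration for the synthetic clade generator
#'
#' Builds and validates the parameter set controlling a synthetic
#' bacterial clade: a hierarchy of groups / species / genomes with
#' layered sequence divergence, gene gain and loss on an accessory pool,
#' chromosome rearrangements, draft-assembly fragmentation and
#' annotation noise. The defaults emulate (at reduced scale) a
#' multi-group clade in which genomes of one species share >=97%
#' core-gene identity while species and groups fall below it.
#'
#' Divergence parameters are layer-wise expected pairwise divergences:
#' \code{between_species_divergence} is the expected per-site divergence
#' contributed by the species layer alone (two species of the same
#' group), so realized divergence across layers compounds.
#'
#' @param n_groups number of groups (clades) in the simulated family.
#' @param species_per_group species per group.
#' @param genomes_per_species genomes sampled per species.
#' @param core_panel_size number of universally present single-copy genes.
#' @param accessory_pool_size size of the accessory gene pool.
#' @param within_species_divergence,between_species_divergence,between_group_divergence
#'   expected pairwise substitutions/site contributed by each layer;
#'   must be ordered within <= species <= group.
#' @param gene_gain_rate,gene_loss_rate expected accessory gain/loss
#'   events per branch (Poisson).
#' @param rearrangement_rate expected inversions+translocations per branch.
#' @param mean_gene_length_codons mean gene length in codons.
#' @param draft_fraction proportion of genomes fragmented into drafts.
#' @param scaffolds_per_draft length-2 integer range of scaffold counts.
#' @param gene_split_probability probability that a draft carries one
#'   gene split across a scaffold junction.
#' @param noise_annotation_rates named proportions (relative to gene
#'   count) of "hypothetical", "mobile" and "repeat" noise rows.
#' @param seed integer seed; fully determines the output.
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(n_groups = 4L, species_per_group = 5L,
                      genomes_per_species = 2L,
                      core_panel_size = 300L, accessory_pool_size = 400L,
                      within_species_divergence = 0.01,
                      between_species_divergence = 0.05,
                      between_group_divergence = 0.12,
                      gene_gain_rate = 8, gene_loss_rate = 8,
                      rearrangement_rate = 15,
                      mean_gene_length_codons = 300L,
                      draft_fraction = 0.8,
                      scaffolds_per_draft = c(4L, 20L),
                      gene_split_probability = 0.05,
                      noise_annotation_rates = c(hypothetical = 0.25,
                                                 mobile = 0.01,
                                                 `repeat` = 0.005),
                      seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              species_per_group = as.integer(species_per_group),
              genomes_per_species = as.integer(genomes_per_species),
              core_panel_size = as.integer(core_panel_size),
              accessory_pool_size = as.integer(accessory_pool_size),
              within_species_divergence = within_species_divergence,
              between_species_divergence = between_species_divergence,
              between_group_divergence = between_group_divergence,
              gene_gain_rate = gene_gain_rate,
              gene_loss_rate = gene_loss_rate,
              rearrangement_rate = rearrangement_rate,
              mean_gene_length_codons = as.integer(mean_gene_length_codons),
              draft_fraction = draft_fraction,
              scaffolds_per_draft = as.integer(scaffolds_per_draft),
              gene_split_probability = gene_split_probability,
              noise_annotation_rates = noise_annotation_rates,
              seed = as.integer(seed))
  rates <- c("within_species_divergence", "between_species_divergence",
             "between_group_divergence", "gene_gain_rate", "gene_loss_rate",
             "rearrangement_rate", "draft_fraction",
             "gene_split_probability")
  for (f in rates)
    if (any(cfg[[f]] < 0)) stop("invalid SimConfig: ", f, " must be >= 0")
  if (any(cfg$noise_annotation_rates < 0))
    stop("invalid SimConfig: noise_annotation_rates must be >= 0")
  if (cfg$within_species_divergence > cfg$between_species_divergence ||
      cfg$between_species_divergence > cfg$between_group_divergence)
    stop("invalid SimConfig: divergences must be ordered ",
         "within_species_divergence <= between_species_divergence ",
         "<= between_group_divergence")
  if (cfg$core_panel_size < 3L)
    stop("invalid SimConfig: core_panel_size must be >= 3")
  if (length(cfg$scaffolds_per_draft) != 2L ||
      any(cfg$scaffolds_per_draft < 1L) ||
      cfg$scaffolds_per_draft[1] > cfg$scaffolds_per_draft[2])
    stop("invalid SimConfig: scaffolds_per_draft must be a valid range")
  if (cfg$n_groups < 1L || cfg$species_per_group < 1L ||
      cfg$genomes_per_species < 1L)
    stop("invalid SimConfig: n_groups, species_per_group and ",
         "genomes_per_species must be >= 1")
  class(cfg) <- "SimConfig"
  cfg
}

# Poisson-distributed inversions/translocations applied to a master
# gene-order data.frame(gene, strand). Inversions reverse a block and
# flip its strands; translocations move a block elsewhere.
applyRearrangements <- function(ord, rate) {
  n_ev <- rpois(1L, rate)
  n <- nrow(ord)
  if (n_ev == 0L || n < 4L) return(ord)
  for (e in seq_len(n_ev)) {
    len <- sample(2:max(2L, n %/% 4L), 1L)
    i <- sample(n, 1L)
    idx <- ((i - 1L + seq_len(len) - 1L) %% n) + 1L
    if (runif(1) < 0.5) {                      # inversion
      block <- ord[rev(idx), ]
      block$strand <- ifelse(block$strand == "+", "-", "+")
      ord[idx, ] <- block
    } else {                                   # translocation
      block <- ord[idx, ]
      rest <- ord[-idx, , drop = FALSE]
      j <- sample(nrow(rest) + 1L, 1L)
      ord <- rbind(rest[seq_len(j - 1L), , drop = FALSE], block,
                   rest[seq(j, length.out = nrow(rest) - j + 1L),
                        , drop = FALSE])
      rownames(ord) <- NULL
    }
  }
  rownames(ord) <- NULL
  ord
}

# Ladder newick over the group/species/genome hierarchy, with nominal
# branch lengths of half the layer divergence.
truthNewick <- function(ids_by_group, cfg) {
  bl <- function(x) format(x, scientific = FALSE)
  ladder <- function(tips, len) {
    if (length(tips) == 1L) return(paste0(tips[1], ":", bl(len)))
    rest <- ladder(tips[-1L], len)
    paste0("(", tips[1], ":", bl(len), ",", rest, "):", bl(len / 2))
  }
  grp <- vapply(ids_by_group, function(sp_list) {
    sp_clades <- vapply(sp_list, function(genomes)
      if (length(genomes) == 1L)
        paste0(genomes, ":", bl(cfg$within_species_divergence / 2))
      else paste0("(", paste0(genomes, ":",
                              bl(cfg$within_species_divergence / 2),
                              collapse = ","), ")"),
      character(1))
    ladder(sp_clades, cfg$between_species_divergence / 2)
  }, character(1))
  paste0(ladder(grp, cfg$between_group_divergence / 2), ";")
}

#' Simulate a synthetic bacterial clade with known ground truth
#'
#' Generates genomes, gene calls and truth tables for a hierarchical
#' clade: root gene sequences are mutated independently along group,
#' species and genome layers (uniform-rate independent-site
#' substitutions, stop codons avoided); accessory gene content evolves
#' by Poisson gain/loss; circular gene order evolves by random
#' inversions and block translocations; a configured fraction of genomes
#' is fragmented into draft assemblies with optional gene splitting; and
#' annotation noise rows (hypothetical proteins, mobile element
#' proteins, repeat regions) are interleaved.
#'
#' @param config a \code{SimConfig} from \code{\link{simConfig}}.
#' @return list with elements \code{genomes} (list of genome records:
#'   id, group, species, status, scaffold lengths, N50), \code{genecalls}
#'   (one data.frame of all gene calls) and \code{truth}
#'   (\code{SyntheticTruth}: species/group assignments, circular core
#'   gene orders, true tree newick, per-gene homologous sequence sets,
#'   genome-by-gene content table).
#' @export
simulateDataset <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  cfg <- config
  set.seed(cfg$seed)

  core_genes <- sprintf("Core conserved protein CG%04d",
                        seq_len(cfg$core_panel_size))
  acc_genes <- if (cfg$accessory_pool_size > 0)
    sprintf("Accessory protein AC%04d", seq_len(cfg$accessory_pool_size))
  else character(0)
  all_genes <- c(core_genes, acc_genes)

  # gene lengths (codons) and root sequences
  lens <- pmax(60L, round(rnorm(length(all_genes),
                                cfg$mean_gene_length_codons,
                                cfg$mean_gene_length_codons / 8)))
  names(lens) <- all_genes
  root_seq <- lapply(all_genes, function(g)
    seqChars(randomCodingSequence(lens[[g]])))
  names(root_seq) <- all_genes

  # root gene order and content
  root_ord <- data.frame(
    gene = sample(all_genes),
    strand = sample(c("+", "-"), length(all_genes), replace = TRUE),
    stringsAsFactors = FALSE)
  root_content <- c(core_genes,
                    acc_genes[runif(length(acc_genes)) < 0.5])

  p_grp <- pairwiseToLineageRate(cfg$between_group_divergence)
  p_sp <- pairwiseToLineageRate(cfg$between_species_divergence)
  p_gen <- pairwiseToLineageRate(cfg$within_species_divergence)

  genomes <- list(); calls <- list(); truth_orders <- list()
  species_assignment <- character(0); group_assignment <- character(0)
  gene_seq_truth <- lapply(all_genes, function(g) character(0))
  names(gene_seq_truth) <- all_genes
  content_rows <- list()
  ids_by_group <- list()

  evolveContent <- function(content) {
    lost <- intersect(content, acc_genes)
    n_loss <- min(rpois(1L, cfg$gene_loss_rate), length(lost))
    if (n_loss > 0) content <- setdiff(content, sample(lost, n_loss))
    absent <- setdiff(acc_genes, content)
    n_gain <- min(rpois(1L, cfg$gene_gain_rate), length(absent))
    if (n_gain > 0) content <- c(content, sample(absent, n_gain))
    content
  }

  for (gi in seq_len(cfg$n_groups)) {
    grp <- LETTERS[gi]
    grp_seq <- lapply(root_seq, mutateSequence, p = p_grp)
    grp_ord <- applyRearrangements(root_ord, cfg$rearrangement_rate)
    grp_content <- evolveContent(root_content)
    ids_by_group[[grp]] <- list()

    for (si in seq_len(cfg$species_per_group)) {
      sp_id <- sprintf("%s_sp%02d", grp, si)
      # accessory sequences evolve to the species level only; genomes of
      # one species share accessory sequence (cost-saving simplification)
      sp_seq <- lapply(grp_seq, mutateSequence, p = p_sp)
      sp_ord <- applyRearrangements(grp_ord, cfg$rearrangement_rate)
      sp_content <- evolveContent(grp_content)
      group_assignment[[sp_id]] <- grp
      ids_by_group[[grp]][[sp_id]] <- character(0)

      for (ki in seq_len(cfg$genomes_per_species)) {
        gid <- sprintf("%s_sp%02d_g%02d", grp, si, ki)
        gen_ord <- applyRearrangements(sp_ord,
                                       cfg$rearrangement_rate / 5)
        present <- sp_content
        ord_here <- gen_ord[gen_ord$gene %in% present, , drop = FALSE]

        gseqs <- sp_seq
        for (g in core_genes)
          gseqs[[g]] <- mutateSequence(sp_seq[[g]], p_gen)
        seq_str <- vapply(gseqs, paste, character(1), collapse = "")

        for (g in intersect(all_genes, present))
          gene_seq_truth[[g]][[gid]] <- seq_str[[g]]

        truth_orders[[gid]] <-
          ord_here$gene[ord_here$gene %in% core_genes]
        species_assignment[[gid]] <- sp_id
        ids_by_group[[grp]][[sp_id]] <-
          c(ids_by_group[[grp]][[sp_id]], gid)

        # noise rows interleaved into the layout
        n_noise <- rpois(3L, cfg$noise_annotation_rates *
                           nrow(ord_here))
        noise_fun <- rep(c("hypothetical protein",
                           "Mobile element protein", "repeat region"),
                         n_noise)
        layout <- data.frame(gene = ord_here$gene,
                             strand = ord_here$strand,
                             noise = FALSE, stringsAsFactors = FALSE)
        if (length(noise_fun)) {
          pos <- sample(nrow(layout) + 1L, length(noise_fun),
                        replace = TRUE)
          noise_df <- data.frame(gene = noise_fun,
                                 strand = sample(c("+", "-"),
                                                 length(noise_fun),
                                                 replace = TRUE),
                                 noise = TRUE, stringsAsFactors = FALSE)
          keyed <- rbind(cbind(layout, k = seq_len(nrow(layout))),
                         cbind(noise_df, k = pos - 0.5))
          layout <- keyed[order(keyed$k), c("gene", "strand", "noise")]
          rownames(layout) <- NULL
        }
        noise_seqs <- vapply(seq_len(sum(layout$noise)), function(i)
          randomCodingSequence(50L), character(1))
        layout$sequence <- NA_character_
        layout$sequence[!layout$noise] <- seq_str[layout$gene[!layout$noise]]
        layout$sequence[layout$noise] <- noise_seqs

        stops <- cumsum(nchar(layout$sequence))
        starts <- c(1L, head(stops, -1L) + 1L)
        gcalls <- data.frame(
          genome_id = gid, scaffold_id = "scf_1",
          feature_id = sprintf("fig|%s.peg.%d", gid,
                               seq_len(nrow(layout))),
          type = "peg", start = starts, stop = stops,
          strand = layout$strand, func = layout$gene,
          sequence = layout$sequence, partial = FALSE,
          stringsAsFactors = FALSE)

        glen <- sum(nchar(layout$sequence))
        genomes[[gid]] <- list(genome_id = gid, group = grp,
                               species = sp_id, status = "complete",
                               scaffold_lengths = c(scf_1 = glen),
                               n50 = glen)
        calls[[gid]] <- gcalls
        cr <- table(factor(gcalls$func[!layout$noise],
                           levels = all_genes))
        content_rows[[gid]] <- as.integer(cr)
      }
    }
  }

  content <- do.call(rbind, content_rows)
  dimnames(content) <- list(names(content_rows), all_genes)

  truth <- list(species_assignment = species_assignment,
                group_assignment = group_assignment,
                true_gene_orders = truth_orders,
                true_tree = truthNewick(ids_by_group, cfg),
                gene_sequences = gene_seq_truth,
                content = content,
                core_genes = core_genes,
                gene_lengths_bp = 3L * lens)
  class(truth) <- "SyntheticTruth"

  # fragment a configured fraction into drafts (first genome kept
  # complete so a reference always exists)
  gids <- names(genomes)
  drafts <- gids[runif(length(gids)) < cfg$draft_fraction]
  drafts <- setdiff(drafts, gids[1])
  for (gid in drafts) {
    n_sc <- sample(seq(cfg$scaffolds_per_draft[1],
                       cfg$scaffolds_per_draft[2]), 1L)
    n_core <- sum(!calls[[gid]]$func %in% c("hypothetical protein",
                                            "Mobile element protein",
                                            "repeat region"))
    n_sc <- min(n_sc, max(1L, n_core - 1L))
    fr <- fragmentAssembly(genomes[[gid]], calls[[gid]], n_sc,
                           split_genes = runif(1) <
                             cfg$gene_split_probability,
                           seed = stageSeed(cfg$seed,
                                            paste0("frag_", gid)))
    genomes[[gid]] <- fr$genome
    calls[[gid]] <- fr$genecalls
  }

  list(genomes = genomes,
       genecalls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       truth = truth)
}

#' Fragment a complete genome into a shuffled draft assembly
#'
#' Cuts the circular gene layout of a complete genome into
#' \code{n_scaffolds} segments, then randomizes scaffold order and
#' orientation. Within-scaffold gene order is preserved (up to
#' whole-scaffold reversal) and the union of scaffold gene complements
#' equals the original. With \code{split_genes}, one gene at a
#' breakpoint is emitted as two partial calls whose lengths sum to the
#' full gene length.
#'
#' @param genome a genome record from \code{\link{simulateDataset}}.
#' @param genecalls this genome's gene-call data.frame.
#' @param n_scaffolds number of scaffolds to produce (>= 1).
#' @param split_genes whether to split one gene at a breakpoint.
#' @param seed integer seed.
#' @return list(genome = updated record flagged draft, genecalls =
#'   re-coordinated calls).
#' @export
fragmentAssembly <- function(genome, genecalls, n_scaffolds,
                             split_genes = FALSE, seed = 1L) {
  if (genome$status != "complete")
    stop("fragmentAssembly requires a complete genome")
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  gc <- genecalls[order(genecalls$start), , drop = FALSE]
  n <- nrow(gc)
  if (n_scaffolds > n)
    stop("n_scaffolds (", n_scaffolds, ") exceeds gene count (", n, ")")
  set.seed(seed)

  if (n_scaffolds == 1L && !isTRUE(split_genes)) {
    # single-scaffold "draft": layout unchanged, only the flag flips
    genome$status <- "draft"
    return(list(genome = genome, genecalls = genecalls))
  }

  # breakpoints between layout positions (circular): segment i runs
  # cuts[i]..cuts[i+1]-1
  cuts <- sort(sample(n, n_scaffolds))
  seg_of <- rep(NA_integer_, n)
  for (i in seq_len(n_scaffolds)) {
    from <- cuts[i]
    to <- if (i < n_scaffolds) cuts[i + 1L] - 1L else cuts[1L] - 1L + n
    seg_of[((from:to - 1L) %% n) + 1L] <- i
  }

  segs <- lapply(seq_len(n_scaffolds), function(i) {
    idx <- ((seq(cuts[i], length.out = sum(seg_of == i)) - 1L) %% n) + 1L
    gc[idx, , drop = FALSE]
  })

  if (isTRUE(split_genes) && n_scaffolds >= 1L) {
    # split the first gene of scaffold 1's segment: its tail stays, the
    # head is appended to the previous segment (circular neighbor)
    victim <- segs[[1L]][1L, , drop = FALSE]
    len <- nchar(victim$sequence)
    if (len >= 6L) {
      cut_at <- sample(seq(3L, len - 3L), 1L)
      head_part <- victim; tail_part <- victim
      head_part$sequence <- substr(victim$sequence, 1L, cut_at)
      tail_part$sequence <- substr(victim$sequence, cut_at + 1L, len)
      head_part$partial <- TRUE; tail_part$partial <- TRUE
      head_part$feature_id <- paste0(victim$feature_id, ".a")
      tail_part$feature_id <- paste0(victim$feature_id, ".b")
      prev <- if (n_scaffolds == 1L) 1L else n_scaffolds
      segs[[1L]] <- rbind(tail_part, segs[[1L]][-1L, , drop = FALSE])
      segs[[prev]] <- rbind(segs[[prev]], head_part)
    }
  }

  ord <- sample(n_scaffolds)
  flip <- runif(n_scaffolds) < 0.5
  out <- list()
  lens <- numeric(n_scaffolds)
  for (k in seq_len(n_scaffolds)) {
    seg <- segs[[ord[k]]]
    if (flip[k] && nrow(seg) > 0L) {
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
    }
    scf <- sprintf("scf_%d", k)
    stops <- cumsum(nchar(seg$sequence))
    seg$scaffold_id <- scf
    seg$start <- c(1L, head(stops, -1L) + 1L)
    seg$stop <- stops
    lens[k] <- if (nrow(seg)) stops[nrow(seg)] else 0L
    out[[k]] <- seg
  }
  new_calls <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  genome$status <- "draft"
  genome$scaffold_lengths <- setNames(lens, sprintf("scf_%d",
                                                    seq_len(n_scaffolds)))
  genome$n50 <- assemblyN50(lens)
  list(genome = genome, genecalls = new_calls)
}

#' Write a synthetic dataset to disk in exchange formats
#'
#' One RAST-dialect tab-separated annotation table and one FASTA of
#' scaffold sequences per genome, a genome metadata table, and truth
#' tables (species assignment, circular core-gene orders, true tree in
#' newick). Tables round-trip losslessly through
#' \code{\link{readRastTable}}.
#'
#' @param genomes,genecalls,truth output of \code{\link{simulateDataset}}.
#' @param directory output directory (created if absent).
#' @return data.frame manifest (file, type).
#' @export
writeDataset <- function(genomes, genecalls, truth, directory) {
  if (!length(genomes)) return(data.frame(file = character(0),
                                          type = character(0)))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  manifest <- list()
  for (gid in names(genomes)) {
    gc <- genecalls[genecalls$genome_id == gid, , drop = FALSE]
    tab <- file.path(directory, paste0(gid, ".rast.tsv"))
    writeRastTable(gc, tab)
    manifest[[length(manifest) + 1L]] <- c(tab, "rast_table")
    # scaffold FASTA: concatenated gene sequences in layout order
    fa <- file.path(directory, paste0(gid, ".fna"))
    scafs <- split(gc, gc$scaffold_id)
    seqs <- vapply(scafs, function(s)
      paste(s$sequence[order(s$start)], collapse = ""), character(1))
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- names(scafs)
    Biostrings::writeXStringSet(ss, fa)
    manifest[[length(manifest) + 1L]] <- c(fa, "fasta")
  }
  meta <- data.frame(
    genome_id = names(genomes),
    group = vapply(genomes, `[[`, character(1), "group"),
    species = vapply(genomes, `[[`, character(1), "species"),
    status = vapply(genomes, `[[`, character(1), "status"),
    n50 = vapply(genomes, `[[`, numeric(1), "n50"),
    n_scaffolds = vapply(genomes, function(g)
      length(g$scaffold_lengths), integer(1)),
    stringsAsFactors = FALSE)
  mf <- file.path(directory, "metadata.tsv")
  write.table(meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest[[length(manifest) + 1L]] <- c(mf, "metadata")

  sp <- data.frame(genome_id = names(truth$species_assignment),
                   species = unname(truth$species_assignment),
                   group = unname(
                     truth$group_assignment[truth$species_assignment]),
                   stringsAsFactors = FALSE)
  sf <- file.path(directory, "truth_species.tsv")
  write.table(sp, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest[[length(manifest) + 1L]] <- c(sf, "truth")

  of <- file.path(directory, "truth_gene_orders.tsv")
  ords <- data.frame(
    genome_id = rep(names(truth$true_gene_orders),
                    vapply(truth$true_gene_orders, length, integer(1))),
    position = unlist(lapply(truth$true_gene_orders, seq_along)),
    gene = unlist(truth$true_gene_orders), row.names = NULL,
    stringsAsFactors = FALSE)
  write.table(ords, of, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest[[length(manifest) + 1L]] <- c(of, "truth")

  tf <- file.path(directory, "truth_tree.nwk")
  writeLines(truth$true_tree, tf)
  manifest[[length(manifest) + 1L]] <- c(tf, "truth")

  out <- do.call(rbind, manifest)
  data.frame(file = out[, 1], type = out[, 2], stringsAsFactors = FALSE)
}

#' Write one genome's gene calls as a RAST-dialect table
#'
#' Columns: contig_id, feature_id, type, start, stop, strand, function,
#' nucleotide_sequence. Minus-strand features are exported with
#' start > stop, as RAST spreadsheets do.
#'
#' @param genecalls gene-call data.frame for one genome.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeRastTable <- function(genecalls, path) {
  out <- data.frame(contig_id = genecalls$scaffold_id,
                    feature_id = genecalls$feature_id,
                    type = genecalls$type,
                    start = ifelse(genecalls$strand == "-",
                                   genecalls$stop, genecalls$start),
                    stop = ifelse(genecalls$strand == "-",
                                  genecalls$start, genecalls$stop),
                    strand = genecalls$strand,
                    "function" = genecalls$func,
                    nucleotide_sequence = genecalls$sequence,
                    stringsAsFactors = FALSE, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
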