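test_that("occurrence rounding follows the documented breaks", {
  expect_identical(roundOccurrence(c(0.333, 0.667, 2, 0.5, 1.49, 1.5)),
                   c(0L, 1L, 2L, 1L, 1L, 2L))
})

test_that("species profiles average member genomes then round", {
  m <- rbind(g1 = c(A = 1L, B = 0L, C = 2L),
             g2 = c(A = 1L, B = 0L, C = 2L),
             g3 = c(A = 0L, B = 1L, C = 2L))
  sp <- c(g1 = "s1", g2 = "s1", g3 = "s1")
  tab <- data.frame(species = "s1", name = NA, status = "candidate",
                    group = NA, n_genomes = 3L)
  asg <- new("SpeciesAssignment", genomeSpecies = sp,
             speciesTable = tab)
  prof <- speciesOccurrenceProfile(annMatrix(m), asg)
  expect_identical(prof["s1", ], c(A = 1L, B = 0L, C = 2L))
})

test_that("Bray-Curtis matches hand values and metric properties", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 1, 0), c(0, 0, 2)), 1)
  # Hellinger toy: rows become (.7071, 0, .7071) and (0, .7071, .7071)
  expect_equal(brayCurtis(c(1, 0, 1), c(0, 1, 1), hellinger = TRUE),
               0.5, tolerance = 1e-10)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")

  # dual route: hand formula vs the vegan-backed implementation
  set.seed(6)
  for (i in 1:10) {
    x <- rpois(20, 2); y <- rpois(20, 2)
    if (sum(x) == 0 || sum(y) == 0) next
    hx <- sqrt(x / sum(x)); hy <- sqrt(y / sum(y))
    expect_equal(brayCurtis(x, y, hellinger = TRUE),
                 sum(abs(hx - hy)) / sum(hx + hy), tolerance = 1e-12)
    expect_equal(brayCurtis(x, y, hellinger = FALSE),
                 sum(abs(x - y)) / sum(x + y), tolerance = 1e-12)
    expect_equal(brayCurtis(x, y), brayCurtis(y, x))
  }
})

test_that("Hellinger rows are unit vectors under the squared-sum norm", {
  set.seed(7)
  m <- matrix(rpois(60, 3), 6)
  m[1, ] <- m[1, ] + 1L   # no all-zero rows
  h <- vegan::decostand(m, method = "hellinger")
  expect_equal(rowSums(h^2), rep(1, 6), ignore_attr = TRUE)
})

makeContentFixture <- function(counts, species_of) {
  ids <- rownames(counts)
  tab <- data.frame(species = unique(species_of),
                    name = NA_character_, status = "candidate",
                    group = NA_character_,
                    n_genomes = as.integer(
                      table(species_of)[unique(species_of)]),
                    stringsAsFactors = FALSE)
  list(am = annMatrix(counts),
       asg = new("SpeciesAssignment",
                 genomeSpecies = setNames(species_of, ids),
                 speciesTable = tab))
}

test_that("rarefaction is flat with zero variance on identical genomes", {
  counts <- matrix(rep(c(1L, 1L, 0L, 2L), each = 4), 4,
                   dimnames = list(paste0("g", 1:4), paste0("f", 1:4)))
  fx <- makeContentFixture(counts, paste0("s", 1:4))
  r <- rarefyPanCore(fx$am, fx$asg, setNames(rep("G1", 4),
                                             paste0("s", 1:4)),
                     replicates = 20, seed = 1)
  expect_true(all(r$pan_mean == 3))   # f1,f2,f4 present
  expect_true(all(r$core_mean == 2))  # f1,f2 single copy
  expect_true(all(r$pan_sd == 0) && all(r$core_sd == 0))
})

test_that("rarefaction means match exhaustive enumeration on a toy group", {
  # 2 species x 2 genomes; enumerate all species orders x genome picks
  counts <- rbind(g1 = c(A = 1L, B = 1L, C = 0L, D = 0L),
                  g2 = c(A = 1L, B = 0L, C = 1L, D = 0L),
                  g3 = c(A = 1L, B = 0L, C = 0L, D = 2L),
                  g4 = c(A = 1L, B = 1L, C = 1L, D = 1L))
  fx <- makeContentFixture(counts, c("s1", "s1", "s2", "s2"))
  sg <- c(s1 = "G", s2 = "G")

  pan_n <- function(rows) sum(colSums(counts[rows, , drop = FALSE]
                                      >= 1) >= 1)
  core_n <- function(rows) sum(colSums(counts[rows, , drop = FALSE]
                                       == 1) == length(rows))
  exp_pan <- c(0, 0); exp_core <- c(0, 0); combos <- 0
  for (ord in list(c("s1", "s2"), c("s2", "s1")))
    for (p1 in c(1, 2)) for (p2 in c(1, 2)) {
      picks <- c(rownames(counts)[p1 + (ord[1] == "s2") * 2],
                 rownames(counts)[p2 + (ord[2] == "s2") * 2])
      exp_pan <- exp_pan + c(pan_n(picks[1]), pan_n(picks))
      exp_core <- exp_core + c(core_n(picks[1]), core_n(picks))
      combos <- combos + 1
    }
  exp_pan <- exp_pan / combos; exp_core <- exp_core / combos

  r <- rarefyPanCore(fx$am, fx$asg, sg, replicates = 4000, seed = 5)
  se <- sqrt(pmax(r$pan_sd, r$core_sd)^2 / 4000)
  expect_equal(r$pan_mean, exp_pan, tolerance = 0.05)
  expect_equal(r$core_mean, exp_core, tolerance = 0.05)
  # within-replicate monotonicity comes with nesting: pan up, core down
  expect_true(all(diff(r$pan_mean) >= -1e-9))
  expect_true(all(diff(r$core_mean) <= 1e-9))
})

test_that("rarefaction truncates when more species are requested than exist", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"),
                                             c("A", "B")))
  fx <- makeContentFixture(counts, c("s1", "s2"))
  expect_warning(
    r <- rarefyPanCore(fx$am, fx$asg, c(s1 = "G", s2 = "G"),
                       n_max = 5, replicates = 3, seed = 1),
    "truncated")
  expect_identical(max(r$n), 2L)
})

test_that("Venn regions behave on disjoint and identical group pools", {
  counts <- rbind(g1 = c(A = 1L, B = 1L, C = 0L, D = 0L),
                  g2 = c(A = 0L, B = 0L, C = 1L, D = 1L))
  fx <- makeContentFixture(counts, c("s1", "s2"))
  sg <- c(s1 = "X", s2 = "Y")
  v <- suppressWarnings(vennOverlap(fx$am, fx$asg, sg,
                                    species_per_group = 1,
                                    replicates = 2, seed = 1))
  pan <- setNames(v$pan$mean, v$pan$region)
  expect_equal(pan[["X"]], 2); expect_equal(pan[["Y"]], 2)
  expect_equal(pan[["X&Y"]], 0)

  counts2 <- rbind(g1 = c(A = 1L, B = 1L), g2 = c(A = 1L, B = 1L))
  fx2 <- makeContentFixture(counts2, c("s1", "s2"))
  v2 <- suppressWarnings(vennOverlap(fx2$am, fx2$asg, sg,
                                     species_per_group = 1,
                                     replicates = 2, seed = 1))
  pan2 <- setNames(v2$pan$mean, v2$pan$region)
  expect_equal(pan2[["X&Y"]], 2)
  expect_equal(pan2[["X"]], 0); expect_equal(pan2[["Y"]], 0)
  expect_error(vennOverlap(fx$am, fx$asg, c(s1 = "X", s2 = "X")),
               "2 groups")
})

test_that("Venn regions equal exhaustive values when sampling is degenerate", {
  # every group holds <= species_per_group species: no randomness
  counts <- rbind(g1 = c(A = 1L, B = 1L, C = 0L),
                  g2 = c(A = 1L, B = 0L, C = 0L),
                  g3 = c(A = 1L, B = 0L, C = 1L))
  fx <- makeContentFixture(counts, c("s1", "s2", "s3"))
  sg <- c(s1 = "X", s2 = "X", s3 = "Y")
  v <- suppressWarnings(vennOverlap(fx$am, fx$asg, sg,
                                    species_per_group = 15,
                                    replicates = 3, seed = 2))
  pan <- setNames(v$pan$mean, v$pan$region)
  core <- setNames(v$core$mean, v$core$region)
  # X pan {A,B}, Y pan {A,C}: shared {A}, X-only {B}, Y-only {C}
  expect_equal(unname(pan[c("X", "Y", "X&Y")]), c(1, 1, 1))
  # X core {A} (B absent in s2), Y core {A,C}
  expect_equal(unname(core[c("X", "Y", "X&Y")]), c(0, 1, 1))
  expect_true(all(v$pan$sd == 0))
})

test_that("binary export writes presence strings and round-trips", {
  m <- rbind(g1 = c(A = 1L, B = 0L, C = 2L),
             g2 = c(A = 0L, B = 1L, C = 0L))
  path <- withr::local_tempfile(fileext = ".fasta")
  exportBinaryMatrix(m, path)
  lines <- readLines(path)
  expect_identical(lines[lines == ">g1" | lines == ">g2"],
                   c(">g1", ">g2"))
  expect_identical(lines[which(lines == ">g1") + 1L], "101")
  back <- readBinaryMatrix(path)
  expect_identical(back, ifelse(m >= 1L, 1L, 0L))
  expect_identical(nrow(back), 2L)
})
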