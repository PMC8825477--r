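test_that("example parents are consistent with the panel and fully phased", {
  panel <- populus_panel()
  par <- example_parents(panel)
  expect_equal(par$mother$ploidy, 2L)
  expect_equal(par$father$ploidy, 3L)
  expect_setequal(names(par$father$alleles_by_locus), panel$name)
  # disjoint allele sets by default: every marker discriminates
  expect_setequal(discriminating_markers(par$mother, par$father, panel),
                  panel$name)
  # with shared markers, only the remainder discriminates
  shared <- setdiff(panel$name, populus_discriminating_markers())
  par2 <- example_parents(panel, shared_markers = shared)
  expect_setequal(discriminating_markers(par2$mother, par2$father, panel),
                  populus_discriminating_markers())
  # haplotypes carry one allele per homolog per locus
  h1 <- par$father$haplotypes[["6"]]
  expect_equal(dim(h1), c(3L, 3L))
  expect_setequal(rownames(h1), panel$name[panel$chromosome == 6L])
})

test_that("FDR restitution without loss transmits the father's full genotype", {
  panel <- tiny_panel()
  par <- tiny_parents(panel)
  set.seed(1)
  g <- simulate_triploid_meiosis(par$father,
                                 meiosis_params(p_fdr = 1), panel)
  expect_equal(g$mode, "FDR")
  expect_equal(g$chromosome_count, 2L * 3L)
  expect_true(all(lengths(g$copies) == 3L))
  for (chr in names(g$copies)) {
    for (m in rownames(par$father$haplotypes[[chr]])) {
      transmitted <- sort(vapply(g$copies[[chr]], `[[`, numeric(1), m))
      expect_equal(transmitted,
                   sort(as.numeric(names(par$father$alleles_by_locus[[m]]))))
    }
  }
  expect_error(simulate_triploid_meiosis(par$mother, meiosis_params(), panel),
               "triploid")
})

test_that("normal reduced meiosis follows the unequal 1:2 segregation pattern", {
  panel <- tiny_panel()
  par <- tiny_parents(panel)
  draws <- 1e4L
  set.seed(42)
  copies <- integer(draws)
  for (i in seq_len(draws)) {
    g <- simulate_triploid_meiosis(par$father, meiosis_params(), panel)
    copies[i] <- length(g$copies[["1"]])
  }
  expect_setequal(unique(copies), c(1L, 2L))
  se <- stats::sd(copies) / sqrt(draws)
  expect_lt(abs(mean(copies) - 1.5), 3 * se + 1e-12)

  # 10% lagging-chromosome loss scales the mean to 1.5 * 0.9
  set.seed(43)
  copies2 <- vapply(seq_len(draws), function(i) {
    length(simulate_triploid_meiosis(
      par$father, meiosis_params(elimination_rate = 0.1, gain_rate = 0),
      panel)$copies[["1"]])
  }, integer(1))
  se2 <- stats::sd(copies2) / sqrt(draws)
  expect_lt(abs(mean(copies2) - 1.35), 3 * se2 + 1e-12)
})

test_that("eggs are reduced: one allele per locus, Mendelian segregation", {
  panel <- tiny_panel()
  par <- tiny_parents(panel)
  set.seed(11)
  g <- simulate_egg(par$mother, meiosis_params(), panel)
  expect_equal(g$chromosome_count, 2L)
  expect_true(all(lengths(g$copies) == 1L))
  ma <- as.numeric(names(par$mother$alleles_by_locus[["mA1"]]))
  draws <- 1e4L
  seen <- vapply(seq_len(draws), function(i)
    simulate_egg(par$mother, meiosis_params(), panel)$copies[["1"]][[1L]][["mA1"]],
    numeric(1))
  expect_true(all(seen %in% ma))
  p <- mean(seen == ma[1L])
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / draws))
  # homozygous maternal locus always transmits its allele
  hom <- parental_genotype("Mh", 2L, list(mA1 = c(`120` = 2L)),
                           haplotypes = list(`1` = matrix(c(120, 120), 1,
                             dimnames = list("mA1", NULL))))
  expect_equal(simulate_egg(hom, meiosis_params(crossover_model = "none"),
                            panel)$copies[["1"]][[1L]][["mA1"]], 120)
  expect_error(simulate_egg(par$father, meiosis_params(), panel), "diploid")
})

test_that("fertilization unions gametes additively and enforces pollen viability", {
  panel <- populus_panel()
  par <- example_parents(panel)
  params <- meiosis_params(p_fdr = 1, viability_min_chromosomes = 29L)
  set.seed(5)
  egg <- simulate_egg(par$mother, params, panel)
  pollen <- simulate_triploid_meiosis(par$father, params, panel)
  expect_equal(pollen$chromosome_count, 57L)
  child <- fertilize(egg, pollen, params)
  expect_equal(unname(child$truth_copies), rep(4L, 19))
  expect_equal(ploidy_class_from_copies(child$truth_copies)$label, "tetraploid")
  # per-locus dosages are the multiset union of the gametes
  for (m in c("LG_I_918", "LG_VI_4649"))
    expect_equal(sum(child$alleles_by_locus[[m]]), 4L)
  # pollen below the viability floor is rejected
  weak_pollen <- pollen
  weak_pollen$chromosome_count <- 27L
  expect_null(fertilize(egg, weak_pollen, params))
})

test_that("peak synthesis follows the dosage x size-decay x noise model", {
  panel <- as_marker_panel(data.frame(
    name = "mX", chromosome = 1L, size_min = 195, size_max = 260,
    dye = "FAM", position_rank = 1L, stringsAsFactors = FALSE))
  geno <- list(S1 = list(alleles_by_locus = list(mX = c(`200` = 2L, `220` = 1L))))
  # sigma 0, no decay: signals exactly proportional to dosage
  pk <- synthesize_peaks(geno, panel,
                         peak_noise_model(sigma = 0, size_decay = 1,
                                          size_jitter = 0))
  expect_equal(pk$height[1L] / pk$height[2L], 2, tolerance = 1e-9)
  # dosage 2:1 at 200 vs 220 bp with decay 0.995: ratio 2 / 0.995^20
  pk2 <- synthesize_peaks(geno, panel,
                          peak_noise_model(sigma = 0, size_decay = 0.995,
                                           size_jitter = 0))
  expect_equal(pk2$height[1L] / pk2$height[2L], 2 / 0.995^20, tolerance = 1e-9)
  # allele outside the size window is a fixture bug
  bad <- list(S1 = list(alleles_by_locus = list(mX = c(`300` = 1L))))
  expect_error(synthesize_peaks(bad, panel, peak_noise_model()), "size window")
  # a five-allele locus re-bins to five alleles downstream
  five <- list(S1 = list(alleles_by_locus = list(mX = stats::setNames(
    rep(1L, 3), c("200", "206", "212")))),
    S2 = list(alleles_by_locus = list(mX = c(`218` = 1L, `224` = 2L))))
  set.seed(2)
  pk5 <- synthesize_peaks(five, panel, peak_noise_model(sigma = 0.05))
  pk5$signal <- pk5$height
  expect_equal(length(unique(bin_peaks_to_alleles(pk5)$allele)), 5L)
})

test_that("population simulation is seed-reproducible with coherent truth labels", {
  expect_equal(nrow(simulate_population(n = 0, seed = 1)$peaks), 0L)
  a <- simulate_population(n = 8, seed = 99)
  b <- simulate_population(n = 8, seed = 99)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth_copies, b$truth_copies)
  expect_identical(a$truth_classes, b$truth_classes)
  # conservation: no offspring allele absent from both parents
  parental <- unlist(lapply(c(a$genotypes[[1L]]$alleles_by_locus,
                              a$genotypes[[2L]]$alleles_by_locus), names))
  off <- a$genotypes[grep("^S", names(a$genotypes))]
  for (o in off)
    expect_true(all(unlist(lapply(o$alleles_by_locus, names)) %in% parental))
  # pure FDR with no loss gives only tetraploids
  tet <- simulate_population(n = 6, params = meiosis_params(p_fdr = 1),
                             seed = 4)
  expect_true(all(tet$truth_classes == "tetraploid"))
  # mixed parameters yield both triploid- and tetraploid-range classes
  mix <- simulate_population(n = 40, params = meiosis_params(
    p_fdr = 0.5, elimination_rate = 0.05), seed = 10)
  expect_true(any(grepl("triploid", mix$truth_classes)) &&
              any(grepl("tetraploid", mix$truth_classes)))
  # an impossible corner fails loudly rather than spinning
  expect_error(simulate_population(n = 1, params = meiosis_params(
    viability_min_chromosomes = 60L), seed = 1, max_attempts = 200L),
    "attempts")
})

test_that("gamete copy-number support matches the meiotic mode", {
  panel <- tiny_panel()
  par <- tiny_parents(panel)
  draw <- function(params, n = 400L) {
    lapply(seq_len(n), function(i)
      simulate_triploid_meiosis(par$father, params, panel))
  }
  set.seed(8)
  fdr <- marker_chromosome_gamete_distribution(draw(meiosis_params(p_fdr = 1)), 1)
  expect_equal(unname(fdr["3"]), 400L)     # point mass at 3 without loss
  normal <- marker_chromosome_gamete_distribution(draw(meiosis_params()), 1)
  expect_true(all(normal[c("0", "3", "4")] == 0L))
  expect_true(all(normal[c("1", "2")] > 0L))
  # support spans 0..4 only when restitution and missegregation co-occur
  both <- marker_chromosome_gamete_distribution(
    draw(meiosis_params(p_fdr = 1, elimination_rate = 0.3, gain_rate = 0.3),
         n = 2000L), 1)
  expect_true(all(both > 0L))
  noloss <- marker_chromosome_gamete_distribution(
    draw(meiosis_params(p_fdr = 0.5)), 1)
  expect_true(all(noloss[c("0", "4")] == 0L))
})

test_that("FDR and SDR retention hit the crossover-model closed forms", {
  # no crossovers: FDR keeps everything, SDR nothing
  expect_equal(fdr_sdr_retention("FDR", "none", reps = 200, seed = 1), 1)
  expect_equal(fdr_sdr_retention("SDR", "none", reps = 200, seed = 1), 0)
  # single obligate uniform crossover, loci uniform on the arm:
  # FDR = P(proximal) + P(distal)/2 = 0.75, SDR = P(distal) = 0.50
  fdr <- fdr_sdr_retention("FDR", "single_obligate_uniform", reps = 1e4,
                           seed = 2)
  sdr <- fdr_sdr_retention("SDR", "single_obligate_uniform", reps = 1e4,
                           seed = 2)
  expect_lt(abs(fdr - 0.75), 0.02)
  expect_lt(abs(sdr - 0.50), 0.02)
  # FDR exceeds SDR under every crossover model
  for (cm in c("none", "single_obligate_uniform", "poisson")) {
    f <- fdr_sdr_retention("FDR", cm, reps = 3000, seed = 3)
    s <- fdr_sdr_retention("SDR", cm, reps = 3000, seed = 3)
    expect_gt(f, s)
  }
  expect_error(fdr_sdr_retention("XDR"), "arg")
})
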