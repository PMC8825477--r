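#' The 47-marker Populus SSR reference panel
#'
#' A marker panel of 47 SSR loci covering all 19 *Populus* chromosomes,
#' following the published layout for the TB03 x 'Yinzhong' cross (marker
#' names and chromosome assignments as reported for that panel). Fragment
#' size windows and dye labels are synthetic plumbing: the sources report
#' neither, and nothing downstream depends on their specific values.
#'
#' @return A `marker_panel` with 47 rows.
#' @export
populus_panel <- function() {
  markers <- list(
    `1` = c("LG_I_918", "LG_I_7828", "U16", "U21902"),
    `2` = c("LG_II_2319", "Pop_02_5006", "Pop_02_7518"),
    `3` = c("LG_III_6624", "Pop_03_4203"),
    `4` = c("LG_IV_5071", "Pop_04_3397"),
    `5` = c("GCPM_3536-2"),
    `6` = c("LG_VI_1534", "Pop_06_1171", "LG_VI_4649"),
    `7` = c("GCPM_1054-1", "Pop_07_2598"),
    `8` = c("PMGC_2607"),
    `9` = c("Pop_09_501", "Pop_09_1080"),
    `10` = c("PMGC_2163", "Pop_10_2614", "Pop_10_3412"),
    `11` = c("Pop_11_580", "Pop_11_827", "GCPM_790-1", "Pop_11_3271"),
    `12` = c("Pop_12_1990", "Pop_12_2242"),
    `13` = c("Pop_13_94", "Pop_13_293"),
    `14` = c("Pop_14_422", "LG_XIV_584", "GCPM_1175-1"),
    `15` = c("Pop_15_764", "Pop_15_1904", "Pop_15_2638"),
    `16` = c("LG_XVI_2403", "GCPM_67", "Pop_16_1501"),
    `17` = c("Pop_17_882"),
    `18` = c("Pop_18_1647", "Pop_18_1887", "GCPM_1920-1", "GCPM_162-1"),
    `19` = c("Pop_19_1801", "LG_XIX_4912"))
  name <- unlist(markers, use.names = FALSE)
  chromosome <- rep(as.integer(names(markers)), lengths(markers))
  rank <- unlist(lapply(lengths(markers), seq_len), use.names = FALSE)
  i <- seq_along(name)
  size_min <- 100 + 5 * ((i - 1L) %% 40L)
  dyes <- c("FAM", "HEX", "TAMRA", "ROX")
  as_marker_panel(data.frame(
    name = name, chromosome = chromosome, size_min = size_min,
    size_max = size_min + 60, dye = dyes[(i - 1L) %% 4L + 1L],
    position_rank = rank, stringsAsFactors = FALSE))
}

#' Markers amplifying fully different fragments between the two parents
#'
#' The 12 markers (on 11 chromosomes) at which the example parents share no
#' allele, mirroring the fully discriminating subset reported for the real
#' cross; used to verify the maternal contribution.
#'
#' @return Character vector of 12 marker names.
#' @export
populus_discriminating_markers <- function() {
  c("LG_I_918", "Pop_02_7518", "Pop_03_4203", "Pop_04_3397", "PMGC_2607",
    "PMGC_2163", "Pop_11_3271", "Pop_13_293", "GCPM_67", "Pop_18_1647",
    "GCPM_162-1", "Pop_19_1801")
}

#' Deterministic example parents for the 2x x 3x cross
#'
#' Builds a diploid mother and a fully heterozygous triploid father over a
#' marker panel. The father carries three distinct alleles at every locus
#' (one per homolog); the mother carries two. By default the maternal allele
#' sets are disjoint from the paternal set at every marker, which makes every
#' true offspring dosage vector primitive (the maternal allele always has
#' dosage 1) and hence exactly recoverable from peak ratios; pass
#' `shared_markers` to emulate real crosses where the parents share an
#' allele at some loci (e.g. all panel markers except
#' [populus_discriminating_markers()]). Alleles sit on a >= 6 bp grid inside
#' each marker's size window, so binning at the default tolerance is
#' unambiguous. Phased haplotypes are attached for the meiosis simulator.
#'
#' @param panel `marker_panel` (default [populus_panel()]).
#' @param mother_id,father_id Parent identifiers.
#' @param shared_markers Markers at which the mother shares her first allele
#'   with the father (default none).
#' @return List with elements `mother` and `father` (`parental_genotype`
#'   objects with haplotypes).
#' @export
example_parents <- function(panel = populus_panel(),
                            mother_id = "TB03", father_id = "YZ",
                            shared_markers = character(0)) {
  father_alleles <- mother_alleles <- list()
  for (i in seq_len(nrow(panel))) {
    m <- panel$name[i]
    base <- panel$size_min[i]
    fa <- base + c(10, 16, 22)
    ma <- if (m %in% shared_markers) base + c(10, 34) else base + c(34, 40)
    father_alleles[[m]] <- stats::setNames(rep(1L, 3L), as.character(fa))
    mother_alleles[[m]] <- stats::setNames(rep(1L, 2L), as.character(ma))
  }
  mk_haps <- function(alleles, ploidy) {
    haps <- list()
    for (chr in sort(unique(panel$chromosome))) {
      mk <- panel[panel$chromosome == chr, , drop = FALSE]
      mk <- mk[order(mk$position_rank), , drop = FALSE]
      mat <- t(vapply(mk$name,
                      function(m) as.numeric(names(alleles[[m]])),
                      numeric(ploidy)))
      if (nrow(mk) == 1L) mat <- matrix(mat, nrow = 1L,
                                        dimnames = list(mk$name, NULL))
      rownames(mat) <- mk$name
      haps[[as.character(chr)]] <- mat
    }
    haps
  }
  list(mother = parental_genotype(mother_id, 2L, mother_alleles,
                                  haplotypes = mk_haps(mother_alleles, 2L)),
       father = parental_genotype(father_id, 3L, father_alleles,
                                  haplotypes = mk_haps(father_alleles, 3L)))
}

#' Meiosis simulator parameters
#'
#' @param p_fdr Probability a pollen grain arises by first-division
#'   restitution (FDR; transmits all three homologs of each chromosome).
#' @param p_sdr Probability of second-division restitution (SDR; transmits
#'   two sister-derived copies of one homolog). `p_fdr + p_sdr <= 1`; the
#'   remainder is normal reduced meiosis with unequal 1:2 segregation.
#' @param elimination_rate Per-copy probability that a transmitted chromosome
#'   is lost as a lagging chromosome.
#' @param gain_rate Per-chromosome probability that a restitution (FDR/SDR)
#'   gamete additionally captures a leftover sister chromatid (nondisjunction
#'   into the fused nucleus), the route to 4-copy chromosomes in unreduced
#'   pollen and hence hyper-tetraploid offspring. Defaults to
#'   `elimination_rate / 5`: chromosome gains in interploidy-cross progeny
#'   are several-fold rarer than losses.
#' @param crossover_model `"none"`, `"single_obligate_uniform"` (one
#'   crossover per chromosome at the four-strand stage, position uniform
#'   along the arm) or `"poisson"` (count drawn from `map_length_cM / 100`).
#' @param map_length_cM Genetic length used by the Poisson model.
#' @param viability_min_chromosomes Minimum pollen chromosome count for
#'   fertility (default 29, just above 3x/2 = 28.5 for x = 19: aneuploid
#'   pollen below half the triploid complement is taken as inviable).
#' @return A `meiosis_params` object.
#' @export
meiosis_params <- function(p_fdr = 0, p_sdr = 0, elimination_rate = 0,
                           gain_rate = elimination_rate / 5,
                           crossover_model = c("single_obligate_uniform",
                                               "none", "poisson"),
                           map_length_cM = 100,
                           viability_min_chromosomes = 29L) {
  crossover_model <- match.arg(crossover_model)
  assert_scalar_number(p_fdr, "p_fdr", 0, 1)
  assert_scalar_number(p_sdr, "p_sdr", 0, 1)
  if (p_fdr + p_sdr > 1) stop("p_fdr + p_sdr must be <= 1", call. = FALSE)
  assert_scalar_number(elimination_rate, "elimination_rate", 0, 1)
  assert_scalar_number(gain_rate, "gain_rate", 0, 1)
  assert_scalar_number(viability_min_chromosomes, "viability_min_chromosomes", 0)
  structure(list(p_fdr = p_fdr, p_sdr = p_sdr,
                 elimination_rate = elimination_rate, gain_rate = gain_rate,
                 crossover_model = crossover_model,
                 map_length_cM = map_length_cM,
                 viability_min_chromosomes = as.integer(viability_min_chromosomes)),
            class = "meiosis_params")
}

#' Multiplicative peak-noise model for synthetic electropherogram summaries
#'
#' @param sigma Standard deviation of the lognormal multiplicative signal
#'   noise (0 = noise-free).
#' @param size_decay Per-bp relative amplification efficiency (must lie in
#'   (0.9, 1.1); values below 1 mean longer fragments amplify less).
#' @param base_signal Mean single-copy fluorescence signal.
#' @param size_jitter Gaussian sd (bp) of reported fragment sizes around the
#'   true allele size, emulating run-to-run electrophoretic drift.
#' @return A `peak_noise_model` object.
#' @export
peak_noise_model <- function(sigma = 0.1, size_decay = 0.997,
                             base_signal = 2000, size_jitter = 0.08) {
  assert_scalar_number(sigma, "sigma", 0)
  if (size_decay <= 0.9 || size_decay >= 1.1)
    stop("size_decay must lie in (0.9, 1.1)", call. = FALSE)
  assert_scalar_number(base_signal, "base_signal", 1e-9)
  assert_scalar_number(size_jitter, "size_jitter", 0)
  structure(list(sigma = sigma, size_decay = size_decay,
                 base_signal = base_signal, size_jitter = size_jitter),
            class = "peak_noise_model")
}

# locus positions in (0, 1) along a chromosome, from position ranks
locus_positions <- function(n) (seq_len(n) - 0.5) / n

# replicate each homolog into two chromatids and apply crossovers; returns a
# list of chromatid allele matrices (loci x 2*ploidy) plus homolog origins
make_chromatids <- function(hap_matrix, params) {
  ploidy <- ncol(hap_matrix)
  n <- nrow(hap_matrix)
  chromatids <- hap_matrix[, rep(seq_len(ploidy), each = 2L), drop = FALSE]
  origin <- rep(seq_len(ploidy), each = 2L)
  n_xo <- switch(params$crossover_model,
                 none = 0L,
                 single_obligate_uniform = 1L,
                 poisson = stats::rpois(1L, params$map_length_cM / 100))
  if (n_xo > 0L && ploidy >= 2L && n > 0L) {
    pos <- locus_positions(n)
    for (x in seq_len(n_xo)) {
      homs <- sample(seq_len(ploidy), 2L)
      c1 <- sample(which(origin == homs[1L]), 1L)
      c2 <- sample(which(origin == homs[2L]), 1L)
      u <- stats::runif(1L)
      distal <- pos > u
      if (any(distal)) {
        tmp <- chromatids[distal, c1]
        chromatids[distal, c1] <- chromatids[distal, c2]
        chromatids[distal, c2] <- tmp
      }
    }
  }
  list(chromatids = chromatids, origin = origin)
}

#' Simulate one pollen grain from triploid meiosis
#'
#' Draws the meiotic mode once per gamete: with probability `p_fdr` the grain
#' is FDR-unreduced (one crossover-shuffled chromatid from *each* of the
#' three homologs per chromosome), with `p_sdr` SDR-unreduced (the two sister
#' chromatids of one random homolog), otherwise normal reduced meiosis in
#' which each chromosome independently sends 1 or 2 of its 3 homologs to the
#' pole with equal probability (the unequal 1:2 anaphase pattern of a
#' trivalent). Every transmitted copy is then lost independently with
#' `elimination_rate` (lagging chromosomes).
#'
#' @param father `parental_genotype` with ploidy 3 and phased haplotypes.
#' @param params `meiosis_params`.
#' @param panel `marker_panel` (defines loci per chromosome).
#' @return A `gamete`: list with `parent_id`, `mode`, `copies` (per
#'   chromosome, a list of named allele vectors, one per transmitted copy)
#'   and `chromosome_count`.
#' @export
simulate_triploid_meiosis <- function(father, params, panel = populus_panel()) {
  if (father$ploidy != 3L)
    stop("father must be triploid (ploidy 3)", call. = FALSE)
  if (is.null(father$haplotypes))
    stop("father carries no phased haplotypes", call. = FALSE)
  u <- stats::runif(1L)
  mode <- if (u < params$p_fdr) "FDR"
          else if (u < params$p_fdr + params$p_sdr) "SDR"
          else "normal"
  copies <- list()
  for (chr in names(father$haplotypes)) {
    hap <- father$haplotypes[[chr]]
    ct <- make_chromatids(hap, params)
    picked <- switch(mode,
      FDR = vapply(1:3, function(h) sample(rep(which(ct$origin == h), 2L), 1L),
                   integer(1)),
      SDR = which(ct$origin == sample(1:3, 1L)),
      normal = {
        k <- sample(1:2, 1L)
        homs <- sample(1:3, k)
        vapply(homs, function(h) sample(rep(which(ct$origin == h), 2L), 1L),
               integer(1))
      })
    # restitution nuclei occasionally capture a leftover sister chromatid
    # (the 4-signal fused nuclei seen at telophase II)
    if (mode %in% c("FDR", "SDR") && params$gain_rate > 0 &&
        stats::runif(1L) < params$gain_rate) {
      leftover <- setdiff(seq_len(ncol(ct$chromatids)), picked)
      picked <- c(picked, leftover[sample.int(length(leftover), 1L)])
    }
    if (params$elimination_rate > 0)
      picked <- picked[stats::runif(length(picked)) >= params$elimination_rate]
    copies[[chr]] <- lapply(picked, function(j)
      stats::setNames(ct$chromatids[, j], rownames(hap)))
  }
  structure(list(parent_id = father$parent_id, mode = mode, copies = copies,
                 chromosome_count = sum(lengths(copies))),
            class = "gamete")
}

#' Simulate a normal reduced egg from the diploid mother
#'
#' Exactly one homolog-derived chromatid per chromosome (after crossovers),
#' hence one allele per locus and a chromosome count equal to the number of
#' chromosomes in the panel.
#'
#' @param mother `parental_genotype` with ploidy 2 and phased haplotypes.
#' @param params `meiosis_params` (only the crossover model is used).
#' @param panel `marker_panel`.
#' @return A `gamete`.
#' @export
simulate_egg <- function(mother, params = meiosis_params(),
                         panel = populus_panel()) {
  if (mother$ploidy != 2L)
    stop("mother must be diploid (ploidy 2)", call. = FALSE)
  if (is.null(mother$haplotypes))
    stop("mother carries no phased haplotypes", call. = FALSE)
  copies <- list()
  for (chr in names(mother$haplotypes)) {
    hap <- mother$haplotypes[[chr]]
    ct <- make_chromatids(hap, params)
    j <- sample(ncol(ct$chromatids), 1L)
    copies[[chr]] <- list(stats::setNames(ct$chromatids[, j], rownames(hap)))
  }
  structure(list(parent_id = mother$parent_id, mode = "reduced",
                 copies = copies, chromosome_count = sum(lengths(copies))),
            class = "gamete")
}

#' Fuse an egg and a pollen grain into an offspring genotype
#'
#' Pollen below `viability_min_chromosomes` is rejected (returns `NULL`):
#' severely hypo-aneuploid grains are modelled as inviable. Otherwise the
#' per-locus allele multisets of both gametes are united and the true
#' per-chromosome copy numbers recorded (egg contributes 1 per chromosome,
#' pollen 0-4).
#'
#' @param egg,pollen `gamete` objects from the diploid and triploid parent.
#' @param params `meiosis_params` (viability threshold).
#' @return An `offspring_genotype` (list with `alleles_by_locus`,
#'   `truth_copies` named by chromosome, `pollen_mode`), or `NULL` on
#'   rejection.
#' @export
fertilize <- function(egg, pollen, params) {
  if (pollen$chromosome_count < params$viability_min_chromosomes)
    return(NULL)
  chroms <- names(egg$copies)
  alleles_by_locus <- list()
  truth <- stats::setNames(integer(length(chroms)), chroms)
  for (chr in chroms) {
    all_copies <- c(egg$copies[[chr]], pollen$copies[[chr]])
    truth[chr] <- length(all_copies)
    if (length(all_copies) == 0L) next
    markers <- names(all_copies[[1L]])
    for (m in markers) {
      sizes <- vapply(all_copies, `[[`, numeric(1), m)
      tab <- table(sizes)
      alleles_by_locus[[m]] <- stats::setNames(as.integer(tab), names(tab))
    }
  }
  structure(list(alleles_by_locus = alleles_by_locus, truth_copies = truth,
                 pollen_mode = pollen$mode),
            class = "offspring_genotype")
}

#' Synthesize a capillary-electrophoresis peak table from genotypes
#'
#' For every genotype x locus x allele a peak is emitted with
#' `signal = base_signal * dosage * size_decay^(size - window_min) *
#' LogNormal(0, sigma)` and a reported size jittered around the true allele
#' size. Deterministic given the RNG state.
#'
#' @param genotypes Named list (by sample id) of objects with an
#'   `alleles_by_locus` field (`offspring_genotype` or `parental_genotype`).
#' @param panel `marker_panel`.
#' @param noise `peak_noise_model`.
#' @return Peak-table data frame (`sample_id`, `marker`, `size`, `height`).
#' @export
synthesize_peaks <- function(genotypes, panel, noise = peak_noise_model()) {
  rows <- vector("list", length(genotypes))
  for (s in names(genotypes)) {
    g <- genotypes[[s]]
    parts <- list()
    for (m in names(g$alleles_by_locus)) {
      i <- match(m, panel$name)
      if (is.na(i)) stop("genotype locus not in panel: ", m, call. = FALSE)
      dos <- g$alleles_by_locus[[m]]
      sizes <- as.numeric(names(dos))
      if (any(sizes < panel$size_min[i] | sizes > panel$size_max[i]))
        stop("allele outside size window at ", m, " (fixture bug)",
             call. = FALSE)
      signal <- noise$base_signal * as.numeric(dos) *
        noise$size_decay^(sizes - panel$size_min[i])
      if (noise$sigma > 0)
        signal <- signal * stats::rlnorm(length(signal), 0, noise$sigma)
      rep_size <- sizes + if (noise$size_jitter > 0)
        stats::rnorm(length(sizes), 0, noise$size_jitter) else 0
      parts[[m]] <- data.frame(sample_id = s, marker = m, size = rep_size,
                               height = signal, stringsAsFactors = FALSE)
    }
    rows[[s]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward-simulate an interploidy-cross progeny with truth labels
#'
#' Draws reduced eggs from the mother and pollen from triploid meiosis of
#' the father, rejects inviable pollen (resampling until `n` offspring are
#' accepted), records true per-chromosome copy numbers and ploidy classes,
#' and synthesizes a peak table for parents plus offspring.
#'
#' @param mother,father `parental_genotype` objects with haplotypes (default
#'   [example_parents()]).
#' @param n Number of accepted offspring.
#' @param params `meiosis_params`.
#' @param noise `peak_noise_model`.
#' @param panel `marker_panel`.
#' @param seed Optional integer seed (fully reproducible outputs).
#' @param max_attempts Abort if this many fertilizations all get rejected.
#' @return List with `peaks`, `truth_copies` (data frame sample x
#'   chromosome), `truth_classes` (named character), `truth_modes`,
#'   `genotypes`, `mother`, `father`, `panel`, `params`, `noise`.
#' @export
simulate_population <- function(mother = NULL, father = NULL, n = 60L,
                                params = meiosis_params(p_fdr = 0.5,
                                                        elimination_rate = 0.05),
                                noise = peak_noise_model(),
                                panel = populus_panel(), seed = NULL,
                                max_attempts = 1e5L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mother) || is.null(father)) {
    par <- example_parents(panel)
    mother <- mother %||% par$mother
    father <- father %||% par$father
  }
  offspring <- list()
  attempts <- 0L
  while (length(offspring) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("no viable offspring after ", max_attempts,
           " attempts; parameters reject everything", call. = FALSE)
    egg <- simulate_egg(mother, params, panel)
    pollen <- simulate_triploid_meiosis(father, params, panel)
    child <- fertilize(egg, pollen, params)
    if (!is.null(child)) {
      id <- sprintf("S%03d", length(offspring) + 1L)
      offspring[[id]] <- child
    }
  }
  truth_copies <- if (n > 0L) {
    df <- as.data.frame(do.call(rbind, lapply(offspring, `[[`, "truth_copies")))
    names(df) <- paste0("chr", names(df))
    cbind(data.frame(sample_id = names(offspring), stringsAsFactors = FALSE), df)
  } else data.frame(sample_id = character(), stringsAsFactors = FALSE)
  truth_classes <- vapply(offspring, function(o)
    ploidy_class_from_copies(o$truth_copies)$label, character(1))
  truth_modes <- vapply(offspring, `[[`, character(1), "pollen_mode")
  genotypes <- c(stats::setNames(list(mother, father),
                                 c(mother$parent_id, father$parent_id)),
                 offspring)
  peaks <- if (n > 0L) synthesize_peaks(genotypes, panel, noise)
           else data.frame(sample_id = character(), marker = character(),
                           size = numeric(), height = numeric(),
                           stringsAsFactors = FALSE)
  list(peaks = peaks, truth_copies = truth_copies,
       truth_classes = truth_classes, truth_modes = truth_modes,
       genotypes = genotypes, mother = mother, father = father,
       panel = panel, params = params, noise = noise)
}

#' Copy-count distribution of one chromosome across gametes
#'
#' @param gametes List of `gamete` objects.
#' @param chromosome Chromosome number.
#' @return Named integer vector of counts over copy numbers 0-4.
#' @export
marker_chromosome_gamete_distribution <- function(gametes, chromosome) {
  if (length(gametes) == 0L) stop("no gametes", call. = FALSE)
  k <- vapply(gametes, function(g)
    length(g$copies[[as.character(chromosome)]]), integer(1))
  counts <- stats::setNames(integer(5L), 0:4)
  tab <- table(k)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Heterozygosity retained by FDR- vs SDR-type unreduced gametes
#'
#' Monte-Carlo estimate of the fraction of (locus, replicate) pairs at which
#' a 2n gamete from a fully heterozygous diploid model parent still carries
#' two distinct alleles. FDR gametes combine one chromatid from each homolog
#' (non-sister), SDR gametes the two sister chromatids of one homolog.
#' Without crossovers the retention is exactly 1 (FDR) and 0 (SDR). Under
#' the single-obligate-uniform crossover model with loci uniform along one
#' arm the closed forms are 0.75 (FDR: a locus proximal to the crossover is
#' always heterozygous, a distal one with probability 1/2) and 0.50 (SDR:
#' heterozygous exactly when distal).
#'
#' @param mode `"FDR"` or `"SDR"`.
#' @param crossover_model `"none"`, `"single_obligate_uniform"` or
#'   `"poisson"`.
#' @param loci Either a single integer (that many locus positions are
#'   redrawn uniformly on (0,1) each replicate) or a fixed numeric vector of
#'   positions in (0,1).
#' @param reps Number of replicate meioses.
#' @param map_length_cM Genetic length for the Poisson model.
#' @param seed Optional integer seed.
#' @return Mean retained heterozygosity in `[0, 1]`.
#' @export
fdr_sdr_retention <- function(mode = c("FDR", "SDR"),
                              crossover_model = c("single_obligate_uniform",
                                                  "none", "poisson"),
                              loci = 10L, reps = 1e4L,
                              map_length_cM = 100, seed = NULL) {
  mode <- match.arg(mode)
  crossover_model <- match.arg(crossover_model)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fixed_pos <- if (length(loci) > 1L || !isTRUE(all.equal(loci, round(loci))))
    as.numeric(loci) else NULL
  n <- if (is.null(fixed_pos)) as.integer(loci) else length(fixed_pos)
  het <- numeric(reps)
  for (r in seq_len(reps)) {
    pos <- fixed_pos %||% stats::runif(n)
    # chromatid homolog-origin labels at each locus: rows A1,A2,B1,B2
    ct <- matrix(rep(c(1L, 1L, 2L, 2L), each = n), nrow = n)
    n_xo <- switch(crossover_model, none = 0L, single_obligate_uniform = 1L,
                   poisson = stats::rpois(1L, map_length_cM / 100))
    for (x in seq_len(n_xo)) {
      c1 <- sample(1:2, 1L); c2 <- sample(3:4, 1L)
      u <- stats::runif(1L)
      distal <- pos > u
      tmp <- ct[distal, c1]
      ct[distal, c1] <- ct[distal, c2]
      ct[distal, c2] <- tmp
    }
    g <- if (mode == "FDR") ct[, c(sample(1:2, 1L), sample(3:4, 1L)), drop = FALSE]
         else { h <- sample(c(0L, 2L), 1L); ct[, h + 1:2, drop = FALSE] }
    het[r] <- mean(g[, 1L] != g[, 2L])
  }
  mean(het)
}
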