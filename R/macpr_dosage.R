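#' Bin raw peaks into shared alleles for one marker
#'
#' Fragment sizes from capillary electrophoresis drift by fractions of a base
#' pair between runs, so the same allele appears at slightly different sizes
#' in different samples. Peaks are clustered across samples by single linkage
#' (adjacent sizes closer than `bin_tolerance` join one cluster); clusters
#' wider than `2 * bin_tolerance` are split at their largest internal gap.
#' Each cluster becomes one allele whose label is the rounded median size.
#' Within a sample, peaks falling into the same bin sum their signal.
#'
#' @param peaks Data frame of peaks for a single marker (`sample_id`, `size`,
#'   `signal`).
#' @param bin_tolerance Maximum bp gap joining two sizes into one allele
#'   (default 0.5; safe for SSR motifs spaced >= 2 bp).
#' @param size_window Optional `c(min, max)` expected fragment window; peaks
#'   outside it are excluded as off-ladder and counted in the `off_ladder`
#'   attribute of the result.
#' @return Data frame of allele calls (`sample_id`, `marker`, `allele`,
#'   `signal`), at most one row per sample x allele.
#' @export
bin_peaks_to_alleles <- function(peaks, bin_tolerance = 0.5, size_window = NULL) {
  assert_scalar_number(bin_tolerance, "bin_tolerance", lower = 1e-9)
  if (nrow(peaks) == 0L)
    return(structure(data.frame(sample_id = character(), marker = character(),
                                allele = numeric(), signal = numeric(),
                                stringsAsFactors = FALSE), off_ladder = 0L))
  if (length(unique(peaks$marker)) > 1L)
    stop("bin_peaks_to_alleles expects peaks from a single marker", call. = FALSE)
  off <- 0L
  if (!is.null(size_window)) {
    keep <- peaks$size >= size_window[1L] & peaks$size <= size_window[2L]
    off <- sum(!keep)
    peaks <- peaks[keep, , drop = FALSE]
  }
  if (nrow(peaks) == 0L)
    return(structure(data.frame(sample_id = character(), marker = character(),
                                allele = numeric(), signal = numeric(),
                                stringsAsFactors = FALSE), off_ladder = off))
  ord <- order(peaks$size)
  sizes <- peaks$size[ord]
  # single linkage: break where consecutive gap exceeds tolerance
  cl <- cumsum(c(1, diff(sizes) > bin_tolerance))
  # split over-wide clusters at their largest gap until all fit 2*tolerance
  repeat {
    widths <- tapply(sizes, cl, function(s) max(s) - min(s))
    wide <- names(widths)[widths > 2 * bin_tolerance]
    if (length(wide) == 0L) break
    id <- wide[1L]
    idx <- which(cl == as.numeric(id))
    gaps <- diff(sizes[idx])
    cut <- which.max(gaps)
    cl[idx[(cut + 1L):length(idx)]] <- max(cl) + 1L
  }
  centers <- tapply(sizes, cl, function(s) round(stats::median(s)))
  allele <- as.numeric(centers[as.character(cl)])
  d <- data.frame(sample_id = peaks$sample_id[ord], marker = peaks$marker[ord],
                  allele = allele, signal = peaks$signal[ord],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(signal ~ sample_id + marker + allele, data = d, FUN = sum)
  agg <- agg[order(agg$sample_id, agg$allele), ]
  rownames(agg) <- NULL
  structure(agg, off_ladder = off)
}

#' Fit a per-locus allele amplification-efficiency model from the parents
#'
#' Different alleles of one SSR locus amplify with different efficiency
#' (shorter fragments typically amplify better), so raw peak ratios are not
#' directly proportional to allele dosage. Because the parents' dosages are
#' known (diploid mother: dosages summing to 2; triploid father: summing to
#' 3), the per-allele efficiency is estimated as the mean of
#' `signal / known_dosage` over parental observations, renormalised to
#' geometric mean 1 within the locus. For offspring alleles never seen in a
#' parent, a log-linear size-decay slope (fit when >= 3 parental alleles are
#' available) extrapolates the efficiency.
#'
#' @param parent_calls Allele calls (from [bin_peaks_to_alleles()]) restricted
#'   to the parents, for one marker.
#' @param mother,father `parental_genotype` objects with declared dosages.
#' @param marker Marker name.
#' @param match_tol bp tolerance for matching binned alleles to declared
#'   parental allele sizes.
#' @param shrink Fraction by which per-allele log-efficiencies are pulled
#'   toward the fitted size trend when >= 3 parental alleles are available
#'   (default 0.5). Amplification bias declines smoothly with fragment
#'   length, so departures from the trend estimated from single parental
#'   observations are mostly measurement noise; `shrink = 0` keeps the raw
#'   signal/dosage ratios.
#' @return An `amplification_model`: list with `marker`, `efficiency_by_allele`
#'   (named, geometric mean 1), `size_decay` (per-bp log-efficiency slope) and
#'   `mean_size` (anchor for the fallback).
#' @export
fit_amplification_model <- function(parent_calls, mother, father, marker,
                                    match_tol = 1.0, shrink = 0.5) {
  declared <- list(mother = mother$alleles_by_locus[[marker]],
                   father = father$alleles_by_locus[[marker]])
  ids <- c(mother$parent_id, father$parent_id)
  if (is.null(declared$mother) && is.null(declared$father)) {
    warning("locus ", marker, " absent in both parents; efficiencies set to 1")
    return(structure(list(marker = marker,
                          efficiency_by_allele = stats::setNames(numeric(0), character(0)),
                          size_decay = 0, mean_size = NA_real_),
                     class = "amplification_model"))
  }
  ratios <- list()
  for (k in c("mother", "father")) {
    dec <- declared[[k]]
    if (is.null(dec)) next
    pid <- if (k == "mother") mother$parent_id else father$parent_id
    calls <- parent_calls[parent_calls$sample_id == pid, , drop = FALSE]
    if (nrow(calls) == 0L) next
    ref <- as.numeric(names(dec))
    hit <- match_allele(calls$allele, ref, tol = match_tol)
    if (anyNA(hit))
      stop("parent ", pid, " shows allele(s) at ", marker,
           " absent from its declared genotype (possible contamination): ",
           paste(calls$allele[is.na(hit)], collapse = ", "), call. = FALSE)
    for (j in seq_along(hit)) {
      key <- format(ref[hit[j]], trim = TRUE)
      ratios[[key]] <- c(ratios[[key]], calls$signal[j] / dec[hit[j]])
    }
  }
  if (length(ratios) == 0L) {
    warning("no parental calls at ", marker, "; efficiencies set to 1")
    return(structure(list(marker = marker,
                          efficiency_by_allele = stats::setNames(numeric(0), character(0)),
                          size_decay = 0, mean_size = NA_real_),
                     class = "amplification_model"))
  }
  eff <- vapply(ratios, mean, numeric(1))
  eff <- eff / exp(mean(log(eff)))          # geometric mean 1 within the locus
  sizes <- as.numeric(names(eff))
  size_decay <- 0
  if (length(eff) >= 3L) {
    fit <- stats::lm(log(eff) ~ sizes)
    size_decay <- unname(stats::coef(fit)[2L])
    if (shrink > 0) {
      eff <- exp((1 - shrink) * log(eff) + shrink * unname(stats::fitted(fit)))
      eff <- eff / exp(mean(log(eff)))
    }
  }
  structure(list(marker = marker, efficiency_by_allele = eff,
                 size_decay = size_decay, mean_size = mean(sizes)),
            class = "amplification_model")
}

#' Predict relative amplification efficiency for alleles under a fitted model
#'
#' Known parental alleles use their fitted efficiency; unseen alleles fall
#' back to `exp(size_decay * (size - mean parental size))`.
#'
#' @param model An `amplification_model`.
#' @param alleles Numeric allele sizes (bp).
#' @return Positive efficiencies, one per allele.
#' @export
predict_efficiency <- function(model, alleles) {
  known <- model$efficiency_by_allele
  idx <- match_allele(alleles, as.numeric(names(known)), tol = 1.0)
  out <- numeric(length(alleles))
  for (i in seq_along(alleles)) {
    out[i] <- if (!is.na(idx[i])) unname(known[idx[i]])
              else if (is.na(model$mean_size)) 1
              else exp(model$size_decay * (alleles[i] - model$mean_size))
  }
  out
}

# A non-primitive dosage vector (gcd > 1) is ratio-identical to its
# primitive form; with a reduced maternal gamete the true vector is
# primitive, so reduce when the reduced total is admissible. The reduced
# call keeps the residual and is marked ambiguous (the data cannot tell the
# two apart).
reduce_to_primitive <- function(cfg, candidate_totals) {
  d <- cfg$dosage_by_allele
  g <- Reduce(function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a },
              as.integer(d))
  if (g > 1L && (cfg$total_copies %/% g) %in% candidate_totals) {
    cfg$dosage_by_allele <- stats::setNames(as.integer(d %/% g), names(d))
    cfg$total_copies <- cfg$total_copies %/% as.integer(g)
    cfg$ambiguous <- TRUE
  }
  cfg
}

# all integer vectors d >= 1 of length k summing to total (compositions)
dosage_vectors <- function(total, k) {
  if (k == 1L) return(matrix(total, nrow = 1L))
  out <- list()
  for (first in seq_len(total - k + 1L)) {
    rest <- dosage_vectors(total - first, k - 1L)
    out[[first]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Assign an allelic configuration by MAC-PR peak-ratio fitting
#'
#' The MAC-PR (microsatellite allele counting - peak ratios) step: given the
#' observed signal proportions of the alleles called for one sample at one
#' locus, every integer dosage vector `d` (each allele >= 1 copy, total in
#' `candidate_totals`) is scored by the squared distance between the observed
#' proportions and the efficiency-adjusted expected proportions
#' `d * e / sum(d * e)`. The minimising vector is returned. When the best
#' vector of a *different* total copy number fits within `tie_tolerance` of
#' the winner, the call is flagged `ambiguous` (retained, but down-weighted
#' by the karyotyping stage).
#'
#' Alleles whose efficiency-normalised proportion falls below `min_prop` are
#' treated as stutter/background and dropped before fitting.
#'
#' Signal proportions determine a dosage vector only up to scalar multiples:
#' `a:b = 1:1` and `2:2` predict identical peak ratios. Exact residual ties
#' are therefore resolved to the smallest total — the primitive (gcd 1)
#' vector. In progeny of a cross with a reduced maternal gamete the true
#' vector always contains a dosage-1 maternal allele, so it is primitive and
#' this resolution recovers it.
#'
#' @param calls Allele calls for one sample x marker (columns `allele`,
#'   `signal`), or a named numeric vector of signals keyed by allele size.
#' @param model `amplification_model` for the locus.
#' @param candidate_totals Integer set of admissible total copy numbers
#'   (default 1:6: in a 2x x 3x cross the additive rule egg 1 + pollen 0-4
#'   spans 1-5 copies, and 6 leaves headroom).
#' @param tie_tolerance Residual difference below which two totals are
#'   considered tied (default 0.01).
#' @param min_prop Minimum normalised signal proportion for an allele to be
#'   believed (default 0.02).
#' @param prefer_total Optional total (e.g. the sample's modal locus total)
#'   preferred among near-tied candidates; exact ties still resolve to the
#'   primitive vector.
#' @return An `allelic_config`: list with `sample_id`, `marker`,
#'   `dosage_by_allele` (named integer vector), `total_copies`,
#'   `fit_residual`, `ambiguous`. Returns `NULL` for zero total signal
#'   (missing data).
#' @export
assign_allelic_configuration <- function(calls, model,
                                         candidate_totals = 1:6,
                                         tie_tolerance = 0.01,
                                         min_prop = 0.02,
                                         prefer_total = NULL) {
  if (is.data.frame(calls)) {
    signals <- stats::setNames(calls$signal, format(calls$allele, trim = TRUE))
    sample_id <- calls$sample_id[1L] %||% NA_character_
    marker <- calls$marker[1L] %||% model$marker
  } else {
    signals <- calls
    sample_id <- NA_character_
    marker <- model$marker
  }
  candidate_totals <- sort(unique(as.integer(candidate_totals)))
  if (length(signals) == 0L || sum(signals) <= 0) return(NULL)
  alleles <- as.numeric(names(signals))
  eff <- predict_efficiency(model, alleles)
  norm <- signals / eff
  keep <- norm / sum(norm) >= min_prop
  signals <- signals[keep]; alleles <- alleles[keep]; eff <- eff[keep]
  k <- length(alleles)
  if (k == 0L) return(NULL)
  feasible <- candidate_totals[candidate_totals >= k]
  if (length(feasible) == 0L)
    stop("no candidate total can hold ", k, " distinct alleles at ", marker,
         call. = FALSE)
  obs <- as.numeric(signals) / sum(signals)
  best_by_total <- lapply(feasible, function(t) {
    D <- dosage_vectors(t, k)
    expd <- D * rep(eff, each = nrow(D))
    expp <- expd / rowSums(expd)
    res <- rowSums((expp - rep(obs, each = nrow(D)))^2)
    i <- which.min(res)
    list(total = t, dosage = D[i, ], residual = res[i])
  })
  res <- vapply(best_by_total, `[[`, numeric(1), "residual")
  totals <- vapply(best_by_total, `[[`, integer(1), "total")
  # Selection among candidate totals (totals ascend):
  # 1. exact residual ties are scalar-multiple dosage vectors (1:1 vs 2:2
  #    predict identical ratios); resolve to the primitive (smallest) one,
  #    which is the true vector whenever a reduced maternal gamete
  #    contributes a dosage-1 allele;
  # 2. among near-ties (within tie_tolerance) prefer `prefer_total` when
  #    given — in a near-euploid genome most loci share the modal total;
  # 3. otherwise parsimony: larger totals offer a finer grid of expected
  #    proportions and overfit noise by a few 1e-3 in residual, while
  #    genuinely different dosage vectors differ by >= ~0.03, so take the
  #    smallest near-tied total.
  near <- which(res - min(res) < tie_tolerance)
  exact <- which(res - min(res) < 1e-9)
  win_i <- if (length(exact) > 1L) exact[1L]
           else if (!is.null(prefer_total) && prefer_total %in% totals[near])
             near[match(prefer_total, totals[near])]
           else near[1L]
  win <- best_by_total[[win_i]]
  # exact-equal alternatives are the scalar-multiple family already resolved
  # by primitivity; only genuinely competing totals raise the ambiguity flag
  others <- res[totals != win$total & abs(res - win$residual) >= 1e-9]
  ambiguous <- length(others) > 0L && min(others) - win$residual < tie_tolerance
  dosage <- stats::setNames(as.integer(win$dosage), format(alleles, trim = TRUE))
  structure(list(sample_id = sample_id, marker = marker,
                 dosage_by_allele = dosage,
                 total_copies = as.integer(win$total),
                 fit_residual = win$residual, ambiguous = ambiguous),
            class = "allelic_config")
}

#' Call allelic configurations for a whole peak table
#'
#' End-to-end MAC-PR dosage calling: peaks are binned to alleles per marker
#' (within the panel's size windows), amplification efficiencies are fitted
#' from the parents' known-dosage peaks, and every offspring sample x locus
#' is assigned an integer allelic configuration.
#'
#' Totals are fitted in two passes. Pass one fits every locus independently
#' over `candidate_totals`. Pass two recomputes only the loci whose total
#' deviates from the sample's modal locus total, restricting candidates to
#' `modal - 1, modal, modal + 1` plus the pass-one winner: most loci of a
#' sample share its ploidy, and deviants (real aneuploidy or segmental
#' variants) are re-examined against nearby totals rather than locked to the
#' mode; keeping the pass-one winner in the set prevents a decisively
#' deviant locus from being forced into the modal window.
#'
#' @param peaks Peak table (see [read_peak_table()]).
#' @param panel `marker_panel`.
#' @param mother,father `parental_genotype` objects; their `parent_id`s
#'   identify parental rows inside `peaks`.
#' @param candidate_totals,bin_tolerance,tie_tolerance,min_prop See
#'   [assign_allelic_configuration()] and [bin_peaks_to_alleles()].
#' @param two_pass Disable to keep the independent per-locus fits.
#' @return Long data frame (class `genotype_calls`) with one row per sample x
#'   marker x allele: `sample_id`, `marker`, `allele`, `dosage`,
#'   `total_copies`, `fit_residual`, `ambiguous`. The per-sample modal totals
#'   are attached as attribute `genome_modal`.
#' @export
call_dosages <- function(peaks, panel, mother, father,
                         candidate_totals = 1:6, bin_tolerance = 0.5,
                         tie_tolerance = 0.01, min_prop = 0.02,
                         two_pass = TRUE) {
  if (!"signal" %in% names(peaks)) peaks$signal <- peaks$height
  parent_ids <- c(mother$parent_id, father$parent_id)
  configs <- list()
  models <- list()
  calls_by_marker <- list()
  for (i in seq_len(nrow(panel))) {
    m <- panel$name[i]
    pk <- peaks[peaks$marker == m, , drop = FALSE]
    if (nrow(pk) == 0L) next
    calls <- bin_peaks_to_alleles(pk, bin_tolerance = bin_tolerance,
                                  size_window = c(panel$size_min[i], panel$size_max[i]))
    if (nrow(calls) == 0L) next
    calls_by_marker[[m]] <- calls
    models[[m]] <- fit_amplification_model(
      calls[calls$sample_id %in% parent_ids, , drop = FALSE],
      mother, father, m)
    for (s in setdiff(unique(calls$sample_id), parent_ids)) {
      cfg <- assign_allelic_configuration(
        calls[calls$sample_id == s, , drop = FALSE], models[[m]],
        candidate_totals = candidate_totals, tie_tolerance = tie_tolerance,
        min_prop = min_prop)
      if (!is.null(cfg)) configs[[paste(s, m, sep = "\r")]] <- cfg
    }
  }
  if (length(configs) == 0L)
    return(structure(config_table(configs), genome_modal = integer(0)))
  samples <- unique(vapply(configs, `[[`, character(1), "sample_id"))
  modal <- stats::setNames(integer(length(samples)), samples)
  for (s in samples) {
    sc <- configs[vapply(configs, function(x) x$sample_id == s, logical(1))]
    tot <- vapply(sc, `[[`, integer(1), "total_copies")
    w <- ifelse(vapply(sc, `[[`, logical(1), "ambiguous"), 0.5, 1)
    modal[s] <- weighted_mode(tot, w)
  }
  if (two_pass) {
    for (key in names(configs)) {
      cfg <- configs[[key]]
      gm <- modal[cfg$sample_id]
      if (cfg$total_copies == gm) next
      cand2 <- intersect(candidate_totals, (gm - 1L):(gm + 1L))
      k <- length(cfg$dosage_by_allele)
      if (length(cand2[cand2 >= k]) == 0L) next
      calls <- calls_by_marker[[cfg$marker]]
      cfg2 <- assign_allelic_configuration(
        calls[calls$sample_id == cfg$sample_id, , drop = FALSE],
        models[[cfg$marker]], candidate_totals = cand2,
        tie_tolerance = tie_tolerance, min_prop = min_prop,
        prefer_total = unname(gm))
      if (!is.null(cfg2)) configs[[key]] <- reduce_to_primitive(cfg2, candidate_totals)
    }
  }
  structure(config_table(configs), genome_modal = modal)
}

#' Flatten a list of allelic configurations into a long table
#'
#' @param configs List of `allelic_config` objects.
#' @return Data frame with one row per allele of each configuration.
#' @export
config_table <- function(configs) {
  empty <- data.frame(sample_id = character(), marker = character(),
                      allele = numeric(), dosage = integer(),
                      total_copies = integer(), fit_residual = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (length(configs) == 0L) return(structure(empty, class = c("genotype_calls", "data.frame")))
  out <- do.call(rbind, lapply(configs, function(cfg) {
    data.frame(sample_id = cfg$sample_id, marker = cfg$marker,
               allele = as.numeric(names(cfg$dosage_by_allele)),
               dosage = as.integer(cfg$dosage_by_allele),
               total_copies = cfg$total_copies,
               fit_residual = cfg$fit_residual,
               ambiguous = cfg$ambiguous, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$marker, out$allele), ]
  rownames(out) <- NULL
  structure(out, class = c("genotype_calls", "data.frame"))
}
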