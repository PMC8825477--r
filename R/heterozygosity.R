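#' Observed heterozygosity at one locus
#'
#' For a mixed-ploidy population, Ho is defined here as the proportion of
#' genotyped individuals whose allelic configuration holds at least two
#' distinct alleles (so `aab` is heterozygous, `aaa` is not). Samples with no
#' configuration at the locus are excluded from the denominator.
#'
#' @param locus_configs Genotype-call rows (long form) for one marker across
#'   samples.
#' @return Ho in `[0, 1]`.
#' @export
observed_heterozygosity <- function(locus_configs) {
  if (nrow(locus_configs) == 0L)
    stop("no genotyped samples at this locus: Ho undefined", call. = FALSE)
  n_alleles <- tapply(locus_configs$allele, locus_configs$sample_id,
                      function(a) length(unique(a)))
  mean(n_alleles >= 2L)
}

#' Per-locus observed heterozygosity for a genotype-call table
#'
#' @param configs Genotype-call table (see [call_dosages()]).
#' @return Named numeric vector of Ho keyed by marker.
#' @export
ho_by_locus <- function(configs) {
  vapply(split(configs, configs$marker), observed_heterozygosity, numeric(1))
}

#' Aggregate locus heterozygosities to chromosome means
#'
#' The chromosome value is the unweighted arithmetic mean of its member-locus
#' Ho values, rounded for reporting (3 decimals by default; pass `digits =
#' Inf` for full precision). Chromosomes with no locus carrying a defined Ho
#' are omitted with a warning.
#'
#' @param ho Named numeric vector of per-locus Ho (names are marker names).
#' @param panel `marker_panel` mapping markers to chromosomes.
#' @param digits Decimal places for reporting (default 3).
#' @return Named numeric vector of Ho keyed by chromosome number.
#' @export
chromosome_heterozygosity <- function(ho, panel, digits = 3) {
  chr <- panel$chromosome[match(names(ho), panel$name)]
  if (anyNA(chr))
    stop("locus/loci not in panel: ",
         paste(names(ho)[is.na(chr)], collapse = ", "), call. = FALSE)
  out <- tapply(ho, chr, mean)
  missing <- setdiff(unique(panel$chromosome), as.integer(names(out)))
  if (length(missing) > 0L)
    warning("chromosome(s) without loci omitted: ",
            paste(missing, collapse = ", "))
  res <- stats::setNames(as.numeric(out), names(out))
  if (is.finite(digits)) res <- round(res, digits)
  res[order(as.integer(names(res)))]
}

#' Paternal heterozygosity transmission indicator for one configuration
#'
#' Did the father's pollen transmit two or more distinct alleles to this
#' offspring at this locus? The maternal contribution (one allele, since the
#' mother produces reduced eggs) is subtracted from the configuration: one
#' copy of a mother-specific allele when one is present, otherwise one copy
#' of an allele the parents share. The indicator is 1 if the remaining
#' (paternal) multiset still holds >= 2 distinct alleles. The locus is
#' informative only when the father is heterozygous there.
#'
#' @param dosage_by_allele Named integer vector: allele size -> dosage for
#'   one sample x locus.
#' @param marker Marker name.
#' @param mother,father `parental_genotype` objects.
#' @param match_tol bp tolerance for allele identity against parental sizes.
#' @return `1` or `0`; `NA` with attribute `reason = "not_informative"` when
#'   the father is homozygous or a parent lacks the locus, `NA` with
#'   `reason = "no_maternal_allele"` when no maternal allele is found in the
#'   configuration (possible null allele; pair excluded).
#' @export
paternal_transmission <- function(dosage_by_allele, marker, mother, father,
                                  match_tol = 1.0) {
  pat <- father$alleles_by_locus[[marker]]
  mat <- mother$alleles_by_locus[[marker]]
  if (is.null(pat) || is.null(mat) || length(unique(names(pat))) < 2L)
    return(structure(NA_integer_, reason = "not_informative"))
  off <- dosage_by_allele
  off_sizes <- as.numeric(names(off))
  pat_sizes <- as.numeric(names(pat))
  mat_sizes <- as.numeric(names(mat))
  shared_mat <- !is.na(match_allele(mat_sizes, pat_sizes, tol = match_tol))
  # prefer removing a mother-specific allele; fall back to a shared one
  specific <- mat_sizes[!shared_mat]
  shared <- mat_sizes[shared_mat]
  hit <- match_allele(off_sizes, specific, tol = match_tol)
  take <- which(!is.na(hit))[1L]
  if (is.na(take)) {
    hit <- match_allele(off_sizes, shared, tol = match_tol)
    take <- which(!is.na(hit))[1L]
  }
  if (is.na(take))
    return(structure(NA_integer_, reason = "no_maternal_allele"))
  off[take] <- off[take] - 1L
  off <- off[off > 0L]
  as.integer(length(off) >= 2L)
}

#' Pearson correlation between locus heterozygosity and allele count
#'
#' Standard Pearson correlation with the exact t-based two-sided p-value
#' (df = n - 2). Loci with more alleles segregating in the progeny tend to be
#' heterozygous in more individuals; this quantifies that association.
#'
#' @param ho Named numeric vector of per-locus Ho.
#' @param allele_counts Named integer vector of distinct allele counts in the
#'   progeny per locus (matched by name when both are named).
#' @return List with `r`, `p`, `df`.
#' @export
ho_allele_count_correlation <- function(ho, allele_counts) {
  if (!is.null(names(ho)) && !is.null(names(allele_counts)))
    allele_counts <- allele_counts[names(ho)]
  if (length(ho) < 3L) stop("need >= 3 loci for a correlation", call. = FALSE)
  if (stats::var(ho) == 0 || stats::var(allele_counts) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(allele_counts, ho, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Full heterozygosity and paternal-transmission summary
#'
#' Computes: Ho per locus, per chromosome (unweighted means of member loci)
#' and per ploidy group; the overall Ho (unweighted mean over loci); the
#' distinct allele count per locus; and paternal heterozygosity transmission
#' pooled over informative (sample, locus) pairs, overall and per ploidy
#' group (a sample-averaged variant is also reported for comparison).
#'
#' @param configs Genotype-call table.
#' @param panel `marker_panel`.
#' @param mother,father `parental_genotype` objects.
#' @param classes Optional named character vector mapping `sample_id` to a
#'   ploidy label; enables the per-group breakdowns.
#' @param digits Rounding for reported chromosome means (default 3).
#' @return A `heterozygosity_summary` list.
#' @export
heterozygosity_summary <- function(configs, panel, mother, father,
                                   classes = NULL, digits = 3) {
  ho <- ho_by_locus(configs)
  allele_counts <- vapply(split(configs, configs$marker),
                          function(d) length(unique(d$allele)), integer(1))
  keys <- unique(configs[c("sample_id", "marker")])
  ind <- rep(NA_integer_, nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rows <- configs[configs$sample_id == keys$sample_id[i] &
                    configs$marker == keys$marker[i], ]
    dos <- stats::setNames(rows$dosage, format(rows$allele, trim = TRUE))
    ind[i] <- paternal_transmission(dos, keys$marker[i], mother, father)
  }
  informative <- !is.na(ind)
  by_group_ho <- by_group_tr <- by_group_tr_sample <- NULL
  if (!is.null(classes)) {
    grp_of_pair <- classes[keys$sample_id]
    het_pair <- vapply(seq_len(nrow(keys)), function(i) {
      rows <- configs[configs$sample_id == keys$sample_id[i] &
                      configs$marker == keys$marker[i], ]
      length(unique(rows$allele)) >= 2L
    }, logical(1))
    by_group_ho <- vapply(split(het_pair, grp_of_pair), mean, numeric(1))
    by_group_tr <- vapply(split(ind[informative], grp_of_pair[informative]),
                          mean, numeric(1))
    sample_means <- tapply(ind[informative], keys$sample_id[informative], mean)
    grp_of_sample <- classes[names(sample_means)]
    by_group_tr_sample <- vapply(split(as.numeric(sample_means), grp_of_sample),
                                 mean, numeric(1))
  }
  structure(list(
    ho_by_locus = ho,
    ho_by_chromosome = chromosome_heterozygosity(ho, panel, digits = digits),
    ho_by_group = by_group_ho,
    overall_ho = mean(ho),
    allele_counts = allele_counts,
    paternal_transmission_by_group = by_group_tr,
    paternal_transmission_by_group_sample_mean = by_group_tr_sample,
    overall_paternal_transmission = mean(ind[informative]),
    n_informative_pairs = sum(informative)
  ), class = "heterozygosity_summary")
}
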