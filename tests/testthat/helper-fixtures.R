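# shared fixtures and independent oracles for the test suite

# a small two-chromosome panel for fast meiosis simulations
tiny_panel <- function() {
  as_marker_panel(data.frame(
    name = c("mA1", "mA2", "mB1"),
    chromosome = c(1L, 1L, 2L),
    size_min = c(100, 150, 200), size_max = c(160, 210, 260),
    dye = c("FAM", "HEX", "FAM"),
    position_rank = c(1L, 2L, 1L), stringsAsFactors = FALSE))
}

tiny_parents <- function(panel = tiny_panel()) example_parents(panel)

# flat amplification model: every allele amplifies equally
flat_model <- function(marker = "m") {
  structure(list(marker = marker,
                 efficiency_by_allele = stats::setNames(numeric(0), character(0)),
                 size_decay = 0, mean_size = NA_real_),
            class = "amplification_model")
}

# independently coded exhaustive enumerator over all dosage vectors:
# the oracle for assign_allelic_configuration's objective
oracle_dosage_fit <- function(signals, eff, totals) {
  obs <- signals / sum(signals)
  k <- length(obs)
  best <- NULL
  second_total_res <- Inf
  for (t in totals[totals >= k]) {
    grid <- do.call(expand.grid, rep(list(seq_len(t)), k))
    grid <- grid[rowSums(grid) == t, , drop = FALSE]
    best_t <- Inf
    for (i in seq_len(nrow(grid))) {
      d <- as.numeric(grid[i, ])
      p <- d * eff / sum(d * eff)
      r <- sum((p - obs)^2)
      best_t <- min(best_t, r)
      if (is.null(best) || r < best$residual - 1e-12)
        best <- list(dosage = d, total = t, residual = r)
    }
    if (!is.null(best) && t != best$total)
      second_total_res <- min(second_total_res, best_t)
  }
  # margin of the winning total over the best of any other total
  others <- vapply(totals[totals >= k], function(t) {
    if (t == best$total) return(Inf)
    grid <- do.call(expand.grid, rep(list(seq_len(t)), k))
    grid <- grid[rowSums(grid) == t, , drop = FALSE]
    min(vapply(seq_len(nrow(grid)), function(i) {
      d <- as.numeric(grid[i, ])
      sum((d * eff / sum(d * eff) - obs)^2)
    }, numeric(1)))
  }, numeric(1))
  best$margin <- if (all(is.infinite(others))) Inf else min(others) - best$residual
  best
}

# long-form genotype-call table from per-marker totals for one sample
# (alleles are synthesized as `total` distinct dosage-1 alleles so that the
# totals and allele counts are consistent)
configs_from_totals <- function(sample_id, totals_by_marker, panel,
                                ambiguous = FALSE) {
  rows <- list()
  amb <- if (length(ambiguous) == 1L)
    stats::setNames(rep(ambiguous, length(totals_by_marker)),
                    names(totals_by_marker)) else ambiguous
  for (m in names(totals_by_marker)) {
    t <- totals_by_marker[[m]]
    base <- panel$size_min[panel$name == m] + 10
    rows[[m]] <- data.frame(
      sample_id = sample_id, marker = m,
      allele = base + 4 * seq_len(t) - 4, dosage = 1L,
      total_copies = as.integer(t), fit_residual = 0,
      ambiguous = amb[[m]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# totals for a whole genome: every panel marker at `baseline` except overrides
genome_totals <- function(panel, baseline, overrides = integer(0)) {
  totals <- stats::setNames(rep(baseline, nrow(panel)), panel$name)
  totals[names(overrides)] <- overrides
  as.list(totals)
}

# minimal karyotype report carrying given SV events (for population tallies)
report_with_events <- function(sample_id, panel, events_chr,
                               baseline = 3L) {
  configs <- configs_from_totals(sample_id, genome_totals(panel, baseline),
                                 panel)
  rep <- karyotype_sample(configs, panel)
  if (length(events_chr) > 0L) {
    rep$sv_events <- data.frame(
      sample_id = sample_id, chromosome = as.integer(events_chr),
      type = "deletion", loci = "x", n_loci = 1L,
      relative_to = baseline, ambiguous = FALSE, weak = FALSE,
      stringsAsFactors = FALSE)
  }
  rep
}
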