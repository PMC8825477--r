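#' Call per-chromosome copy numbers for one sample
#'
#' Each chromosome's copy number is aggregated from the total copy numbers of
#' its genotyped loci (ordered by `position_rank`). When the sample's
#' genome-wide modal locus total (`genome_modal`) appears among the
#' chromosome's locus totals it is taken as the chromosome copy number —
#' within-chromosome deviants are then read as segmental variants rather than
#' whole-chromosome changes. Otherwise the chromosome's own modal total is
#' used (ties broken toward `genome_modal`, then toward the larger value).
#' A chromosome whose locus totals disagree is flagged `discordant`;
#' chromosomes with no genotyped locus get an `NA` call.
#'
#' @param sample_configs Genotype-call rows (long form, see [call_dosages()])
#'   for one sample.
#' @param panel `marker_panel`.
#' @param genome_modal The sample's modal locus total copy number.
#' @return Data frame of `chromosome_calls`: one row per chromosome in the
#'   panel with `sample_id`, `chromosome`, `copy_number`, `discordant`,
#'   `n_loci` and list-columns `locus_totals` (named integer vectors ordered
#'   by position) and `locus_ambiguous`.
#' @export
call_chromosome_copy_number <- function(sample_configs, panel, genome_modal) {
  sid <- unique(sample_configs$sample_id)
  if (length(sid) != 1L)
    stop("expected configurations for exactly one sample", call. = FALSE)
  per_locus <- unique(sample_configs[c("marker", "total_copies", "ambiguous")])
  chroms <- sort(unique(panel$chromosome))
  rows <- lapply(chroms, function(chr) {
    mk <- panel[panel$chromosome == chr, , drop = FALSE]
    mk <- mk[order(mk$position_rank), , drop = FALSE]
    loc <- per_locus[match(mk$name, per_locus$marker), , drop = FALSE]
    got <- !is.na(loc$marker)
    totals <- stats::setNames(loc$total_copies[got], mk$name[got])
    amb <- stats::setNames(loc$ambiguous[got], mk$name[got])
    if (length(totals) == 0L) {
      copy <- NA_integer_; disc <- NA
    } else if (genome_modal %in% totals[!amb]) {
      # only unambiguous locus fits anchor the chromosome at the genome
      # modal; an ambiguous lone deviant must not drag a truly aneuploid
      # chromosome back to the modal copy number
      copy <- as.integer(genome_modal)
      disc <- length(unique(totals)) > 1L
    } else {
      w <- ifelse(amb, 0.5, 1)
      copy <- weighted_mode(totals, w, prefer = genome_modal)
      disc <- length(unique(totals)) > 1L
    }
    data.frame(sample_id = sid, chromosome = chr, copy_number = copy,
               discordant = disc, n_loci = length(totals),
               locus_totals = I(list(totals)), locus_ambiguous = I(list(amb)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("chromosome_calls", "data.frame"))
}

#' Detect segmental duplication/deletion events on called chromosomes
#'
#' A structural-variant event is a maximal run of *adjacent* loci (by
#' `position_rank`) whose total copy numbers all deviate from the chromosome
#' copy number in the same direction: `deletion` when below, `duplication`
#' when above. When a run covers at least half of the chromosome's genotyped
#' loci the event carries `ambiguous = TRUE`: the same data equally support a
#' deletion at the run in a higher-copy chromosome or a duplication at the
#' complementary loci in a lower-copy one. An event whose member loci all had
#' ambiguous dosage fits is additionally flagged `weak` (likely noise rather
#' than a real segmental change).
#'
#' @param calls `chromosome_calls` for one sample (see
#'   [call_chromosome_copy_number()]).
#' @param panel `marker_panel` (unused beyond validation; locus order is
#'   already embedded in the calls).
#' @return Data frame of `sv_events`: `sample_id`, `chromosome`, `type`,
#'   `loci` (comma-joined marker names), `n_loci`, `relative_to`,
#'   `ambiguous`, `weak`.
#' @export
detect_structural_variants <- function(calls, panel = NULL) {
  empty <- data.frame(sample_id = character(), chromosome = integer(),
                      type = character(), loci = character(),
                      n_loci = integer(), relative_to = integer(),
                      ambiguous = logical(), weak = logical(),
                      stringsAsFactors = FALSE)
  events <- list()
  for (i in seq_len(nrow(calls))) {
    totals <- calls$locus_totals[[i]]
    copy <- calls$copy_number[i]
    if (is.na(copy) || length(totals) == 0L) next
    amb <- calls$locus_ambiguous[[i]]
    dev <- sign(totals - copy)
    r <- rle(dev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0) next
      idx <- starts[j]:ends[j]
      events[[length(events) + 1L]] <- data.frame(
        sample_id = calls$sample_id[i], chromosome = calls$chromosome[i],
        type = if (r$values[j] < 0) "deletion" else "duplication",
        loci = paste(names(totals)[idx], collapse = ","),
        n_loci = length(idx), relative_to = copy,
        ambiguous = length(idx) >= length(totals) / 2,
        weak = all(amb[idx]), stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Classify a sample's ploidy from chromosome calls and SV events
#'
#' The euploid baseline `m` is the modal chromosome copy number restricted to
#' 3 or 4 (the two euploid states reachable in a 2x x 3x cross; a modal value
#' outside that range snaps to the nearer of the two). Labels follow the
#' convention: every chromosome equal to `m` and no deletion event is
#' euploid (`triploid`/`tetraploid`); any chromosome below `m` *or* any
#' segmental deletion — with none above — makes the sample `hypo-`; any
#' chromosome above `m` with none below and no deletion makes it `hyper-`;
#' both directions at once is `complex`. A segmental deletion therefore
#' demotes an otherwise-euploid sample to `hypo-` (a genome with four copies
#' of every chromosome but a deleted fragment is not a full tetraploid);
#' duplications do not promote. Deletion events flagged `weak` (all member
#' loci ambiguous) are ignored by default.
#'
#' @param calls `chromosome_calls` for one sample.
#' @param sv_events Data frame from [detect_structural_variants()].
#' @param quorum Minimum number of called chromosomes required (default 15
#'   of 19); below it classification is refused.
#' @param ignore_weak Ignore `weak` deletion events when demoting (default
#'   TRUE).
#' @return A `ploidy_class`: list with `label`, `baseline` and `deviation`
#'   (signed per-chromosome deltas, named by chromosome).
#' @export
classify_ploidy <- function(calls, sv_events = NULL, quorum = 15L,
                            ignore_weak = TRUE) {
  copies <- calls$copy_number
  called <- !is.na(copies)
  if (sum(called) < quorum)
    stop("sample ", calls$sample_id[1L], ": only ", sum(called),
         " chromosomes called (quorum ", quorum, "); unclassifiable",
         call. = FALSE)
  copies <- copies[called]
  chroms <- calls$chromosome[called]
  n3 <- sum(copies == 3L); n4 <- sum(copies == 4L)
  m <- if (n3 > n4) 3L else if (n4 > n3) 4L
       else if (mean(copies) >= 3.5) 4L else 3L
  dev <- stats::setNames(as.integer(copies - m), chroms)
  has_del <- FALSE
  if (!is.null(sv_events) && nrow(sv_events) > 0L) {
    del <- sv_events$type == "deletion"
    if (ignore_weak) del <- del & !sv_events$weak
    has_del <- any(del)
  }
  lower <- any(dev < 0L) || has_del
  higher <- any(dev > 0L)
  base_name <- if (m == 3L) "triploid" else "tetraploid"
  label <- if (lower && higher) "complex"
           else if (lower) paste0("hypo-", base_name)
           else if (higher) paste0("hyper-", base_name)
           else base_name
  structure(list(label = label, baseline = m, deviation = dev),
            class = "ploidy_class")
}

#' Karyotype one sample: chromosome calls, SV events, ploidy class
#'
#' @param sample_configs Genotype-call rows for one sample.
#' @param panel `marker_panel`.
#' @param genome_modal Modal locus total for the sample; computed from the
#'   configurations when omitted (ambiguous fits weighted 0.5).
#' @param quorum,ignore_weak Passed to [classify_ploidy()].
#' @return A `karyotype_report`: list with `sample_id`, `calls`, `sv_events`,
#'   `ploidy` and `chromosome_total` (sum of called copy numbers).
#' @export
karyotype_sample <- function(sample_configs, panel, genome_modal = NULL,
                             quorum = 15L, ignore_weak = TRUE) {
  if (is.null(genome_modal)) {
    per_locus <- unique(sample_configs[c("marker", "total_copies", "ambiguous")])
    genome_modal <- weighted_mode(per_locus$total_copies,
                                  ifelse(per_locus$ambiguous, 0.5, 1))
  }
  calls <- call_chromosome_copy_number(sample_configs, panel, genome_modal)
  sv <- detect_structural_variants(calls, panel)
  ploidy <- classify_ploidy(calls, sv, quorum = quorum,
                            ignore_weak = ignore_weak)
  structure(list(sample_id = calls$sample_id[1L], calls = calls,
                 sv_events = sv, ploidy = ploidy,
                 chromosome_total = sum(calls$copy_number, na.rm = TRUE)),
            class = "karyotype_report")
}

#' Karyotype every sample in a genotype-call table
#'
#' @param configs Genotype-call table from [call_dosages()].
#' @param panel `marker_panel`.
#' @param quorum,ignore_weak Passed to [classify_ploidy()].
#' @return Named list of `karyotype_report` objects, one per sample.
#' @export
karyotype_population <- function(configs, panel, quorum = 15L,
                                 ignore_weak = TRUE) {
  modal <- attr(configs, "genome_modal")
  samples <- unique(configs$sample_id)
  reports <- lapply(samples, function(s) {
    karyotype_sample(configs[configs$sample_id == s, , drop = FALSE], panel,
                     genome_modal = if (!is.null(modal)) unname(modal[s]) else NULL,
                     quorum = quorum, ignore_weak = ignore_weak)
  })
  stats::setNames(reports, samples)
}

#' Check that every offspring carries exactly one maternal allele per locus
#'
#' In a 2x x 3x cross with reduced (1n) eggs, every offspring should hold
#' exactly one copy of a maternal allele at each locus. The check is
#' restricted to fully discriminating markers — those whose maternal and
#' paternal allele sets are disjoint — where maternal copies can be counted
#' unambiguously. A count of 2 at such a locus is the signature of an
#' unreduced (2n) egg.
#'
#' @param configs Genotype-call table.
#' @param mother,father `parental_genotype` objects.
#' @param panel `marker_panel`.
#' @param match_tol bp tolerance for matching called alleles to parental
#'   allele sizes.
#' @return List with `per_pair` (sample x locus maternal copy counts),
#'   `per_sample` (counts of checked/passing loci and a `pass` flag) and
#'   `all_pass`.
#' @export
verify_maternal_contribution <- function(configs, mother, father, panel,
                                         match_tol = 1.0) {
  disc <- discriminating_markers(mother, father, panel, match_tol = match_tol)
  if (length(disc) == 0L)
    stop("no discriminating markers (disjoint parental allele sets) in panel",
         call. = FALSE)
  sub <- configs[configs$marker %in% disc, , drop = FALSE]
  keys <- unique(sub[c("sample_id", "marker")])
  counts <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rows <- sub[sub$sample_id == keys$sample_id[i] & sub$marker == keys$marker[i], ]
    mat <- as.numeric(names(mother$alleles_by_locus[[keys$marker[i]]]))
    hit <- !is.na(match_allele(rows$allele, mat, tol = match_tol))
    counts[i] <- sum(rows$dosage[hit])
  }
  per_pair <- cbind(keys, maternal_copies = counts)
  rownames(per_pair) <- NULL
  per_sample <- do.call(rbind, lapply(split(per_pair, per_pair$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1L], n_loci = nrow(d),
               n_single = sum(d$maternal_copies == 1L),
               pass = all(d$maternal_copies == 1L), stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  list(per_pair = per_pair, per_sample = per_sample,
       all_pass = all(per_sample$pass))
}

#' Markers whose parental allele sets are disjoint
#'
#' @param mother,father `parental_genotype` objects.
#' @param panel `marker_panel`.
#' @param match_tol bp tolerance under which two parental alleles are
#'   considered the same fragment.
#' @return Character vector of marker names.
#' @export
discriminating_markers <- function(mother, father, panel, match_tol = 1.0) {
  mk <- intersect(panel$name, intersect(names(mother$alleles_by_locus),
                                        names(father$alleles_by_locus)))
  keep <- vapply(mk, function(m) {
    a <- as.numeric(names(mother$alleles_by_locus[[m]]))
    b <- as.numeric(names(father$alleles_by_locus[[m]]))
    all(is.na(match_allele(a, b, tol = match_tol)))
  }, logical(1))
  mk[keep]
}

#' Summarize a karyotyped population
#'
#' @param reports List of `karyotype_report` objects.
#' @return List with `dosage_freq` (per-chromosome copy-number frequency
#'   table: `chromosome`, `copy_number`, `n`, `freq`), `class_counts` (ploidy
#'   label counts), and `sv_summary` (events per chromosome with `percent` of
#'   all events, one decimal).
#' @export
summarize_population <- function(reports) {
  if (length(reports) == 0L) stop("no reports to summarize", call. = FALSE)
  calls <- do.call(rbind, lapply(reports, `[[`, "calls"))
  calls <- calls[!is.na(calls$copy_number), , drop = FALSE]
  freq <- do.call(rbind, lapply(split(calls, calls$chromosome), function(d) {
    tab <- table(d$copy_number)
    data.frame(chromosome = d$chromosome[1L],
               copy_number = as.integer(names(tab)),
               n = as.integer(tab), freq = as.numeric(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- NULL
  labels <- vapply(reports, function(r) r$ploidy$label, character(1))
  class_counts <- as.data.frame(table(label = labels), stringsAsFactors = FALSE)
  names(class_counts) <- c("label", "n")
  events <- do.call(rbind, lapply(reports, `[[`, "sv_events"))
  if (is.null(events) || nrow(events) == 0L) {
    sv_summary <- data.frame(chromosome = integer(), n_events = integer(),
                             percent = numeric(), stringsAsFactors = FALSE)
  } else {
    tab <- table(events$chromosome)
    sv_summary <- data.frame(chromosome = as.integer(names(tab)),
                             n_events = as.integer(tab),
                             percent = round(100 * as.numeric(tab) / nrow(events), 1),
                             stringsAsFactors = FALSE)
  }
  list(dosage_freq = freq, class_counts = class_counts, sv_summary = sv_summary,
       n_samples = length(reports), n_sv_events = if (is.null(events)) 0L else nrow(events))
}

#' Ploidy class directly from a vector of true chromosome copy numbers
#'
#' Convenience for truth-labelling simulated genomes: builds minimal
#' chromosome calls (no segmental events possible for whole-chromosome
#' truth) and applies the same classification rules as the inference path.
#'
#' @param copies Integer vector of per-chromosome copy numbers (named or in
#'   chromosome order).
#' @return A `ploidy_class`.
#' @export
ploidy_class_from_copies <- function(copies) {
  n <- length(copies)
  calls <- data.frame(sample_id = "truth", chromosome = seq_len(n),
                      copy_number = as.integer(copies), discordant = FALSE,
                      n_loci = 1L, stringsAsFactors = FALSE)
  calls$locus_totals <- I(lapply(copies, function(x) stats::setNames(as.integer(x), "chr")))
  calls$locus_ambiguous <- I(lapply(copies, function(x) stats::setNames(FALSE, "chr")))
  classify_ploidy(calls, NULL, quorum = min(15L, n))
}
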