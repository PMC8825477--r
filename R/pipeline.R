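#' Build a validated pipeline run configuration
#'
#' @param peaks,parents,panel Paths to the peak table, parental genotype
#'   table and marker panel.
#' @param out_dir Output directory (created if absent).
#' @param candidate_totals,tie_tolerance,min_prop,bin_tolerance Dosage
#'   options (see [call_dosages()]).
#' @param signal Peak signal column policy (see [read_peak_table()]).
#' @param quorum Classification quorum (see [classify_ploidy()]).
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when the caller also simulates).
#' @return A `run_config` list.
#' @export
run_config <- function(peaks, parents, panel, out_dir,
                       candidate_totals = 2:6, tie_tolerance = 0.01,
                       min_prop = 0.02, bin_tolerance = 0.5,
                       signal = "auto", quorum = 15L, seed = 1L) {
  cfg <- list(peaks = peaks, parents = parents, panel = panel,
              out_dir = out_dir, candidate_totals = candidate_totals,
              tie_tolerance = tie_tolerance, min_prop = min_prop,
              bin_tolerance = bin_tolerance, signal = signal,
              quorum = as.integer(quorum), seed = as.integer(seed))
  for (f in c("peaks", "parents", "panel"))
    if (!file.exists(cfg[[f]]))
      stop("config: ", f, " path does not exist: ", cfg[[f]], call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full molecular-karyotyping pipeline
#'
#' Orchestrates dosage calling, karyotyping and heterozygosity analysis, and
#' writes the report bundle into `config$out_dir`:
#' \describe{
#'   \item{genotypes.csv}{wide allelic-configuration table}
#'   \item{karyotype_report.json}{per-sample chromosome calls, SV events and
#'     ploidy class}
#'   \item{karyotype_report.csv}{per-sample per-chromosome copy numbers}
#'   \item{table1_analog.csv}{per-locus and per-chromosome Ho}
#'   \item{fig3_analog.csv}{per-chromosome dosage frequencies and SV tally
#'     (percentages to one decimal)}
#'   \item{class_counts.csv}{ploidy-class counts}
#'   \item{transmission_by_group.csv}{paternal heterozygosity transmission
#'     per ploidy group (pooled and sample-averaged)}
#'   \item{run_log.txt}{package version, seed, parameter values}
#' }
#' A stage failure aborts the run with the stage named and removes the
#' partial outputs written by this run.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return Invisibly, a list with the in-memory results (`configs`,
#'   `reports`, `summary`, `het`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character(0)
  emit <- function(fname, writer) {
    path <- file.path(out, fname)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "input"
  res <- tryCatch({
    panel <- read_marker_panel(config$panel)
    parents <- read_parental_genotypes(config$parents)
    ploidies <- vapply(parents, `[[`, integer(1), "ploidy")
    if (!all(c(2L, 3L) %in% ploidies))
      stop("parents table must hold one diploid and one triploid parent")
    mother <- parents[[which(ploidies == 2L)[1L]]]
    father <- parents[[which(ploidies == 3L)[1L]]]
    peaks <- read_peak_table(config$peaks, signal = config$signal)

    stage <- "dosage"
    configs <- call_dosages(peaks, panel, mother, father,
                            candidate_totals = config$candidate_totals,
                            bin_tolerance = config$bin_tolerance,
                            tie_tolerance = config$tie_tolerance,
                            min_prop = config$min_prop)
    emit("genotypes.csv", function(p) write_genotype_table(configs, p))

    stage <- "karyotype"
    reports <- karyotype_population(configs, panel, quorum = config$quorum)
    summary <- summarize_population(reports)
    emit("karyotype_report.json", function(p) write_karyotype_json(reports, p))
    emit("karyotype_report.csv", function(p) {
      wide <- do.call(rbind, lapply(reports, function(r) {
        row <- data.frame(sample_id = r$sample_id,
                          ploidy_class = r$ploidy$label,
                          chromosome_total = r$chromosome_total,
                          n_sv_events = nrow(r$sv_events),
                          stringsAsFactors = FALSE)
        cp <- stats::setNames(as.list(r$calls$copy_number),
                              paste0("chr", r$calls$chromosome))
        cbind(row, as.data.frame(cp))
      }))
      utils::write.csv(wide, p, row.names = FALSE, quote = FALSE)
    })
    emit("class_counts.csv", function(p)
      utils::write.csv(summary$class_counts, p, row.names = FALSE, quote = FALSE))
    emit("fig3_analog.csv", function(p) {
      freq <- summary$dosage_freq
      freq$freq <- round(freq$freq, 3)
      sv <- summary$sv_summary
      utils::write.csv(freq, p, row.names = FALSE, quote = FALSE)
      # SV tally appended as a second block with its own header
      cat("\n", file = p, append = TRUE)
      suppressWarnings(utils::write.table(sv, p, append = TRUE, sep = ",",
                                          row.names = FALSE, quote = FALSE))
    })

    stage <- "heterozygosity"
    classes <- vapply(reports, function(r) r$ploidy$label, character(1))
    het <- heterozygosity_summary(configs, panel, mother, father,
                                  classes = classes)
    emit("table1_analog.csv", function(p) {
      chr_of <- panel$chromosome[match(names(het$ho_by_locus), panel$name)]
      loci <- data.frame(chromosome = chr_of, locus = names(het$ho_by_locus),
                         ho_locus = round(het$ho_by_locus, 3),
                         ho_chromosome = het$ho_by_chromosome[as.character(chr_of)],
                         stringsAsFactors = FALSE)
      loci <- loci[order(loci$chromosome, loci$locus), ]
      utils::write.csv(loci, p, row.names = FALSE, quote = FALSE)
    })
    emit("transmission_by_group.csv", function(p) {
      groups <- names(het$paternal_transmission_by_group)
      utils::write.csv(data.frame(
        group = c(groups, "overall"),
        transmission_pooled = round(c(het$paternal_transmission_by_group,
                                      het$overall_paternal_transmission), 3),
        transmission_sample_mean = round(c(
          het$paternal_transmission_by_group_sample_mean[groups],
          mean(het$paternal_transmission_by_group_sample_mean)), 3),
        ho = round(c(het$ho_by_group[groups], het$overall_ho), 3),
        stringsAsFactors = FALSE), p, row.names = FALSE, quote = FALSE)
    })

    emit("run_log.txt", function(p) {
      writeLines(c(
        paste0("macploidy ", as.character(utils::packageVersion("macploidy"))),
        paste0("R ", R.version$major, ".", R.version$minor),
        paste0("seed: ", config$seed),
        paste0("candidate_totals: ",
               paste(config$candidate_totals, collapse = ",")),
        paste0("tie_tolerance: ", config$tie_tolerance),
        paste0("min_prop: ", config$min_prop),
        paste0("bin_tolerance: ", config$bin_tolerance),
        paste0("quorum: ", config$quorum),
        paste0("inputs: ", config$peaks, " ", config$parents, " ",
               config$panel)), p)
    })
    list(configs = configs, reports = reports, summary = summary, het = het)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Write karyotype reports as JSON
#'
#' @param reports List of `karyotype_report` objects.
#' @param path Output path.
#' @export
write_karyotype_json <- function(reports, path) {
  payload <- lapply(unname(reports), function(r) {
    list(sample_id = r$sample_id,
         ploidy_class = r$ploidy$label,
         baseline = r$ploidy$baseline,
         chromosome_total = r$chromosome_total,
         chromosomes = lapply(seq_len(nrow(r$calls)), function(i) {
           list(chromosome = r$calls$chromosome[i],
                copy_number = r$calls$copy_number[i],
                discordant = r$calls$discordant[i],
                locus_totals = as.list(r$calls$locus_totals[[i]]))
         }),
         sv_events = if (nrow(r$sv_events) == 0L) list() else
           lapply(seq_len(nrow(r$sv_events)), function(i)
             as.list(r$sv_events[i, ])))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Published per-locus observed heterozygosity reference table
#'
#' The locus-level Ho values reported for the 47-marker panel of a diploid x
#' triploid *Populus* cross progeny, shipped as reference data: feeding these
#' through [chromosome_heterozygosity()] reproduces the published
#' per-chromosome means, and their unweighted grand mean the whole-progeny
#' Ho.
#'
#' @return Data frame with columns `chromosome`, `locus`, `ho`.
#' @export
populus_reference_ho <- function() {
  path <- system.file("extdata", "populus_cross_locus_ho.csv",
                      package = "macploidy")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
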