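#' Read an SSR marker panel
#'
#' A marker panel maps each microsatellite (SSR) marker to its chromosome
#' (1-19 for *Populus*), expected fragment-size window, fluorescent dye, and
#' ordering of the locus along the chromosome (`position_rank`, used to merge
#' adjacent discordant loci into a single structural-variant event).
#'
#' @param path Path to a delimited text file with header columns `name`,
#'   `chromosome`, `size_min`, `size_max`, `dye`, `position_rank`.
#' @param format Field delimiter dialect: `"comma"` (default) or `"tab"`.
#' @return A `marker_panel`: a validated data frame with one row per marker.
#' @export
read_marker_panel <- function(path, format = c("comma", "tab")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("marker panel file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = if (format == "comma") "," else "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_marker_panel(df)
}

#' Validate a data frame as a marker panel
#'
#' @param df Data frame with columns `name`, `chromosome`, `size_min`,
#'   `size_max`, `dye`, `position_rank`.
#' @return The validated `marker_panel`.
#' @export
as_marker_panel <- function(df) {
  required <- c("name", "chromosome", "size_min", "size_max", "dye", "position_rank")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("marker panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[required]
  if (nrow(df) > 0L) {
    df$chromosome <- as.integer(df$chromosome)
    df$position_rank <- as.integer(df$position_rank)
    bad_chr <- which(is.na(df$chromosome) | df$chromosome < 1L | df$chromosome > 19L)
    if (length(bad_chr) > 0L)
      stop("chromosome outside 1-19 at row(s): ", paste(bad_chr, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(df$name))
      stop("duplicate marker name(s): ",
           paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
           call. = FALSE)
    if (any(df$size_min >= df$size_max))
      stop("size_min must be < size_max for every marker", call. = FALSE)
    dup_rank <- vapply(split(df$position_rank, df$chromosome),
                       anyDuplicated, integer(1))
    if (any(dup_rank > 0L))
      stop("position_rank not unique within chromosome(s): ",
           paste(names(dup_rank)[dup_rank > 0L], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Write a marker panel to CSV
#' @param panel A `marker_panel`.
#' @param path Output file path.
#' @export
write_marker_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capillary-electrophoresis peak table
#'
#' Reads a GeneMarker-style fragment-analysis export: one row per called peak
#' with the sample, marker, fragment size in bp (fractional) and fluorescence
#' signal. Peak `signal` is taken from the `area` column when present, else
#' from `height` (MAC-PR was originally described on peak areas; exports often
#' carry only heights), overridable via `signal`.
#'
#' Rows whose size or signal does not parse are reported and skipped; rows
#' with non-positive signal are dropped with a message. If no row survives,
#' that is an error.
#'
#' @param path Path to the peak table.
#' @param dialect `"comma"` or `"tab"` field separator.
#' @param signal Which column feeds the peak signal: `"auto"` (area when
#'   available, else height), `"area"`, or `"height"`.
#' @return Data frame with columns `sample_id`, `marker`, `size`, `signal`
#'   (plus the raw `height`/`area` columns that were present).
#' @export
read_peak_table <- function(path, dialect = c("comma", "tab"),
                            signal = c("auto", "area", "height")) {
  dialect <- match.arg(dialect)
  signal <- match.arg(signal)
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = if (dialect == "comma") "," else "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("sample_id", "marker", "size", "height")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$size <- suppressWarnings(as.numeric(df$size))
  df$height <- suppressWarnings(as.numeric(df$height))
  if ("area" %in% names(df))
    df$area <- suppressWarnings(as.numeric(df$area))
  sig_col <- switch(signal,
                    auto = if ("area" %in% names(df)) "area" else "height",
                    area = {
                      if (!"area" %in% names(df))
                        stop("signal = \"area\" requested but no area column",
                             call. = FALSE)
                      "area"
                    },
                    height = "height")
  bad <- which(is.na(df$size) | is.na(df[[sig_col]]))
  if (length(bad) > 0L) {
    message(length(bad), " row(s) with unparseable size/", sig_col, " skipped ",
            "(rows ", paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "", ")")
    df <- df[-bad, , drop = FALSE]
  }
  nonpos <- which(df[[sig_col]] <= 0 | df$size <= 0)
  if (length(nonpos) > 0L) {
    message(length(nonpos), " row(s) with non-positive size/signal dropped")
    df <- df[-nonpos, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop("no usable rows in peak table ", path, call. = FALSE)
  df$signal <- df[[sig_col]]
  rownames(df) <- NULL
  df
}

#' Write a peak table to CSV
#' @param peaks Data frame with at least `sample_id`, `marker`, `size`, `height`.
#' @param path Output file path.
#' @export
write_peak_table <- function(peaks, path) {
  cols <- intersect(c("sample_id", "marker", "size", "height", "area"),
                    names(peaks))
  utils::write.csv(peaks[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read parental genotypes with known allele dosages
#'
#' Long-format table with columns `parent_id`, `ploidy`, `marker`,
#' `allele_size`, `dosage`; per parent and locus the dosages must sum to the
#' declared ploidy (2 for the diploid mother, 3 for the triploid father).
#'
#' @param path Path to the parents table (CSV).
#' @return Named list of `parental_genotype` objects, one per `parent_id`.
#' @export
read_parental_genotypes <- function(path) {
  if (!file.exists(path)) stop("parents file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("parent_id", "ploidy", "marker", "allele_size", "dosage")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("parents table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$parent_id), function(d) {
    alleles <- lapply(split(d, d$marker), function(m) {
      v <- as.integer(m$dosage)
      names(v) <- as.character(m$allele_size)
      v
    })
    parental_genotype(d$parent_id[1L], as.integer(d$ploidy[1L]), alleles)
  })
  out
}

#' Construct a parental genotype
#'
#' @param parent_id Identifier.
#' @param ploidy Integer ploidy (2 or 3 for the cross modelled here).
#' @param alleles_by_locus Named list (by marker) of named integer vectors:
#'   allele size (bp, as name) -> dosage. Dosages must sum to `ploidy` at
#'   every locus.
#' @param haplotypes Optional phased homologs for the meiosis simulator: a
#'   list keyed by chromosome, each a loci x ploidy matrix of allele sizes
#'   with markers as row names.
#' @return A `parental_genotype` object.
#' @export
parental_genotype <- function(parent_id, ploidy, alleles_by_locus,
                              haplotypes = NULL) {
  sums <- vapply(alleles_by_locus, sum, numeric(1))
  bad <- names(alleles_by_locus)[sums != ploidy]
  if (length(bad) > 0L)
    stop("dosages do not sum to ploidy ", ploidy, " for ", parent_id,
         " at locus/loci: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  structure(list(parent_id = parent_id, ploidy = as.integer(ploidy),
                 alleles_by_locus = alleles_by_locus, haplotypes = haplotypes),
            class = "parental_genotype")
}

#' Write parental genotypes to CSV (long format)
#' @param parents List of `parental_genotype` objects.
#' @param path Output file path.
#' @export
write_parental_genotypes <- function(parents, path) {
  rows <- do.call(rbind, lapply(parents, function(p) {
    do.call(rbind, lapply(names(p$alleles_by_locus), function(m) {
      v <- p$alleles_by_locus[[m]]
      data.frame(parent_id = p$parent_id, ploidy = p$ploidy, marker = m,
                 allele_size = as.numeric(names(v)), dosage = as.integer(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write allelic configurations as a wide genotype table
#'
#' One row per sample, one column per marker; each cell holds the allelic
#' configuration as `"size:dosage,size:dosage,..."` with alleles in ascending
#' size order. Rows are ordered by sample, columns by marker name.
#'
#' @param configs A genotype-call table as returned by [call_dosages()]: long
#'   data frame with columns `sample_id`, `marker`, `allele`, `dosage`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genotype_table <- function(configs, path) {
  if (nrow(configs) == 0L) {
    writeLines("sample_id", path)
    return(invisible(path))
  }
  key <- paste(configs$sample_id, configs$marker, sep = "\r")
  if (anyDuplicated(paste(key, configs$allele)))
    stop("conflicting configurations for the same sample x locus", call. = FALSE)
  samples <- sort(unique(configs$sample_id))
  markers <- sort(unique(configs$marker))
  cells <- tapply(seq_len(nrow(configs)), key, function(i) {
    d <- configs[i, ]
    d <- d[order(d$allele), ]
    paste(sprintf("%s:%d", format(d$allele, trim = TRUE), d$dosage),
          collapse = ",")
  })
  wide <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (m in markers)
    wide[[m]] <- unname(cells[paste(samples, m, sep = "\r")])
  wide[is.na(wide)] <- ""
  # configuration cells contain commas, so fields must be quoted
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide genotype table back into long configuration form
#'
#' Inverse of [write_genotype_table()].
#'
#' @param path Path to the genotype table CSV.
#' @return Long data frame with columns `sample_id`, `marker`, `allele`,
#'   `dosage`, `total_copies`.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype table not found: ", path, call. = FALSE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  markers <- setdiff(names(wide), "sample_id")
  rows <- list()
  for (i in seq_len(nrow(wide))) {
    for (m in markers) {
      cell <- wide[[m]][i]
      if (is.na(cell) || !nzchar(cell)) next
      parts <- strsplit(strsplit(cell, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
      allele <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
      dosage <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = wide$sample_id[i], marker = m, allele = allele,
        dosage = dosage, total_copies = sum(dosage), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(), marker = character(),
                      allele = numeric(), dosage = integer(),
                      total_copies = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
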