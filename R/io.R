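# Tetrad table file format (tab-separated, versioned header comment) and
# the bundled dissection-count data.

FORMAT_LINE <- "# tetradkit tetrad table v1"

#' Read a tetrad table from a TSV file
#'
#' The format is tab-separated with `#` comment/provenance lines on top
#' (the first must be the version line), then a header row
#' `strain tetrad_id spore viable mating <marker...>`. Alleles are coded
#' `P`/`Q`/`-`; concrete allele names belong in the marker-map
#' configuration, not in the table.
#'
#' @param path File path.
#' @param map Optional [marker_map()]; when given, the table is validated
#'   against it (marker columns present, 4 spores per tetrad, legal codes).
#' @return A tetrad table tibble.
#' @export
read_tetrad_table <- function(path, map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (!identical(first, FORMAT_LINE)) {
    stop("not a tetradkit tetrad table (missing version header): ", path)
  }
  df <- utils::read.delim(path,
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  need <- c("strain", "tetrad_id", "spore", "viable", "mating")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("tetrad table lacks columns: ", paste(miss, collapse = ", "))
  df$spore <- as.integer(df$spore)
  if (!all(df$viable %in% c("0", "1"))) stop("viable must be 0/1")
  df$viable <- df$viable == "1"
  out <- tibble::as_tibble(df)
  if (!is.null(map)) out <- validate_tetrads(out, map)
  out
}

#' Write a tetrad table to a TSV file
#'
#' Emits the versioned header; when the table carries a simulation
#' configuration (attribute `"sim_config"`), the seed and rates are echoed
#' as provenance comments so the table is reproducible.
#'
#' @param tetrads A tetrad table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tetrad_table <- function(tetrads, path) {
  lines <- FORMAT_LINE
  cfg <- attr(tetrads, "sim_config")
  if (!is.null(cfg)) {
    lines <- c(lines, sprintf(
      "# simulated: n=%d seed=%d m=%d gc=%g mi_ndj=%s mii_pssc=%s death=%g",
      cfg$n, cfg$seed, cfg$m, cfg$gc_prob,
      paste(cfg$mi_ndj, collapse = ","), paste(cfg$mii_pssc, collapse = ","),
      cfg$death
    ))
  }
  out <- tetrads
  out$viable <- as.integer(out$viable)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(out, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Bundled tetrad dissection counts
#'
#' Count tables from dissections of wild-type, htz1, hho1 and htz1 hho1
#' S. cerevisiae diploids heterozygous for 9 markers on chromosomes III and
#' VIII: per-interval PD/TT/NPD tallies, spore-viability class counts with
#' chromosome III MI-nondisjunction events, and gene-conversion tallies.
#' Columns suffixed `_printed` hold the values published alongside the
#' counts (at their original precision) and are used by the reproduction
#' checks; everything else is recomputed from the raw counts.
#'
#' @param which One of `"intervals"`, `"viability"`,
#'   `"gene_conversion"`.
#' @return A tibble.
#' @export
tetrad_count_data <- function(which = c("intervals", "viability", "gene_conversion")) {
  which <- match.arg(which)
  f <- switch(which,
    intervals = "interval_counts.tsv",
    viability = "viability_counts.tsv",
    gene_conversion = "gene_conversion_counts.tsv"
  )
  path <- system.file("extdata", f, package = "tetradkit", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}
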