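# Report rendering: the three standard tables (viability/NDJ, map
# distances, gene conversion) at conventional precision, plus
# full-precision machine-readable companions. All rounding happens here;
# upstream math is full precision.

# deterministic round-half-up for presentation (base round() is
# round-half-even, which would be surprising in printed tables)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "n.d.", formatC(round_half_up(x, digits),
    format = "f", digits = digits
  ))
}

#' Map-distance report at table precision
#'
#' Formats the output of [map_distance_report()] the way tetrad map tables
#' are conventionally printed: cM and SE at 1 decimal ("28.4 (1.6)"),
#' interference ratio and SE at 2 decimals, percent columns as integers,
#' "n.d." where no NPD tetrads were observed. Chromosome totals are the
#' sums of the 1-decimal interval distances.
#'
#' @param counts Output of [tabulate_interval_counts()] or the bundled
#'   interval counts.
#' @param map A [marker_map()].
#' @param reference Reference strain for percent columns (default
#'   the first strain).
#' @return Tibble of formatted character/integer columns, one row per
#'   strain and interval.
#' @export
report_map_distances <- function(counts, map, reference = counts$strain[1]) {
  full <- map_distance_report(counts, map, reference = reference)
  tibble::tibble(
    strain = full$strain,
    interval = full$interval,
    chrom = full$chrom,
    PD = full$PD, TT = full$TT, NPD = full$NPD, n = full$n,
    cM_se = paste0(fmt_num(full$cM, 1), " (", fmt_num(full$se_cM, 1), ")"),
    pct_ref = as.integer(round_half_up(full$pct_ref)),
    cM_chrom = fmt_num(full$cM_chrom, 1),
    pct_ref_chrom = as.integer(round_half_up(full$pct_ref_chrom)),
    interference = ifelse(is.na(full$ratio), "n.d.",
      paste0(fmt_num(full$ratio, 2), " (", fmt_num(full$se_ratio, 2), ")")
    )
  )
}

#' Viability and nondisjunction report at table precision
#'
#' @param viab Tibble from [viability_table()] or [viability_from_counts()]
#'   with a `strain` column and class counts.
#' @param ndj Optional tibble from [infer_mi_ndj()] (joined by strain).
#' @return Formatted tibble: viability to whole percent, NDJ to 2 decimals,
#'   "n.d." where nondisjunction could not be scored.
#' @export
report_viability <- function(viab, ndj = NULL) {
  out <- tibble::tibble(
    strain = viab$strain,
    n_tetrads = viab$n_tetrads,
    pct_viability = as.integer(round_half_up(viab$pct_viability)),
    n4 = viab$n4, n3 = viab$n3, n2 = viab$n2, n1 = viab$n1, n0 = viab$n0
  )
  if (!is.null(ndj)) {
    ndj_fmt <- tibble::tibble(
      strain = ndj$strain,
      ndj_pct = ifelse(ndj$n_examined > 0 & ndj$ndj_events > 0,
        fmt_num(ndj$ndj_pct, 2), "n.d."
      ),
      ndj_fraction = ifelse(ndj$n_examined > 0,
        paste0(ndj$ndj_events, "/", ndj$n_examined), "n.d."
      )
    )
    out <- dplyr::left_join(out, ndj_fmt, by = "strain")
  }
  out
}

#' Gene-conversion report at table precision
#'
#' @param gc_summary Output of [summarize_gene_conversions()].
#' @return Formatted tibble: percentages as integers, per-tetrad rates at
#'   2 decimals, ratio versus the reference at 1 decimal, p-values at
#'   conventional precision.
#' @export
report_gene_conversion <- function(gc_summary) {
  chrom_pct <- do.call(rbind, lapply(gc_summary$pct_gc_by_chrom, function(p) {
    setNames(as.integer(round_half_up(p)), names(p))
  }))
  colnames(chrom_pct) <- paste0("pct_gc_", colnames(chrom_pct))
  out <- tibble::tibble(
    strain = gc_summary$strain,
    n_tetrads = gc_summary$n_tetrads,
    n_with_gc = gc_summary$n_with_gc,
    pct_with_gc = as.integer(round_half_up(gc_summary$pct_with_gc)),
    total_gc = gc_summary$total_gc,
    gc_per_tetrad = fmt_num(gc_summary$gc_per_tetrad, 2),
    vs_ref = fmt_num(gc_summary$gc_per_tetrad_vs_ref, 1),
    p_two_prop = signif(gc_summary$p_two_prop, 2),
    p_gc_rate = signif(gc_summary$p_gc_rate, 2),
    p_fisher = signif(gc_summary$p_fisher, 4)
  )
  dplyr::bind_cols(out, tibble::as_tibble(chrom_pct))
}

#' Run the full analysis pipeline on a tetrad table
#'
#' Viability and NDJ summaries use all tetrads; gene-conversion summaries
#' use the 4-spore-viable subset; interval counts and map distances use
#' tetrads passing [filter_for_mapping()]. Filter tallies are attached so
#' every excluded tetrad is accounted for.
#'
#' @inheritParams validate_tetrads
#' @param reference Reference strain for percent/ratio columns (default
#'   first strain in the table).
#' @param max_gc Gene-conversion cap for the mapping filter (default 2).
#' @return List with elements `viability`, `ndj`, `gc_summary`,
#'   `interval_counts`, `map_full` (full precision), `reports` (the three
#'   formatted tables) and `filter_counts`.
#' @export
analyze_tetrads <- function(tetrads, map, reference = NULL, max_gc = 2) {
  tetrads <- validate_tetrads(tetrads, map)
  if (is.null(reference)) reference <- tetrads$strain[1]
  viab <- viability_table(tetrads)
  ndj <- infer_mi_ndj(tetrads)
  vb <- classify_viability(tetrads)
  four <- tetrads[rep(vb$n_viable == 4L, each = 4L), , drop = FALSE]
  gc_summary <- if (nrow(four) > 0) {
    summarize_gene_conversions(four, map, reference = reference)
  } else {
    NULL
  }
  mapped <- filter_for_mapping(tetrads, map, max_gc = max_gc)
  counts <- tabulate_interval_counts(mapped, map)
  map_full <- if (nrow(counts) > 0) {
    map_distance_report(counts, map, reference = reference)
  } else {
    NULL
  }
  list(
    viability = viab,
    ndj = ndj,
    gc_summary = gc_summary,
    interval_counts = counts,
    map_full = map_full,
    reports = list(
      viability = report_viability(viab, ndj),
      map_distances = if (nrow(counts) > 0) {
        report_map_distances(counts, map, reference = reference)
      } else {
        NULL
      },
      gene_conversion = if (!is.null(gc_summary)) {
        report_gene_conversion(gc_summary)
      } else {
        NULL
      }
    ),
    filter_counts = attr(mapped, "filter_counts")
  )
}

#' Write analysis reports to a directory
#'
#' Writes the three formatted tables plus full-precision machine-readable
#' companions as tab-separated files.
#'
#' @param results Output of [analyze_tetrads()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) {
      return()
    }
    df <- as.data.frame(df)
    # flatten list-columns for serialisation
    for (cl in names(df)) {
      if (is.list(df[[cl]])) {
        df[[cl]] <- vapply(df[[cl]], function(x) {
          paste(names(x), round_half_up(unlist(x), 2), sep = "=", collapse = ";")
        }, character(1))
      }
    }
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "n.d.")
    written <<- c(written, p)
  }
  wr(results$reports$viability, "viability_report.tsv")
  wr(results$reports$map_distances, "map_distance_report.tsv")
  wr(results$reports$gene_conversion, "gene_conversion_report.tsv")
  wr(results$interval_counts, "interval_counts_full.tsv")
  wr(results$map_full, "map_distances_full.tsv")
  wr(results$gc_summary, "gene_conversion_full.tsv")
  invisible(written)
}
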