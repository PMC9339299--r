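# Closed-form tetrad genetics. All functions are vectorised over counts and
# do their arithmetic at full precision; rounding is the report layer's job.

#' Perkins map distance from tetrad counts
#'
#' The tetrad-based map distance estimator
#' \deqn{cM = 100 (TT/2 + 3\,NPD) / N, \quad N = PD + TT + NPD,}
#' which corrects for double crossovers through the NPD term. The standard
#' error comes from the multinomial delta method: with \eqn{t = TT/N} and
#' \eqn{d = NPD/N},
#' \deqn{se = 100 \sqrt{\left[t(1-t)/4 + 9d(1-d) - 3td\right] / N}.}
#'
#' @param PD,TT,NPD Non-negative tetrad counts (vectorised).
#' @return Tibble with columns `n`, `cM`, `se_cM`, `f_T` (tetratype
#'   frequency).
#' @examples
#' perkins_distance(230, 251, 4) # 28.4 (1.6) at reporting precision
#' @export
perkins_distance <- function(PD, TT, NPD) {
  n <- PD + TT + NPD
  if (any(n <= 0)) stop("empty interval: PD + TT + NPD must be > 0")
  t <- TT / n
  d <- NPD / n
  cM <- 100 * (TT / 2 + 3 * NPD) / n
  se <- 100 * sqrt((t * (1 - t) / 4 + 9 * d * (1 - d) - 3 * t * d) / n)
  tibble::tibble(n = n, cM = cM, se_cM = se, f_T = t)
}

# real cube root (sign-preserving), so x^(2/3) is defined for all real x
.real_cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Expected NPD count in the absence of chiasma interference
#'
#' Papazian's relation gives the nonparental-ditype frequency expected from
#' the observed tetratype frequency \eqn{f_T = TT/N} if crossovers occur
#' without interference:
#' \deqn{E[NPD] = N \cdot \tfrac12\left[1 - f_T - (1 - 3 f_T/2)^{2/3}\right].}
#' For \eqn{f_T > 2/3} the bracket's power term is evaluated with the real
#' cube root, \eqn{(x)^{2/3} = (x^2)^{1/3}}, which keeps the expectation
#' defined and continuous over the whole admissible range of \eqn{f_T}.
#'
#' @inheritParams perkins_distance
#' @return Numeric vector of expected NPD counts.
#' @examples
#' papazian_expected_npd(230, 251, 4) # about 27.6
#' @export
papazian_expected_npd <- function(PD, TT, NPD) {
  n <- PD + TT + NPD
  if (any(n <= 0)) stop("empty interval: PD + TT + NPD must be > 0")
  fT <- TT / n
  n * 0.5 * (1 - fT - .real_cbrt(1 - 1.5 * fT)^2)
}

#' Crossover interference as the observed/expected NPD ratio
#'
#' The ratio NPDobs/NPDexp, with NPDexp from [papazian_expected_npd()].
#' A ratio below 1 indicates positive interference (double crossovers are
#' rarer than independence predicts). The standard error treats the observed
#' NPD count as Poisson: \eqn{se = ratio/\sqrt{NPD}}. When no NPD tetrads
#' were observed (or the expectation is not positive) the ratio is not
#' determined and both fields are `NA` ("n.d." in reports).
#'
#' @inheritParams perkins_distance
#' @return Tibble with columns `npd_expected`, `ratio`, `se_ratio`.
#' @examples
#' interference_ratio(230, 251, 4) # ratio 0.14, se 0.07
#' interference_ratio(180, 129, 0) # n.d.
#' @export
interference_ratio <- function(PD, TT, NPD) {
  e <- papazian_expected_npd(PD, TT, NPD)
  ratio <- ifelse(NPD > 0 & e > 0, NPD / e, NA_real_)
  se <- ifelse(is.na(ratio), NA_real_, ratio / sqrt(NPD))
  tibble::tibble(npd_expected = e, ratio = ratio, se_ratio = se)
}

#' Cumulative chromosome map length
#'
#' Sums interval distances per chromosome. Mirroring how multi-interval
#' totals are usually tabulated alongside 1-decimal interval values, each
#' interval distance is rounded to `digits` decimals before summing
#' (set `digits = Inf` to sum at full precision).
#'
#' @param estimates Tibble with columns `chrom`, `interval`, `cM` (one row
#'   per interval of each chromosome, e.g. from [perkins_distance()] bound
#'   to interval metadata).
#' @param map A [marker_map()]; every interval of every chromosome must be
#'   present.
#' @param digits Decimals to which interval distances are rounded before
#'   summing (default 1).
#' @return Tibble with `chrom` and `cM_total`.
#' @export
chromosome_cumulative <- function(estimates, map, digits = 1) {
  miss <- setdiff(map$intervals$interval, estimates$interval)
  if (length(miss) > 0) {
    stop("missing interval estimate(s): ", paste(miss, collapse = ", "))
  }
  x <- estimates
  if (is.finite(digits)) x$cM <- round(x$cM, digits)
  dplyr::summarise(dplyr::group_by(x, .data$chrom),
    cM_total = sum(.data$cM), .groups = "drop"
  )
}

#' Percent of a reference value
#'
#' @param value,reference_value Numeric; `reference_value` must be positive.
#' @return `100 * value / reference_value` (full precision; reports round to
#'   integers).
#' @examples
#' percent_of_reference(34.8, 28.4) # ~123
#' @export
percent_of_reference <- function(value, reference_value) {
  if (any(reference_value <= 0)) stop("reference value must be > 0")
  100 * value / reference_value
}

#' Full per-interval map report from tallied counts
#'
#' Combines [perkins_distance()], [interference_ratio()] and
#' [chromosome_cumulative()] into one tidy table, with percent-of-reference
#' columns computed against a designated reference strain.
#'
#' @param counts Output of [tabulate_interval_counts()] (or any tibble with
#'   strain, interval, chrom, PD, TT, NPD).
#' @param map A [marker_map()].
#' @param reference Strain name used for the percent columns, or `NULL` to
#'   omit them.
#' @return Tibble with one row per strain and interval carrying n, cM,
#'   se_cM, npd_expected, ratio, se_ratio, pct_ref, cM_chrom,
#'   pct_ref_chrom (full precision; see [report_map_distances()] for the
#'   rounded presentation).
#' @export
map_distance_report <- function(counts, map, reference = NULL) {
  est <- dplyr::bind_cols(
    counts[, c("strain", "interval", "chrom", "PD", "TT", "NPD")],
    perkins_distance(counts$PD, counts$TT, counts$NPD),
    interference_ratio(counts$PD, counts$TT, counts$NPD)[, c("npd_expected", "ratio", "se_ratio")]
  )
  cum <- dplyr::bind_rows(lapply(split(est, est$strain), function(e) {
    cc <- chromosome_cumulative(e, map)
    cc$strain <- e$strain[1]
    cc
  }))
  est <- dplyr::left_join(est, cum, by = c("strain", "chrom"))
  names(est)[names(est) == "cM_total"] <- "cM_chrom"
  if (!is.null(reference)) {
    if (!reference %in% est$strain) stop("reference strain '", reference, "' absent")
    ref <- est[est$strain == reference, c("interval", "cM", "cM_chrom")]
    names(ref) <- c("interval", "cM_ref", "cM_chrom_ref")
    est <- dplyr::left_join(est, ref, by = "interval")
    est$pct_ref <- percent_of_reference(est$cM, est$cM_ref)
    est$pct_ref_chrom <- percent_of_reference(est$cM_chrom, est$cM_chrom_ref)
    est$cM_ref <- NULL
    est$cM_chrom_ref <- NULL
  }
  est
}
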