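# The hypothesis tests applied to tetrad summaries. Generic machinery
# (Fisher's exact test, Student's t, exact binomial) is delegated to stats;
# the pooled-SE Z test and the adjacency-by-chance null are implemented here.

#' Two-proportion Z-test (pooled standard error)
#'
#' Tests H0: p1 = p2 using the pooled-proportion Z statistic
#' \deqn{z = (x_1/n_1 - x_2/n_2) / \sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}, and a two-sided normal p-value.
#' The squared statistic equals Pearson's chi-square without continuity
#' correction on the corresponding 2x2 table.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z` and `p`.
#' @examples
#' two_proportion_z(64, 530, 42, 497) # p ~ 0.056
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    warning("degenerate pooled proportion (all successes or all failures); p = 1")
    return(list(z = 0, p = 1))
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass convention: the sum of
#' hypergeometric probabilities (margins fixed) of all tables at most as
#' probable as the observed one. This is `stats::fisher.test()`'s
#' convention; the wrapper adds the zero-margin guard used by the reports.
#'
#' @param tab A 2x2 matrix of non-negative counts (rows = strains,
#'   columns = event / non-event).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(34, 280, 42, 455), 2, byrow = TRUE)) # 0.2675
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: Fisher's exact test undefined; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Student's t-test with explicit tail convention
#'
#' Thin wrapper over [stats::t.test()] exposing the 1-tail/2-tail and
#' paired/unpaired variants used for viability and cumulative-distance
#' comparisons. One-tailed tests take the alternative that `x` has the
#' larger mean (pass the groups accordingly).
#'
#' @param x,y Numeric vectors of observations (pairs when `paired`).
#' @param tails 1 or 2.
#' @param paired Logical.
#' @return List with `t`, `df`, `p`.
#' @export
student_t <- function(x, y, tails = 2, paired = FALSE) {
  stopifnot(tails %in% c(1, 2))
  if (stats::var(x) == 0 && stats::var(y) == 0 && !paired) {
    stop("zero variance in both groups")
  }
  alt <- if (tails == 1) "greater" else "two.sided"
  ht <- stats::t.test(x, y, alternative = alt, paired = paired, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Null probability that two converted markers are map-adjacent
#'
#' Under the chance model, the two converted markers of a double-conversion
#' tetrad are a uniform draw from all unordered marker pairs; a pair is
#' adjacent iff the two markers are consecutive on the same chromosome
#' (cross-chromosome pairs are never adjacent). For a 9-marker map with 5+4
#' markers this is (4+3)/C(9,2) = 7/36.
#'
#' @param map A [marker_map()].
#' @return Probability in (0, 1).
#' @export
adjacency_null_prob <- function(map) {
  m <- nrow(map$markers)
  if (m < 2) stop("need at least 2 markers")
  nrow(map$intervals) / choose(m, 2)
}

#' Are double gene conversions adjacent more often than chance?
#'
#' For tetrads carrying exactly two gene conversions, compares the observed
#' number whose converted markers are map-adjacent against the uniform-pair
#' null via an exact binomial test (two-sided). An excess of adjacent pairs
#' would indicate conversion tracts spanning neighbouring markers rather
#' than independent events.
#'
#' @param converted A list, one element per double-conversion tetrad, each a
#'   character vector of exactly 2 converted marker names (e.g. the
#'   `converted` column of [count_gene_conversions()] filtered to
#'   `n_gc == 2`).
#' @param map A [marker_map()].
#' @return List with `n` (events), `observed_adjacent`, `expected_adjacent`,
#'   `p_null` (the chance probability of adjacency) and `p` (exact binomial,
#'   two-sided; 1 when there are no events).
#' @export
gc_adjacency_test <- function(converted, map) {
  bad <- vapply(converted, function(v) length(v) != 2L, logical(1))
  if (any(bad)) stop(sum(bad), " tetrad(s) do not have exactly 2 conversions")
  p0 <- adjacency_null_prob(map)
  n <- length(converted)
  if (n == 0) {
    return(list(
      n = 0L, observed_adjacent = 0L, expected_adjacent = 0,
      p_null = p0, p = 1
    ))
  }
  adj_pairs <- paste(map$intervals$left, map$intervals$right)
  is_adj <- vapply(converted, function(v) {
    idx <- match(v, map$markers$marker)
    if (anyNA(idx)) stop("unknown marker(s): ", paste(v[is.na(idx)], collapse = ", "))
    v <- v[order(idx)]
    paste(v[1], v[2]) %in% adj_pairs
  }, logical(1))
  obs <- sum(is_adj)
  list(
    n = n,
    observed_adjacent = obs,
    expected_adjacent = n * p0,
    p_null = p0,
    p = stats::binom.test(obs, n, p = p0)$p.value
  )
}

#' Gene-conversion summary per strain
#'
#' From 4-spore-viable tetrads, tabulates per strain: number of tetrads,
#' tetrads with at least one gene conversion, total conversions,
#' conversions per tetrad, the per-chromosome split of conversions, and the
#' comparisons against a reference strain (two-proportion Z-test on the
#' fraction of tetrads with a conversion, and Fisher's exact test on the
#' with/without-conversion table).
#'
#' @param tetrads A tetrad table restricted to 4-spore-viable tetrads
#'   (possibly several strains).
#' @param map A [marker_map()].
#' @param reference Strain compared against (its own p-values are `NA`).
#' @return Tibble with one row per strain: strain, n_tetrads, n_with_gc,
#'   pct_with_gc, total_gc, gc_per_tetrad, gc_per_tetrad_vs_ref,
#'   pct_gc_by_chrom (list-column of named percentages), p_two_prop
#'   (Z-test on the fraction of tetrads with a conversion), p_gc_rate
#'   (Z-test on total conversions over tetrads), p_fisher. `gc_per_tetrad_vs_ref` is the ratio of the 2-decimal-rounded
#'   per-tetrad rates, matching how such ratios are conventionally
#'   tabulated next to 2-decimal rates.
#' @export
summarize_gene_conversions <- function(tetrads, map, reference) {
  gc <- count_gene_conversions(tetrads, map)
  if (!reference %in% gc$strain) stop("reference strain '", reference, "' absent")
  chroms <- unique(map$markers$chrom)
  per_strain <- lapply(split(gc, gc$strain), function(g) {
    chrom_all <- unlist(g$converted_chrom)
    total <- sum(g$n_gc)
    pct_chrom <- if (total > 0) {
      100 * vapply(chroms, function(ch) sum(chrom_all == ch), numeric(1)) / total
    } else {
      setNames(rep(0, length(chroms)), chroms)
    }
    tibble::tibble(
      strain = g$strain[1],
      n_tetrads = nrow(g),
      n_with_gc = sum(g$n_gc > 0),
      pct_with_gc = 100 * sum(g$n_gc > 0) / nrow(g),
      total_gc = total,
      gc_per_tetrad = total / nrow(g),
      pct_gc_by_chrom = list(pct_chrom)
    )
  })
  out <- dplyr::bind_rows(per_strain)
  ref <- out[out$strain == reference, ]
  out$gc_per_tetrad_vs_ref <- round(out$gc_per_tetrad, 2) / round(ref$gc_per_tetrad, 2)
  out$p_two_prop <- vapply(seq_len(nrow(out)), function(i) {
    if (out$strain[i] == reference) {
      return(NA_real_)
    }
    two_proportion_z(out$n_with_gc[i], out$n_tetrads[i], ref$n_with_gc, ref$n_tetrads)$p
  }, numeric(1))
  out$p_gc_rate <- vapply(seq_len(nrow(out)), function(i) {
    if (out$strain[i] == reference) {
      return(NA_real_)
    }
    # per-tetrad conversion rate compared as a proportion of tetrads
    two_proportion_z(out$total_gc[i], out$n_tetrads[i], ref$total_gc, ref$n_tetrads)$p
  }, numeric(1))
  out$p_fisher <- vapply(seq_len(nrow(out)), function(i) {
    if (out$strain[i] == reference) {
      return(NA_real_)
    }
    fisher_exact_2x2(matrix(
      c(
        out$n_with_gc[i], out$n_tetrads[i] - out$n_with_gc[i],
        ref$n_with_gc, ref$n_tetrads - ref$n_with_gc
      ),
      nrow = 2, byrow = TRUE
    ))
  }, numeric(1))
  out
}
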