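# Sporulation, spore viability, and meiosis-I nondisjunction inference.

#' Sporulation efficiency
#'
#' Percentage of diploid cells that formed spores (dyads, triads or
#' tetrads) under sporulation conditions.
#'
#' @param dyads,triads,tetrads,unsporulated Non-negative cell counts.
#' @return Percentage in \[0, 100\].
#' @export
sporulation_efficiency <- function(dyads, triads, tetrads, unsporulated) {
  total <- dyads + triads + tetrads + unsporulated
  if (total <= 0) stop("no cells counted")
  100 * (dyads + triads + tetrads) / total
}

#' Spore-viability summary per strain
#'
#' Tallies tetrads by number of viable spores (0 to 4) and computes overall
#' spore viability, the fraction of all dissected spores that germinated:
#' \eqn{100 \sum_k k\,c_k / (4\,T)} for class counts \eqn{c_k} over
#' \eqn{T} tetrads.
#'
#' @inheritParams validate_tetrads
#' @return Tibble with one row per strain: strain, n_tetrads, n4..n0 class
#'   counts, pct_viability, and pct4..pct0 class percentages (full
#'   precision).
#' @export
viability_table <- function(tetrads) {
  vb <- classify_viability(tetrads)
  per <- lapply(split(vb, vb$strain), function(v) {
    cl <- vapply(4:0, function(k) sum(v$n_viable == k), integer(1))
    n <- nrow(v)
    out <- tibble::tibble(
      strain = v$strain[1], n_tetrads = n,
      n4 = cl[1], n3 = cl[2], n2 = cl[3], n1 = cl[4], n0 = cl[5],
      pct_viability = 100 * sum(v$n_viable) / (4 * n)
    )
    out[paste0("pct", 4:0)] <- as.list(100 * cl / n)
    out
  })
  dplyr::bind_rows(per)
}

#' Viability summary from pre-tallied class counts
#'
#' Same arithmetic as [viability_table()], starting from the five class
#' counts instead of a spore-level table.
#'
#' @param n4,n3,n2,n1,n0 Tetrad counts by number of viable spores
#'   (vectorised).
#' @return Tibble with n_tetrads, pct_viability and class percentages.
#' @examples
#' viability_from_counts(503, 64, 15, 2, 0) # 96% spore viability
#' @export
viability_from_counts <- function(n4, n3, n2, n1, n0) {
  n <- n4 + n3 + n2 + n1 + n0
  if (any(n <= 0)) stop("no tetrads")
  tibble::tibble(
    n_tetrads = n,
    pct_viability = 100 * (4 * n4 + 3 * n3 + 2 * n2 + n1) / (4 * n),
    pct4 = 100 * n4 / n, pct3 = 100 * n3 / n, pct2 = 100 * n2 / n,
    pct1 = 100 * n1 / n, pct0 = 100 * n0 / n
  )
}

#' Mating phenotype implied by a spore's MAT content
#'
#' A spore carrying only MATa mates as `a`, only MATalpha as `alpha`, and a
#' disome carrying both (e.g. after meiosis-I nondisjunction of the
#' MAT-bearing chromosome) expresses both and is a nonmater.
#'
#' @param has_a,has_alpha Logicals (vectorised): does the spore carry the
#'   MATa / MATalpha allele?
#' @return Character vector: `"a"`, `"alpha"` or `"non"`.
#' @export
mating_phenotype <- function(has_a, has_alpha) {
  if (any(!has_a & !has_alpha)) {
    stop("spore carries no MAT allele (nullisomic spores are inviable)")
  }
  ifelse(has_a & has_alpha, "non", ifelse(has_a, "a", "alpha"))
}

#' Infer meiosis-I nondisjunction from 2-spore-viable tetrads
#'
#' MI nondisjunction of the MAT-bearing chromosome followed by a normal MII
#' produces a tetrad whose 2 viable spores are both MATa/MATalpha disomes,
#' hence both nonmaters. This op counts such double-nonmater tetrads among
#' the 2-spore-viable class. A tetrad enters the denominator only when both
#' viable spores have a determined mating phenotype (an `"nd"` phenotype is
#' missing data, never evidence either way).
#'
#' @inheritParams validate_tetrads
#' @return Tibble per strain: strain, n_two_viable, n_examined (both
#'   phenotypes scored), ndj_events, ndj_pct (events / examined * 100;
#'   `NaN` when nothing could be examined).
#' @export
infer_mi_ndj <- function(tetrads) {
  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  first <- seq(1, nrow(tetrads), by = 4)
  viable <- matrix(tetrads$viable, nrow = 4)
  mating <- matrix(tetrads$mating, nrow = 4)
  two_v <- colSums(viable) == 2L
  scored <- vapply(seq_len(ncol(viable)), function(j) {
    all(mating[viable[, j], j] != "nd")
  }, logical(1))
  event <- vapply(seq_len(ncol(viable)), function(j) {
    all(mating[viable[, j], j] == "non")
  }, logical(1))
  df <- tibble::tibble(
    strain = tetrads$strain[first],
    two_v = two_v, examined = two_v & scored, event = two_v & scored & event
  )
  dplyr::summarise(dplyr::group_by(df, .data$strain),
    n_two_viable = sum(.data$two_v),
    n_examined = sum(.data$examined),
    ndj_events = sum(.data$event),
    ndj_pct = 100 * sum(.data$event) / sum(.data$examined),
    .groups = "drop"
  )
}
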