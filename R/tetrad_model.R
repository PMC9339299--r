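#' @importFrom rlang .data
#' @importFrom stats rbinom rmultinom rpois runif setNames
#' @importFrom utils head
NULL

# A tetrad table is a tidy data frame with one row per spore:
#   strain, tetrad_id, spore (1..4), viable (logical),
#   mating ("a" | "alpha" | "non" | "nd"),
#   one column per mapped marker holding "P", "Q" or "-" (missing).
# Dead spores carry no genotype: all alleles "-", mating "nd".

tetrad_key <- function(tetrads) paste(tetrads$strain, tetrads$tetrad_id, sep = "\r")

#' Validate a tetrad table against a marker map
#'
#' Checks the structural invariants every downstream operation assumes:
#' exactly 4 spores per tetrad, spore indices 1 to 4, allele codes in
#' {P, Q, -}, dead spores fully blank.
#'
#' @param tetrads A tetrad table (see package overview).
#' @param map A [marker_map()].
#' @return The table, invisibly, with rows ordered by strain, tetrad and
#'   spore index. Errors describe the offending tetrad ids.
#' @export
validate_tetrads <- function(tetrads, map) {
  need <- c("strain", "tetrad_id", "spore", "viable", "mating")
  miss <- setdiff(need, names(tetrads))
  if (length(miss) > 0) stop("tetrad table lacks columns: ", paste(miss, collapse = ", "))
  mk <- map_markers(map)
  miss <- setdiff(mk, names(tetrads))
  if (length(miss) > 0) stop("tetrad table lacks marker columns: ", paste(miss, collapse = ", "))

  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  key <- tetrad_key(tetrads)
  cnt <- table(key)
  bad <- names(cnt)[cnt != 4L]
  if (length(bad) > 0) {
    stop(
      "tetrads without exactly 4 spore rows: ",
      paste(sub("\r", "/", head(bad, 5)), collapse = ", ")
    )
  }
  sp <- tetrads$spore
  if (!all(sp == rep(1:4, length.out = length(sp)))) {
    stop("spore indices must be 1,2,3,4 within each tetrad")
  }
  al <- as.matrix(tetrads[, mk, drop = FALSE])
  ok <- al %in% c("P", "Q", "-")
  if (!all(ok)) {
    stop("unknown allele code(s): ", paste(unique(al[!ok]), collapse = ", "))
  }
  dead <- !tetrads$viable
  if (any(al[dead, ] != "-")) {
    stop("dead spores must have all alleles '-' (no dead-spore genotypes)")
  }
  if (!all(tetrads$mating %in% c("a", "alpha", "non", "nd"))) {
    stop("mating must be one of a, alpha, non, nd")
  }
  invisible(tetrads)
}

# 4 x T allele matrix for one marker, tetrads ordered strain/tetrad/spore
.allele_mat <- function(tetrads, marker) {
  matrix(tetrads[[marker]], nrow = 4)
}

# per-tetrad segregation pattern for one marker over *viable* spores only;
# requires 4-spore-viable tetrads for a meaningful call
.patterns_one_marker <- function(al) {
  nP <- colSums(al == "P")
  nQ <- colSums(al == "Q")
  pat <- paste0(nP, ":", nQ)
  pat[nP + nQ < 4L] <- "incomplete"
  pat
}

#' Score the segregation pattern of one marker in one tetrad
#'
#' In a 4-spore-viable tetrad a heterozygous marker segregates 2:2 unless a
#' gene conversion (or scoring failure) intervened; 3:1, 1:3, 4:0 and 0:4
#' are non-Mendelian patterns. Any missing allele among the viable spores
#' makes the marker unscorable (`"incomplete"`).
#'
#' @param tetrad A 4-row tetrad table slice holding one tetrad with 4 viable
#'   spores.
#' @param marker Marker name (must exist as a column).
#' @return One of `"2:2"`, `"3:1"`, `"1:3"`, `"4:0"`, `"0:4"`,
#'   `"incomplete"`.
#' @export
score_marker_segregation <- function(tetrad, marker) {
  if (!marker %in% names(tetrad)) {
    stop("marker '", marker, "' not found in tetrad table: map/table mismatch")
  }
  if (nrow(tetrad) != 4L) stop("a tetrad has exactly 4 spores")
  if (!all(tetrad$viable)) stop("segregation patterns are scored on 4-spore-viable tetrads")
  a <- tetrad[[marker]]
  nP <- sum(a == "P")
  nQ <- sum(a == "Q")
  if (nP + nQ < 4L) {
    return("incomplete")
  }
  paste0(nP, ":", nQ)
}

#' Segregation patterns for all markers of all 4-spore-viable tetrads
#'
#' Vectorised companion of [score_marker_segregation()].
#'
#' @inheritParams validate_tetrads
#' @return Tibble with strain, tetrad_id, marker, chrom, pattern.
#' @export
segregation_patterns <- function(tetrads, map) {
  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  viable_n <- colSums(matrix(tetrads$viable, nrow = 4))
  keep <- viable_n == 4L
  first <- seq(1, nrow(tetrads), by = 4)
  mk <- map$markers
  out <- lapply(seq_len(nrow(mk)), function(i) {
    al <- .allele_mat(tetrads, mk$marker[i])[, keep, drop = FALSE]
    tibble::tibble(
      strain = tetrads$strain[first][keep],
      tetrad_id = tetrads$tetrad_id[first][keep],
      marker = mk$marker[i],
      chrom = mk$chrom[i],
      pattern = .patterns_one_marker(al)
    )
  })
  dplyr::bind_rows(out)
}

#' Count gene conversions per 4-spore-viable tetrad
#'
#' A gene conversion call is any marker whose segregation pattern is neither
#' 2:2 nor incomplete. 4:0 and 0:4 patterns are counted but additionally
#' flagged (`n_flagged_40`): with two independent parental alleles they can
#' also arise from genotyping error, which the tally preserves rather than
#' adjudicates.
#'
#' @inheritParams validate_tetrads
#' @return Tibble with one row per 4-spore-viable tetrad: strain, tetrad_id,
#'   n_gc, converted (list-column of marker names), converted_chrom
#'   (list-column of their chromosomes), n_flagged_40. Tetrads that are not
#'   4-spore viable are an error: filter first.
#' @export
count_gene_conversions <- function(tetrads, map) {
  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  viable_n <- colSums(matrix(tetrads$viable, nrow = 4))
  if (any(viable_n != 4L)) {
    stop(
      "gene conversions are counted on 4-spore-viable tetrads only; ",
      sum(viable_n != 4L), " tetrad(s) are not (filter first)"
    )
  }
  pats <- segregation_patterns(tetrads, map)
  pats$gc <- !(pats$pattern %in% c("2:2", "incomplete"))
  pats$flag40 <- pats$pattern %in% c("4:0", "0:4")
  out <- dplyr::summarise(
    dplyr::group_by(pats, .data$strain, .data$tetrad_id),
    n_gc = sum(.data$gc),
    converted = list(.data$marker[.data$gc]),
    converted_chrom = list(.data$chrom[.data$gc]),
    n_flagged_40 = sum(.data$flag40),
    .groups = "drop"
  )
  out
}

#' Classify a two-marker interval in one tetrad
#'
#' With both markers segregating 2:2, the four two-marker spore genotypes
#' fall into one of three tetrad types: parental ditype (PD, no recombinant
#' spores), tetratype (TT, two recombinants) or nonparental ditype (NPD,
#' four recombinants). A tetrad in which either flanking marker is non-2:2
#' or incomplete is excluded from that interval's tally.
#'
#' @param tetrad A 4-row, 4-spore-viable tetrad slice.
#' @param markerA,markerB Flanking marker names. Cross-chromosome pairs are
#'   permitted (useful for independence checks).
#' @return One of `"PD"`, `"TT"`, `"NPD"`, `"excluded"`.
#' @export
classify_interval <- function(tetrad, markerA, markerB) {
  pa <- score_marker_segregation(tetrad, markerA)
  pb <- score_marker_segregation(tetrad, markerB)
  if (pa != "2:2" || pb != "2:2") {
    return("excluded")
  }
  n_rec <- sum(tetrad[[markerA]] != tetrad[[markerB]])
  switch(as.character(n_rec),
    "0" = "PD",
    "4" = "NPD",
    "2" = "TT",
    stop("impossible recombinant count under 2:2/2:2 segregation")
  )
}

#' Viable-spore count per tetrad
#'
#' @inheritParams validate_tetrads
#' @return Tibble with strain, tetrad_id, n_viable (0..4).
#' @export
classify_viability <- function(tetrads) {
  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  first <- seq(1, nrow(tetrads), by = 4)
  tibble::tibble(
    strain = tetrads$strain[first],
    tetrad_id = tetrads$tetrad_id[first],
    n_viable = colSums(matrix(tetrads$viable, nrow = 4))
  )
}

#' Filter tetrads for linkage mapping
#'
#' Keeps tetrads with exactly 4 viable spores and at most `max_gc` gene
#' conversions, the standard admission rule for tetrad-based map distances.
#' The number removed by each rule is reported via `message()` and attached
#' as the `"filter_counts"` attribute so every exclusion is auditable.
#'
#' @inheritParams validate_tetrads
#' @param max_gc Maximum gene conversions tolerated per tetrad (default 2).
#' @return The filtered tetrad table.
#' @export
filter_for_mapping <- function(tetrads, map, max_gc = 2) {
  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  vb <- classify_viability(tetrads)
  keep4 <- vb$n_viable == 4L
  n_not4 <- sum(!keep4)
  t4 <- tetrads[rep(keep4, each = 4L), , drop = FALSE]
  if (nrow(t4) == 0) {
    message("filter_for_mapping: removed ", n_not4, " non-4-spore-viable; 0 remain")
    attr(t4, "filter_counts") <- c(not_4_viable = n_not4, too_many_gc = 0L, kept = 0L)
    return(t4)
  }
  gc <- count_gene_conversions(t4, map)
  ok <- gc$n_gc <= max_gc
  n_gc_removed <- sum(!ok)
  out <- t4[rep(ok, each = 4L), , drop = FALSE]
  message(
    "filter_for_mapping: removed ", n_not4, " non-4-spore-viable and ",
    n_gc_removed, " with >", max_gc, " gene conversions; ",
    sum(ok), " tetrads kept"
  )
  attr(out, "filter_counts") <- c(
    not_4_viable = n_not4,
    too_many_gc = n_gc_removed, kept = sum(ok)
  )
  out
}

#' Tally PD/TT/NPD counts for every map interval
#'
#' Tetrads are excluded interval-by-interval: a tetrad drops out of an
#' interval's tally when either flanking marker is non-2:2 or incomplete,
#' so totals may differ between intervals of the same strain.
#'
#' @param tetrads A tetrad table that already passed [filter_for_mapping()].
#' @param map A [marker_map()].
#' @return Tibble with one row per strain and interval: strain, interval,
#'   chrom, PD, TT, NPD, excluded, n (= PD+TT+NPD).
#' @export
tabulate_interval_counts <- function(tetrads, map) {
  iv <- map$intervals
  strains <- unique(tetrads$strain)
  if (length(strains) == 0) {
    warning("empty tetrad table: all interval counts zero")
    return(tibble::tibble(
      strain = character(), interval = character(), chrom = character(),
      PD = integer(), TT = integer(), NPD = integer(),
      excluded = integer(), n = integer()
    ))
  }
  tetrads <- dplyr::arrange(tibble::as_tibble(tetrads), .data$strain, .data$tetrad_id, .data$spore)
  first <- seq(1, nrow(tetrads), by = 4)
  strain_of <- tetrads$strain[first]

  per_iv <- lapply(seq_len(nrow(iv)), function(i) {
    a <- .allele_mat(tetrads, iv$left[i])
    b <- .allele_mat(tetrads, iv$right[i])
    ok_a <- colSums(a == "P") == 2L & colSums(a == "Q") == 2L
    ok_b <- colSums(b == "P") == 2L & colSums(b == "Q") == 2L
    usable <- ok_a & ok_b
    n_rec <- colSums(a != b)
    cls <- rep("excluded", length(usable))
    cls[usable & n_rec == 0L] <- "PD"
    cls[usable & n_rec == 2L] <- "TT"
    cls[usable & n_rec == 4L] <- "NPD"
    tab <- table(factor(strain_of, levels = strains), factor(cls, levels = c("PD", "TT", "NPD", "excluded")))
    tibble::tibble(
      strain = strains,
      interval = iv$interval[i],
      chrom = iv$chrom[i],
      PD = as.integer(tab[, "PD"]),
      TT = as.integer(tab[, "TT"]),
      NPD = as.integer(tab[, "NPD"]),
      excluded = as.integer(tab[, "excluded"])
    )
  })
  out <- dplyr::bind_rows(per_iv)
  out$n <- out$PD + out$TT + out$NPD
  dplyr::arrange(out, .data$strain, match(.data$interval, iv$interval))
}
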