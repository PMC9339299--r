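#' Construct a marker map
#'
#' A marker map is the ordered set of heterozygous markers scored in every
#' tetrad, grouped by chromosome. Adjacent markers on the same chromosome
#' define the genetic intervals whose PD/TT/NPD counts are tallied for
#' mapping.
#'
#' @param markers A data frame with columns `marker` (character, unique) and
#'   `chrom` (character). Row order within a chromosome is the map order.
#' @param cen A named numeric vector giving, per chromosome, the centromere
#'   position in Morgans along that chromosome's genetic map (used only by
#'   the simulator). May be `NULL` for analysis-only maps.
#' @param distances Optional numeric vector of true inter-marker distances in
#'   centimorgans, one per interval (used only by the simulator as ground
#'   truth). Order follows `intervals(map)`.
#'
#' @return An object of class `marker_map`: a list with elements
#'   `markers` (tibble: marker, chrom, index), `intervals` (tibble:
#'   interval, chrom, left, right), `cen`, and `distances_cM`.
#'
#' @examples
#' mm <- marker_map(data.frame(
#'   marker = c("A", "B", "C"), chrom = c("1", "1", "1")))
#' mm$intervals
#' @export
marker_map <- function(markers, cen = NULL, distances = NULL) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker", "chrom") %in% names(markers)))
  if (anyDuplicated(markers$marker) > 0) {
    stop("marker names must be unique")
  }
  mk <- tibble::tibble(
    marker = as.character(markers$marker),
    chrom = as.character(markers$chrom)
  )
  mk <- dplyr::mutate(dplyr::group_by(mk, .data$chrom), index = dplyr::row_number())
  mk <- dplyr::ungroup(mk)

  iv <- dplyr::reframe(
    dplyr::group_by(mk, .data$chrom),
    left = .data$marker[-dplyr::n()],
    right = .data$marker[-1]
  )
  iv <- dplyr::mutate(iv,
    interval = paste0(.data$left, "-", .data$right),
    .before = 1
  )
  if (!is.null(distances)) {
    if (length(distances) != nrow(iv)) {
      stop("need one distance per interval (", nrow(iv), "), got ", length(distances))
    }
    iv$cM <- as.numeric(distances)
  }
  structure(
    list(markers = mk, intervals = iv, cen = cen),
    class = "marker_map"
  )
}

#' @export
print.marker_map <- function(x, ...) {
  cat("<marker_map> ", nrow(x$markers), " markers on ",
    length(unique(x$markers$chrom)), " chromosome(s); ",
    nrow(x$intervals), " intervals\n",
    sep = ""
  )
  for (ch in unique(x$markers$chrom)) {
    cat(" ", ch, ": ",
      paste(x$markers$marker[x$markers$chrom == ch], collapse = " - "),
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' The nine-marker chromosome III / VIII yeast map
#'
#' The marker configuration used throughout the package examples: five
#' markers spanning four intervals on chromosome III (HIS4, CEN3, MAT,
#' RAD18, HMR) and four markers spanning three intervals on chromosome VIII
#' (SPO11, SPO13, THR1, LYS2). The MAT locus doubles as the mating-type
#' determinant: the P allele is taken as MATa and the Q allele as MATalpha,
#' which is what makes meiosis-I nondisjunction of chromosome III visible as
#' nonmating disomic spores.
#'
#' @param distances Numeric vector of 7 true interval distances in cM for
#'   simulation, in interval order (III first). Defaults to wild-type
#'   estimates from the bundled count data.
#'
#' @return A `marker_map` with centromere positions set (CEN3 is itself a
#'   marker; the chromosome VIII centromere sits in the SPO11-SPO13
#'   interval, close to SPO13).
#' @export
yeast_marker_map <- function(distances = c(28.4, 19.3, 35.0, 20.8, 41.6, 10.6, 32.4)) {
  mk <- data.frame(
    marker = c(
      "HIS4", "CEN3", "MAT", "RAD18", "HMR",
      "SPO11", "SPO13", "THR1", "LYS2"
    ),
    chrom = c(rep("III", 5), rep("VIII", 4))
  )
  stopifnot(length(distances) == 7)
  d <- distances / 100 # Morgans
  # centromere coordinates on each chromosome's own genetic axis
  cen <- c(III = d[1], VIII = d[5] * 0.9)
  marker_map(mk, cen = cen, distances = distances)
}

#' Genetic coordinates of the markers of a map
#'
#' Cumulative positions (Morgans) along each chromosome implied by the map's
#' true interval distances; first marker of each chromosome is at 0.
#'
#' @param map A `marker_map` with `distances` set.
#' @return Tibble with columns marker, chrom, pos (Morgans).
#' @keywords internal
marker_positions <- function(map) {
  if (is.null(map$intervals$cM)) {
    stop("marker map carries no true distances; pass `distances` to marker_map()")
  }
  out <- lapply(unique(map$markers$chrom), function(ch) {
    mk <- map$markers$marker[map$markers$chrom == ch]
    d <- map$intervals$cM[map$intervals$chrom == ch] / 100
    tibble::tibble(marker = mk, chrom = ch, pos = c(0, cumsum(d)))
  })
  dplyr::bind_rows(out)
}

#' Marker columns of a tetrad table
#' @param tetrads A tetrad table.
#' @param map A `marker_map`.
#' @keywords internal
map_markers <- function(map) map$markers$marker
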