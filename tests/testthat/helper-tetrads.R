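# Builders for small in-code fixtures used across the tests.

# a 2-chromosome toy map: 3 markers on "1", 2 on "2"
toy_map <- function() {
  marker_map(
    data.frame(
      marker = c("A", "B", "C", "D", "E"),
      chrom = c("1", "1", "1", "2", "2")
    ),
    cen = c("1" = 0, "2" = 0),
    distances = c(20, 20, 10)
  )
}

# build one tetrad row-block from per-spore allele strings.
# alleles: list of 4 named character vectors (marker -> "P"/"Q"/"-");
# dead spores are blanked automatically.
make_tetrad <- function(alleles, viable = rep(TRUE, 4),
                        mating = rep("nd", 4),
                        strain = "s", tetrad_id = "t1",
                        markers = names(alleles[[1]])) {
  rows <- lapply(1:4, function(i) {
    al <- if (viable[i]) alleles[[i]][markers] else setNames(rep("-", length(markers)), markers)
    c(
      list(
        strain = strain, tetrad_id = tetrad_id, spore = i,
        viable = viable[i], mating = if (viable[i]) mating[i] else "nd"
      ),
      as.list(al)
    )
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# a fully Mendelian 4-viable tetrad on `map` (all markers 2:2, all PD)
mendelian_tetrad <- function(map, strain = "s", tetrad_id = "t1") {
  mk <- map$markers$marker
  pat <- lapply(c("P", "P", "Q", "Q"), function(a) setNames(rep(a, length(mk)), mk))
  make_tetrad(pat, strain = strain, tetrad_id = tetrad_id, markers = mk)
}

# stack tetrads with distinct ids
stack_tetrads <- function(...) {
  tt <- list(...)
  for (i in seq_along(tt)) tt[[i]]$tetrad_id <- sprintf("t%03d", i)
  dplyr::bind_rows(tt)
}
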