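# Forward simulator of single meioses. Chiasmata are placed on each
# bivalent by a stationary renewal ("counting") process; strand choice is
# uniform (no chromatid interference); gene conversion, meiosis-I
# nondisjunction, meiosis-II precocious sister separation and random spore
# death are applied per the configured rates. Coordinates are genetic
# (Morgans) throughout: markers are points on the chiasma renewal line.

#' Simulation configuration
#'
#' @param map A [marker_map()] carrying true interval distances in cM
#'   (ground truth for parameter-recovery tests).
#' @param n Number of meioses to simulate.
#' @param seed Integer random seed; mandatory, echoed in the output
#'   provenance so every table is reproducible.
#' @param m Interference parameter of the counting model (non-negative
#'   integer). `m = 0` gives a Poisson (no-interference) chiasma process;
#'   larger `m` forces `m` intermediate events between successive chiasmata,
#'   producing positive interference.
#' @param gc_prob Per-marker, per-meiosis gene-conversion probability. The
#'   default 0.015 over 9 markers yields about 0.135 conversions per
#'   tetrad, the rate seen in wild-type dissections.
#' @param mi_ndj Per-chromosome meiosis-I nondisjunction probability
#'   (scalar, recycled over chromosomes, or named by chromosome).
#' @param mii_pssc Per-chromosome probability of a meiosis-II missegregation
#'   following precocious sister separation (one spore disomic, its sister
#'   nullisomic and dead).
#' @param death Independent per-spore random death probability (default
#'   0.04, matching ~96% spore viability).
#' @param strain Strain label written into the output table.
#' @param mat_marker Marker whose alleles encode mating type (P = MATa,
#'   Q = MATalpha); `NA` disables mating phenotypes.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(map, n, seed, m = 0, gc_prob = 0.015,
                       mi_ndj = 0.002, mii_pssc = 0.005, death = 0.04,
                       strain = "sim",
                       mat_marker = if ("MAT" %in% map$markers$marker) "MAT" else NA) {
  stopifnot(inherits(map, "marker_map"), n >= 1, m >= 0, m == round(m))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  probs <- c(gc_prob, mi_ndj, mii_pssc, death)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  chroms <- unique(map$markers$chrom)
  expand <- function(p) {
    if (!is.null(names(p))) {
      out <- p[chroms]
      if (anyNA(out)) stop("per-chromosome probability missing for some chromosome")
      return(unname(out))
    }
    rep_len(p, length(chroms))
  }
  structure(
    list(
      map = map, n = as.integer(n), seed = as.integer(seed), m = as.integer(m),
      gc_prob = gc_prob, mi_ndj = expand(mi_ndj), mii_pssc = expand(mii_pssc),
      death = death, strain = strain, mat_marker = mat_marker, chroms = chroms
    ),
    class = "sim_config"
  )
}

#' Chiasma counts and positions from the counting model
#'
#' For a bivalent of genetic length `x` Morgans, the mean chiasma count is
#' `2x` (each chiasma involves 2 of the 4 chromatids, so each chromatid sees
#' `x` crossovers on average). With `m = 0` the count is Poisson(2x) with
#' uniform positions. With `m > 0`, a Poisson stream of rate `2x(m+1)` is
#' thinned so that every (m+1)-th event is a chiasma, with a uniformly
#' random initial phase (stationary renewal), which spaces chiasmata apart.
#'
#' @param x Genetic length in Morgans (>= 0).
#' @param m Non-negative integer interference parameter.
#' @return Numeric vector of sorted chiasma positions in `[0, x]` (possibly
#'   empty). Draws from the current RNG stream.
#' @export
chiasma_count_model <- function(x, m = 0) {
  if (x < 0) stop("genetic length must be >= 0")
  if (x == 0) {
    return(numeric(0))
  }
  if (m == 0) {
    k <- rpois(1, 2 * x)
    return(sort(runif(k, 0, x)))
  }
  n_ev <- rpois(1, 2 * x * (m + 1))
  if (n_ev == 0) {
    return(numeric(0))
  }
  ev <- sort(runif(n_ev, 0, x))
  phase <- sample.int(m + 1, 1) # index of the first chiasma event
  if (phase > n_ev) {
    return(numeric(0))
  }
  idx <- seq(phase, n_ev, by = m + 1)
  ev[idx]
}

# Resolve one bivalent: 4 chromatid allele vectors over `positions`
# (Morgans), after applying chiasmata left to right. Rows 1,2 start as
# homolog P; rows 3,4 as homolog Q. Each chiasma exchanges everything
# distal (right) of its point between one strand carrying P-derived and
# one carrying Q-derived material *at that point*, each chosen uniformly
# (no chromatid interference). Choosing by local content, not by original
# row label, is what makes every chiasma a genetically effective
# between-homolog exchange once earlier crossovers have shuffled the
# strands; label-based choice would silently allow same-origin swaps and
# deflate crossover counts in distal intervals.
resolve_bivalent <- function(positions, chiasmata) {
  k <- length(chiasmata)
  strands <- matrix(rep(c("P", "P", "Q", "Q"), each = length(positions)),
    nrow = 4, byrow = TRUE
  )
  if (k == 0) {
    return(strands)
  }
  cur <- c("P", "P", "Q", "Q") # strand content at the scan point
  for (x in sort(chiasmata)) {
    i <- sample(which(cur == "P"), 1L)
    j <- sample(which(cur == "Q"), 1L)
    distal <- positions > x
    if (any(distal)) {
      tmp <- strands[i, distal]
      strands[i, distal] <- strands[j, distal]
      strands[j, distal] <- tmp
    }
    cur[c(i, j)] <- c("Q", "P")
  }
  strands
}

# Segregate 4 chromatids into 4 spores. Sisterhood is defined by centromere
# origin (tracked as an extra position in `strands`' last column).
# Returns a list of 4 integer vectors: chromatid row indices per spore.
#  mode "normal": 1 chromatid per spore; "mi_ndj": all 4 to one pole, both
#  its spores disomic, other pole nullisomic; "mii": one spore of one pole
#  takes both chromatids of its pair.
segregate_chromatids <- function(cen_origin, mode = c("normal", "mi_ndj", "mii")) {
  mode <- match.arg(mode)
  pair_p <- which(cen_origin == "P")
  pair_q <- which(cen_origin == "Q")
  stopifnot(length(pair_p) == 2L, length(pair_q) == 2L)
  # random MI orientation: which pair goes to the pole forming spores 1,2
  if (sample.int(2L, 1L) == 1L) {
    pole1 <- pair_p
    pole2 <- pair_q
  } else {
    pole1 <- pair_q
    pole2 <- pair_p
  }
  if (mode == "normal") {
    p1 <- sample(pole1)
    p2 <- sample(pole2)
    return(list(p1[1], p1[2], p2[1], p2[2]))
  }
  if (mode == "mi_ndj") {
    # both pairs to one pole; MII still separates sisters, so each viable
    # spore receives one chromatid of each pair
    a <- c(sample(pair_p, 1), sample(pair_q, 1))
    b <- setdiff(c(pair_p, pair_q), a)
    if (sample.int(2L, 1L) == 1L) {
      return(list(a, b, integer(0), integer(0)))
    }
    return(list(integer(0), integer(0), a, b))
  }
  # mii: precocious sister separation -> both sisters of one pair end in
  # one spore, its sister spore gets none
  p2 <- sample(pole2)
  if (sample.int(2L, 1L) == 1L) {
    both <- if (sample.int(2L, 1L) == 1L) list(pole1, integer(0)) else list(integer(0), pole1)
    return(list(both[[1]], both[[2]], p2[1], p2[2]))
  }
  both <- if (sample.int(2L, 1L) == 1L) list(pole2, integer(0)) else list(integer(0), pole2)
  p1 <- sample(pole1)
  list(p1[1], p1[2], both[[1]], both[[2]])
}

#' Simulate a tetrad dissection experiment
#'
#' Runs `config$n` independent meioses and emits a standard tetrad table.
#' Per meiosis and chromosome, the order of stochastic events is fixed:
#' chiasma placement, strand choice, segregation-mode draw (MI
#' nondisjunction, else MII missegregation, else normal), MI orientation
#' and MII spore assignment; then per-marker gene conversion; then random
#' spore death. Dead spores are blanked (all alleles `-`, mating `nd`).
#'
#' @param config A [sim_config()].
#' @return A tetrad table (tibble) with attribute `"sim_config"` carrying
#'   the configuration, including the seed.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- config$map
  pos <- marker_positions(map)
  markers <- map$markers$marker
  n <- config$n
  n_mk <- length(markers)

  alleles <- matrix("-", nrow = 4 * n, ncol = n_mk, dimnames = list(NULL, markers))
  viable <- rep(TRUE, 4 * n)
  mating <- rep("nd", 4 * n)

  chrom_info <- lapply(seq_along(config$chroms), function(ci) {
    ch <- config$chroms[ci]
    p <- pos[pos$chrom == ch, ]
    list(
      chrom = ch, markers = p$marker, mpos = p$pos,
      len = max(p$pos), cen = unname(config$map$cen[ch]),
      mi = config$mi_ndj[ci], mii = config$mii_pssc[ci]
    )
  })

  for (i in seq_len(n)) {
    rows <- (4 * (i - 1) + 1):(4 * i)
    copies <- vector("list", length(chrom_info)) # per chrom: list of 4 allele-vector lists
    for (ci in seq_along(chrom_info)) {
      info <- chrom_info[[ci]]
      chi <- chiasma_count_model(info$len, config$m)
      strands <- resolve_bivalent(c(info$mpos, info$cen), chi)
      cen_origin <- strands[, length(info$mpos) + 1L]
      mode <- "normal"
      u <- runif(1)
      if (u < info$mi) {
        mode <- "mi_ndj"
      } else if (u < info$mi + info$mii) {
        mode <- "mii"
      }
      assign_idx <- segregate_chromatids(cen_origin, mode)
      # keep the centromere column (last) alongside marker alleles: the
      # mating-phenotype rule for disomes needs centromere origins
      copies[[ci]] <- lapply(assign_idx, function(idx) {
        strands[idx, , drop = FALSE]
      })
    }
    # spore alleles; a spore lacking any chromosome is dead (nullisomy)
    sp_dead <- logical(4)
    for (s in 1:4) {
      for (ci in seq_along(chrom_info)) {
        cp <- copies[[ci]][[s]]
        if (nrow(cp) == 0L) {
          sp_dead[s] <- TRUE
        } else {
          mcols <- seq_along(chrom_info[[ci]]$mpos)
          a <- apply(cp[, mcols, drop = FALSE], 2, function(col) {
            if (length(unique(col)) == 1L) col[1] else "-"
          })
          alleles[rows[s], chrom_info[[ci]]$markers] <- a
        }
      }
    }
    # gene conversion: each marker independently, overwrite one uniformly
    # chosen spore's allele with the other parental allele
    if (config$gc_prob > 0) {
      conv <- which(runif(n_mk) < config$gc_prob)
      for (mi in conv) {
        s <- sample.int(4L, 1L)
        cur <- alleles[rows[s], mi]
        if (cur == "P") {
          alleles[rows[s], mi] <- "Q"
        } else if (cur == "Q") alleles[rows[s], mi] <- "P"
      }
    }
    # mating phenotype from MAT-bearing chromosome content
    if (!is.na(config$mat_marker)) {
      mat_ci <- which(vapply(chrom_info, function(x) config$mat_marker %in% x$markers, logical(1)))
      mat_col <- which(chrom_info[[mat_ci]]$markers == config$mat_marker)
      cen_col <- length(chrom_info[[mat_ci]]$mpos) + 1L
      for (s in 1:4) {
        if (sp_dead[s]) next
        cp <- copies[[mat_ci]][[s]]
        if (nrow(cp) == 1L) {
          # single copy: phenotype follows the (possibly converted) allele
          al <- alleles[rows[s], config$mat_marker]
        } else if (length(unique(cp[, cen_col])) == 2L) {
          # heterocentromeric disome (MI nondisjunction product): carries
          # both homologs and expresses both mating types
          al <- c("P", "Q")
        } else {
          al <- unique(cp[, mat_col])
        }
        mating[rows[s]] <- if (length(al) > 1L) {
          "non"
        } else if (al == "P") "a" else if (al == "Q") "alpha" else "nd"
      }
    }
    # independent random spore death, applied last
    sp_dead <- sp_dead | (runif(4) < config$death)
    if (any(sp_dead)) {
      alleles[rows[sp_dead], ] <- "-"
      mating[rows[sp_dead]] <- "nd"
      viable[rows[sp_dead]] <- FALSE
    }
  }

  out <- tibble::tibble(
    strain = config$strain,
    tetrad_id = rep(sprintf("t%05d", seq_len(n)), each = 4),
    spore = rep(1:4, n),
    viable = viable,
    mating = mating
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(alleles))
  attr(out, "sim_config") <- config
  out
}
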