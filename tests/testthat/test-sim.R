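test_that("chiasma counting model has the right mean and boundaries", {
  expect_identical(chiasma_count_model(0, 0), numeric(0))
  expect_error(chiasma_count_model(-1, 0), ">= 0")
  set.seed(21)
  x <- 0.284
  k <- replicate(2e4, length(chiasma_count_model(x, 0)))
  expect_lt(abs(mean(k) - 2 * x), 3 * sqrt(2 * x / 2e4))
  # interference thins but preserves the mean chiasma rate
  k4 <- replicate(2e4, length(chiasma_count_model(x, 4)))
  expect_lt(abs(mean(k4) - 2 * x), 3 * sqrt(var(k4) / 2e4) + 0.01)
  # and reduces the count variance below Poisson
  expect_lt(var(k4), 0.8 * var(k))
})

test_that("tetratype probability given k chiasmata follows Mather's closed form", {
  set.seed(31)
  pos <- c(0, 0.2)
  for (k in 1:4) {
    tt <- replicate(1e4, {
      s <- tetradkit:::resolve_bivalent(pos, runif(k, 0, 0.2))
      sum(s[, 1] != s[, 2]) == 2
    })
    p_exp <- (2 / 3) * (1 - (-1 / 2)^k)
    expect_lt(abs(mean(tt) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e4) + 1e-9)
  }
  # zero chiasmata: parental ditype, always
  s0 <- tetradkit:::resolve_bivalent(pos, numeric(0))
  expect_equal(sum(s0[, 1] != s0[, 2]), 0)
})

test_that("alleles are conserved 2:2 at every marker before conversion and death", {
  mm <- toy_map()
  cfg <- sim_config(mm,
    n = 200, seed = 52, gc_prob = 0, mi_ndj = 0,
    mii_pssc = 0, death = 0, mat_marker = NA
  )
  tab <- simulate_experiment(cfg)
  for (mk in mm$markers$marker) {
    m <- matrix(tab[[mk]], nrow = 4)
    expect_true(all(colSums(m == "P") == 2 & colSums(m == "Q") == 2))
  }
})

test_that("gene conversion rate matches its binomial expectation", {
  cfg <- sim_config(yeast_marker_map(),
    n = 500, seed = 6, gc_prob = 0.015,
    mi_ndj = 0, mii_pssc = 0, death = 0
  )
  gc <- count_gene_conversions(simulate_experiment(cfg), yeast_marker_map())
  expect_lt(abs(mean(gc$n_gc) - 9 * 0.015), 3 * sqrt(9 * 0.015 / 500))
  # g = 0: nothing converts
  cfg0 <- sim_config(yeast_marker_map(),
    n = 50, seed = 7, gc_prob = 0,
    mi_ndj = 0, mii_pssc = 0, death = 0
  )
  expect_true(all(count_gene_conversions(
    simulate_experiment(cfg0), yeast_marker_map()
  )$n_gc == 0))
})

test_that("pure MI nondisjunction yields 2-viable double-nonmater tetrads", {
  mm <- yeast_marker_map()
  cfg <- sim_config(mm,
    n = 800, seed = 81, gc_prob = 0,
    mi_ndj = c(III = 0.08, VIII = 0), mii_pssc = 0, death = 0
  )
  tab <- simulate_experiment(cfg)
  vb <- classify_viability(tab)
  expect_true(all(vb$n_viable %in% c(2, 4)))
  ndj <- infer_mi_ndj(tab)
  # every 2-viable tetrad is an NDJ tetrad with two nonmaters
  expect_equal(ndj$ndj_events, ndj$n_two_viable)
  # and the event rate recovers the configured probability
  rate <- ndj$ndj_events / 800
  expect_lt(abs(rate - 0.08), 2 * sqrt(0.08 * 0.92 / 800))
})

test_that("pure MII missegregation enriches 3-viable tetrads at its configured rate", {
  mm <- yeast_marker_map()
  cfg <- sim_config(mm,
    n = 800, seed = 82, gc_prob = 0, mi_ndj = 0,
    mii_pssc = c(III = 0.08, VIII = 0), death = 0
  )
  vb <- classify_viability(simulate_experiment(cfg))
  expect_true(all(vb$n_viable %in% c(3, 4)))
  rate <- mean(vb$n_viable == 3)
  expect_lt(abs(rate - 0.08), 2 * sqrt(0.08 * 0.92 / 800))
})

test_that("simulation is reproducible from its seed", {
  mm <- yeast_marker_map()
  a <- simulate_experiment(sim_config(mm, n = 40, seed = 33))
  b <- simulate_experiment(sim_config(mm, n = 40, seed = 33))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_experiment(sim_config(mm, n = 40, seed = 34))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  expect_error(sim_config(mm, n = 10), "seed is mandatory")
})

test_that("interference ratio is near 1 without interference and below 1 with it", {
  mm <- yeast_marker_map()
  cnt0 <- suppressMessages(tabulate_interval_counts(
    simulate_experiment(sim_config(mm,
      n = 3000, seed = 91, gc_prob = 0,
      mi_ndj = 0, mii_pssc = 0, death = 0
    )), mm
  ))
  r0 <- sum(cnt0$NPD) / sum(papazian_expected_npd(cnt0$PD, cnt0$TT, cnt0$NPD))
  expect_lt(abs(r0 - 1), 0.2)
  cnt4 <- suppressMessages(tabulate_interval_counts(
    simulate_experiment(sim_config(mm,
      n = 3000, seed = 92, m = 4, gc_prob = 0,
      mi_ndj = 0, mii_pssc = 0, death = 0
    )), mm
  ))
  r4 <- sum(cnt4$NPD) / sum(papazian_expected_npd(cnt4$PD, cnt4$TT, cnt4$NPD))
  expect_lt(r4, 0.5)
})

test_that("simulated tetrads reproduce the closed-form no-interference expectations", {
  # under a Poisson chiasma process the exact expectation of the Perkins
  # statistic is 100 [3(1 - e^(-2x))/2 - (2/3)(1 - e^(-3x))]; it approaches
  # the true distance x as x -> 0 (the residual is O(x^3) from crossovers
  # beyond the doubles that the 3*NPD term corrects)
  perkins_expect <- function(x) {
    100 * (3 * (1 - exp(-2 * x)) / 2 - (2 / 3) * (1 - exp(-3 * x)))
  }
  expect_lt(abs(perkins_expect(0.106) - 10.6), 0.15)
  mm <- marker_map(
    data.frame(marker = c("L", "M", "R"), chrom = c("1", "1", "1")),
    cen = c("1" = 0), distances = c(19.3, 10.6)
  )
  cfg <- sim_config(mm,
    n = 4000, seed = 14, gc_prob = 0, mi_ndj = 0,
    mii_pssc = 0, death = 0, mat_marker = NA
  )
  cnt <- suppressMessages(tabulate_interval_counts(simulate_experiment(cfg), mm))
  est <- perkins_distance(cnt$PD, cnt$TT, cnt$NPD)
  expect_lt(abs(est$cM[1] - perkins_expect(0.193)), 2 * est$se_cM[1])
  expect_lt(abs(est$cM[2] - perkins_expect(0.106)), 2 * est$se_cM[2])
})
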