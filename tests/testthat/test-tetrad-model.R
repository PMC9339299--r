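map5 <- toy_map()
mk5 <- map5$markers$marker

test_that("segregation scoring distinguishes Mendelian, converted and incomplete markers", {
  al <- function(...) setNames(c(...), mk5)
  tt <- make_tetrad(list(
    al("P", "P", "P", "P", "P"),
    al("P", "P", "P", "P", "Q"),
    al("Q", "Q", "P", "-", "P"),
    al("Q", "Q", "Q", "Q", "Q")
  ))
  expect_equal(score_marker_segregation(tt, "A"), "2:2")
  expect_equal(score_marker_segregation(tt, "C"), "3:1")
  expect_equal(score_marker_segregation(tt, "D"), "incomplete")
  expect_equal(score_marker_segregation(tt, "E"), "2:2")
  expect_error(score_marker_segregation(tt, "NOPE"), "map/table mismatch")
})

test_that("interval classification covers PD, TT, NPD and exclusion", {
  al <- function(a, b) setNames(c(a, b, "P", "P", "P"), mk5)
  pd <- make_tetrad(list(al("P", "P"), al("P", "P"), al("Q", "Q"), al("Q", "Q")))
  npd <- make_tetrad(list(al("P", "Q"), al("P", "Q"), al("Q", "P"), al("Q", "P")))
  tt <- make_tetrad(list(al("P", "P"), al("P", "Q"), al("Q", "P"), al("Q", "Q")))
  conv <- make_tetrad(list(al("P", "P"), al("P", "P"), al("P", "Q"), al("Q", "Q")))
  expect_equal(classify_interval(pd, "A", "B"), "PD")
  expect_equal(classify_interval(npd, "A", "B"), "NPD")
  expect_equal(classify_interval(tt, "A", "B"), "TT")
  expect_equal(classify_interval(conv, "A", "B"), "excluded") # A is 3:1
})

test_that("interval classification is symmetric and P/Q relabeling swaps PD and NPD", {
  set.seed(71)
  for (rep in 1:25) {
    g <- replicate(4, sample(c("P", "Q"), 2, replace = TRUE), simplify = FALSE)
    # force 2:2 at both markers by pairing complements
    g[[3]] <- ifelse(g[[1]] == "P", "Q", "P")
    g[[4]] <- ifelse(g[[2]] == "P", "Q", "P")
    al <- function(v) setNames(c(v, "P", "P", "P"), mk5)
    td <- make_tetrad(lapply(1:4, function(i) al(c(g[[i]][1], g[[i]][2])[c(1, 2)])))
    td <- make_tetrad(list(
      al(c(g[[1]][1], g[[2]][1])), al(c(g[[1]][2], g[[2]][2])),
      al(c(g[[3]][1], g[[4]][1])), al(c(g[[3]][2], g[[4]][2]))
    ))
    cls <- classify_interval(td, "A", "B")
    expect_equal(classify_interval(td, "B", "A"), cls)
    # relabel P<->Q at marker A only
    flip <- td
    flip$A <- ifelse(td$A == "P", "Q", "P")
    cls_flip <- classify_interval(flip, "A", "B")
    expected <- c(PD = "NPD", NPD = "PD", TT = "TT")[cls]
    expect_equal(cls_flip, unname(expected))
    # relabel at both markers is the identity
    flip$B <- ifelse(td$B == "P", "Q", "P")
    expect_equal(classify_interval(flip, "A", "B"), cls)
  }
})

test_that("viability classification counts viable spores", {
  td <- mendelian_tetrad(map5)
  expect_equal(classify_viability(td)$n_viable, 4)
  td3 <- make_tetrad(
    lapply(1:4, function(i) setNames(rep("P", 5), mk5)),
    viable = c(TRUE, TRUE, FALSE, TRUE)
  )
  expect_equal(classify_viability(td3)$n_viable, 3)
})

test_that("mapping filter keeps 4-viable tetrads with at most 2 conversions", {
  al <- function(...) setNames(c(...), mk5)
  ok2 <- make_tetrad(list( # exactly 2 conversions (A 3:1, D 3:1): boundary, kept
    al("P", "P", "P", "P", "P"), al("P", "P", "P", "P", "Q"),
    al("P", "Q", "Q", "P", "P"), al("Q", "Q", "Q", "Q", "Q")
  ))
  bad3 <- make_tetrad(list( # 3 conversions (A, B, D): removed
    al("P", "P", "P", "P", "P"), al("P", "P", "P", "P", "Q"),
    al("P", "P", "Q", "P", "P"), al("Q", "Q", "Q", "Q", "Q")
  ))
  dead <- make_tetrad(
    lapply(1:4, function(i) al("P", "P", "P", "P", "P")),
    viable = c(TRUE, TRUE, TRUE, FALSE)
  )
  tab <- stack_tetrads(ok2, bad3, dead, mendelian_tetrad(map5))
  kept <- suppressMessages(filter_for_mapping(tab, map5))
  expect_equal(length(unique(kept$tetrad_id)), 2)
  fc <- attr(kept, "filter_counts")
  expect_equal(unname(fc["not_4_viable"]), 1)
  expect_equal(unname(fc["too_many_gc"]), 1)
  gcs <- count_gene_conversions(kept, map5)
  expect_true(all(gcs$n_gc <= 2))
})

test_that("gene conversion counting reports converted markers and chromosomes", {
  al <- function(...) setNames(c(...), mk5)
  td <- make_tetrad(list( # A 3:1 and B 1:3, both on chromosome "1"
    al("P", "Q", "P", "P", "P"), al("P", "Q", "P", "P", "Q"),
    al("P", "Q", "Q", "Q", "P"), al("Q", "Q", "Q", "Q", "Q")
  ))
  gc <- count_gene_conversions(td, map5)
  expect_equal(gc$n_gc, 2)
  expect_setequal(gc$converted[[1]], c("A", "B"))
  expect_equal(sort(gc$converted_chrom[[1]]), c("1", "1"))
  expect_equal(count_gene_conversions(mendelian_tetrad(map5), map5)$n_gc, 0)
  # non-4-viable input is the caller's bug
  dead <- make_tetrad(lapply(1:4, function(i) al("P", "P", "P", "P", "P")),
    viable = c(TRUE, FALSE, TRUE, TRUE)
  )
  expect_error(count_gene_conversions(dead, map5), "4-spore-viable")
})

test_that("interval tallies conserve tetrads and exclude conversion-flanked intervals only", {
  al <- function(...) setNames(c(...), mk5)
  # tetrad with B converted (3:1): intervals A-B and B-C excluded, D-E intact
  conv <- make_tetrad(list(
    al("P", "P", "P", "P", "P"), al("P", "P", "P", "P", "P"),
    al("Q", "P", "Q", "Q", "Q"), al("Q", "Q", "Q", "Q", "Q")
  ))
  tab <- stack_tetrads(conv, mendelian_tetrad(map5), mendelian_tetrad(map5))
  cnt <- tabulate_interval_counts(tab, map5)
  expect_true(all(cnt$PD + cnt$TT + cnt$NPD + cnt$excluded == 3))
  expect_equal(cnt$excluded[cnt$interval == "A-B"], 1)
  expect_equal(cnt$excluded[cnt$interval == "B-C"], 1)
  expect_equal(cnt$excluded[cnt$interval == "D-E"], 0)
  expect_equal(cnt$PD[cnt$interval == "D-E"], 3)
  # crossover-free tetrads are all-PD everywhere
  pure <- do.call(stack_tetrads, replicate(10, mendelian_tetrad(map5), simplify = FALSE))
  cnt0 <- tabulate_interval_counts(pure, map5)
  expect_true(all(cnt0$PD == 10 & cnt0$TT == 0 & cnt0$NPD == 0 & cnt0$excluded == 0))
})

test_that("interval tallies agree with an independent row-by-row recount of simulated data", {
  cfg <- sim_config(toy_map(),
    n = 150, seed = 402, gc_prob = 0.03,
    mi_ndj = 0, mii_pssc = 0, death = 0.05, mat_marker = NA
  )
  tab <- simulate_experiment(cfg)
  mapped <- suppressMessages(filter_for_mapping(tab, map5))
  cnt <- tabulate_interval_counts(mapped, map5)
  # oracle: plain loop over tetrads, classifying from scratch
  ids <- unique(mapped$tetrad_id)
  for (i in seq_len(nrow(map5$intervals))) {
    a <- map5$intervals$left[i]
    b <- map5$intervals$right[i]
    tally <- c(PD = 0, TT = 0, NPD = 0, excluded = 0)
    for (id in ids) {
      td <- mapped[mapped$tetrad_id == id, ]
      pa <- table(factor(td[[a]], levels = c("P", "Q", "-")))
      pb <- table(factor(td[[b]], levels = c("P", "Q", "-")))
      if (pa["P"] != 2 || pa["Q"] != 2 || pb["P"] != 2 || pb["Q"] != 2) {
        tally["excluded"] <- tally["excluded"] + 1
      } else {
        nr <- sum(td[[a]] != td[[b]])
        cls <- c("0" = "PD", "2" = "TT", "4" = "NPD")[as.character(nr)]
        tally[cls] <- tally[cls] + 1
      }
    }
    row <- cnt[cnt$interval == map5$intervals$interval[i], ]
    expect_equal(c(row$PD, row$TT, row$NPD, row$excluded), unname(tally))
  }
})

test_that("per-tetrad conversion totals equal per-marker non-2:2 totals", {
  cfg <- sim_config(toy_map(),
    n = 200, seed = 77, gc_prob = 0.05,
    mi_ndj = 0, mii_pssc = 0, death = 0, mat_marker = NA
  )
  tab <- simulate_experiment(cfg)
  gc <- count_gene_conversions(tab, map5)
  pats <- segregation_patterns(tab, map5)
  expect_equal(
    sum(gc$n_gc),
    sum(!pats$pattern %in% c("2:2", "incomplete"))
  )
})
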