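test_that("focus counting flags zero-focus cells for exclusion", {
  tab <- data.frame(
    cell_id = c("a", "a", "b", "c"), length_um = c(3, 3, 2.5, 2.8),
    channel = "locus", position_um = c(1.2, 2.4, 0.7, NA))
  class(tab) <- c("foci_table", "data.frame")
  cf <- count_foci(tab, "locus")
  expect_equal(cf$n_foci[cf$cell_id == "a"], 2L)
  expect_equal(cf$n_foci[cf$cell_id == "c"], 0L)
  expect_true(cf$excluded[cf$cell_id == "c"])
  expect_false(any(cf$excluded[cf$cell_id != "c"]))
  expect_error(count_foci(tab, "nope"), "not present")
})

test_that("orientation geometry: pole choice, relative coordinates, ambiguity", {
  tab <- data.frame(
    cell_id = c("a", "a", "b", "b", "b"),
    length_um = c(3, 3, 3, 3, 3),
    channel = c("ref", "locus", "ref", "ref", "locus"),
    position_um = c(0.3, 2.1, 1.45, 1.55, 1.0))
  class(tab) <- c("foci_table", "data.frame")
  ot <- orient(tab, "ref")
  # cell a: ref near the 0 end -> that end is the new pole; 2.1/3 -> 0.7
  a_loc <- ot[ot$cell_id == "a" & ot$channel == "locus", ]
  expect_equal(a_loc$rel_pos, 0.7)
  # cell b: ref mean exactly at mid-cell -> ambiguous, excluded
  expect_false("b" %in% ot$cell_id)
  expect_equal(attr(ot, "orientation")$n_ambiguous, 1L)
  expect_error(orient(tab, "missing"), "absent")
})

test_that("re-orienting an oriented population is idempotent", {
  cfg <- sim_config("citrate", 500, seed = 9, channels = citrate_channels)
  ot1 <- orient(sample_population(cfg), "ref")
  ot2 <- orient(ot1, "ref")
  expect_equal(as.data.frame(ot2), as.data.frame(ot1), ignore_attr = TRUE)
  expect_equal(attr(ot2, "orientation")$n_ambiguous, 0L)
})

test_that("segregation curves report per-bin fractions with occupancy flags", {
  # population where every cell has two foci -> fraction 1 in every bin
  n <- 60
  tab <- data.frame(
    cell_id = rep(sprintf("c%02d", 1:n), each = 2),
    length_um = rep(seq(2.05, 4.0, length.out = n), each = 2),
    channel = "locus",
    position_um = rep(c(0.5, 1.5), n))
  class(tab) <- c("foci_table", "data.frame")
  cv <- segregation_curves(tab, "locus", bin_um = 0.2, min_n = 5)
  expect_true(all(cv$f2 == 1))
  expect_true(all(cv$f1 == 0))
  expect_equal(sum(cv$n), n)
  expect_true(all(cv$n[cv$reported] >= 5))
  expect_true(all(cv$bin_hi - cv$bin_lo - 0.2 < 1e-9))
})

test_that("position summaries rank two-focus cells before pooling", {
  # all foci at exactly 0.5 -> degenerate medians and zero IQR
  ot <- tiny_oriented(rep(list(0.5), 5))
  ps <- position_summary(ot, "locus")
  expect_equal(ps$median, 0.5)
  expect_equal(ps$q75 - ps$q25, 0)
  # ranked series: proximal median <= distal median, quartiles ordered
  ot <- tiny_oriented(list(c(0.15, 0.8), c(0.25, 0.7), c(0.2, 0.9)))
  ps <- position_summary(ot, "locus")
  prox <- ps[ps$series == "proximal", ]
  dist <- ps[ps$series == "distal", ]
  expect_equal(prox$median, 0.2)
  expect_equal(dist$median, 0.8)
  expect_true(all(ps$q25 <= ps$median & ps$median <= ps$q75))
})

test_that("the profile switching rule fires on strict majority", {
  # 3 one-focus cells (75%) at 0.1/0.2/0.3 + 1 two-focus cell -> one branch
  ot <- tiny_oriented(list(0.1, 0.2, 0.3, c(0.4, 0.6)))
  pr <- segregation_profile_curve(ot, "locus", bin_um = 2, min_n = 1)
  expect_equal(pr$branch, "one")
  expect_equal(pr$median_lo, 0.2)
  expect_true(is.na(pr$median_hi))
  # exactly 50% one-focus cells -> the two-focus branch (strict inequality)
  ot <- tiny_oriented(list(0.1, 0.2, c(0.3, 0.7), c(0.35, 0.8)))
  pr <- segregation_profile_curve(ot, "locus", bin_um = 2, min_n = 1)
  expect_equal(pr$branch, "two")
  expect_equal(pr$median_lo, 0.325)
  expect_equal(pr$median_hi, 0.75)
})

test_that("interfocal distances use exact pairs and minimal-sum matching", {
  tab <- data.frame(
    cell_id = c("a", "a", "b", "b", "b", "b", "c"),
    length_um = 3,
    channel = c("A", "B", "A", "A", "B", "B", "A"),
    position_um = c(0.5, 1.5, 0.4, 2.0, 0.5, 2.3, 1.0))
  class(tab) <- c("foci_table", "data.frame")
  one <- interfocal_analysis(tab, "A", "B", pairing = "one_one")
  expect_equal(one$distances, 1.0)
  expect_equal(one$n_cells, 1L)
  matched <- interfocal_analysis(tab, "A", "B", pairing = "matched")
  # cell b: minimal-sum matching pairs 0.4-0.5 and 2.0-2.3
  expect_setequal(round(matched$distances, 6), c(1.0, 0.1, 0.3))
  # identical positions are colocalized at distance zero
  tab2 <- data.frame(cell_id = "z", length_um = 3,
                     channel = c("A", "B"), position_um = c(1.2, 1.2))
  class(tab2) <- c("foci_table", "data.frame")
  z <- interfocal_analysis(tab2, "A", "B")
  expect_equal(z$distances, 0)
  expect_equal(z$coloc_fraction, 1)
})

test_that("replisome pairs split at the 0.35 relative-separation rule", {
  tab <- data.frame(
    cell_id = c("a", "a", "b", "b", "c"),
    length_um = c(3, 3, 3, 3, 3),
    channel = "rep",
    position_um = c(1.2, 1.8, 0.6, 2.4, NA))
  class(tab) <- c("foci_table", "data.frame")
  rs <- replisome_summary(tab, "rep", min_n = 1)
  # 0.6/3 = 0.2 separation -> together; 1.8/3 = 0.6 -> apart
  expect_equal(rs$pairs$class[rs$pairs$cell_id == "a"], "together")
  expect_equal(rs$pairs$class[rs$pairs$cell_id == "b"], "apart")
  expect_equal(sum(rs$counts$n0), 1L)
  expect_equal(rs$frac_one_among_positive, 0)
})

test_that("joint patterns count exact focus-count combinations", {
  tab <- data.frame(
    cell_id = c("a", "a", "a", "b", "b", "b", "c"),
    length_um = 3,
    channel = c("ori", "ori", "ter", "ori", "ori", "ter", "ori"),
    position_um = c(0.5, 2.5, 1.4, 0.6, 2.4, 1.5, 1.0))
  class(tab) <- c("foci_table", "data.frame")
  jp <- joint_pattern_fraction(tab, "ori", 2L, "ter", 1L)
  expect_equal(jp$fraction, 1)   # cell c lacks a ter channel entirely
  expect_equal(jp$n_cells, 2L)
})

test_that("the region classifier applies the Ori/Ter evidence rules", {
  mk_curves <- function(max_f2) {
    data.frame(channel = "x", bin_lo = 2, bin_hi = 2.2, bin_mid = 2.1,
               n = 100, f1 = 1 - max_f2, f2 = max_f2, f_gt2 = 0,
               reported = TRUE)
  }
  mk_summary <- function(small_med, prox, dist) {
    rbind(
      data.frame(channel = "x", size_class = "small", stratum = 1L,
                 series = "single", n = 50, q25 = small_med - 0.02,
                 median = small_med, q75 = small_med + 0.02),
      data.frame(channel = "x", size_class = "large", stratum = 2L,
                 series = c("proximal", "distal"), n = 50,
                 q25 = c(prox, dist) - 0.02, median = c(prox, dist),
                 q75 = c(prox, dist) + 0.02))
  }
  expect_equal(classify_region(mk_curves(0.4),
                               mk_summary(0.05, 0.45, 0.55))$call, "Ter")
  expect_equal(classify_region(mk_curves(0.9),
                               mk_summary(0.5, 0.2, 0.8))$call, "Ori")
  expect_equal(classify_region(mk_curves(0.9),
                               mk_summary(0.4, 0.35, 0.65))$call, "Arm")
  # low two-focus fraction alone is not Ter if the locus is not polar
  expect_equal(classify_region(mk_curves(0.4),
                               mk_summary(0.45, 0.45, 0.55))$call, "Arm")
  # missing strata -> uncallable with a reason
  res <- classify_region(mk_curves(0.9), mk_summary(0.4, 0.3, 0.7)[1, ])
  expect_equal(res$call, "uncallable")
  expect_match(res$reason, "large")
})
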