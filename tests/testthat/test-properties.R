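# Property-style checks of the simulator against independent oracles.

test_that("Monte-Carlo two-focus fractions match the age-density quadrature", {
  cfg <- sim_config("citrate", 5000, seed = 31,
                    channels = c(a = "628-R", b = "1,509-R", c = "2,499-R",
                                 d = "2,957-R"),
                    params = noise_off)
  tab <- sample_population(cfg)
  p <- cfg$params
  for (ch in c("a", "b", "c")) {
    lc <- parse_locus(unname(cfg$channels[ch]))
    # with noise off, a cell shows two foci iff the locus is past cohesion
    t_sep <- replication_age(lc, p) + p$t_coh_min
    expected <- 1 - steady_state_age_cdf(max(0, t_sep), p)
    cf <- count_foci(tab, ch)
    obs <- mean(cf$n_foci[!cf$excluded] == 2L)
    se <- sqrt(expected * (1 - expected) / sum(!cf$excluded))
    expect_lt(abs(obs - expected), 3 * se)
  }
  # Ter locus: separation requires the per-cell flag and the late window
  expected <- p$p_ter_sep *
    (1 - steady_state_age_cdf(p$tau_min - p$ter_late_min, p))
  cf <- count_foci(tab, "d")
  obs <- mean(cf$n_foci[!cf$excluded] == 2L)
  se <- sqrt(expected * (1 - expected) / sum(!cf$excluded))
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("unoriented positions are symmetric about mid-cell", {
  cfg <- sim_config("citrate", 10000, seed = 33, channels = c(arm = "1,509-R"))
  tab <- sample_population(cfg)
  rel <- tab$position_um[!is.na(tab$position_um)] /
    tab$length_um[!is.na(tab$position_um)]
  ks <- suppressWarnings(stats::ks.test(rel, 1 - rel))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-focus fractions rise with cell size for every locus", {
  cfg <- sim_config("citrate", 20000, seed = 35,
                    channels = c(a = "628-R", b = "1,509-R", c = "2,957-R"))
  tab <- sample_population(cfg)
  for (ch in names(cfg$channels)) {
    cv <- segregation_curves(tab, ch)
    cv <- cv[cv$reported, ]
    # non-decreasing up to sampling error: consecutive drops must stay
    # within 3 binomial SE of the pooled fraction
    pool <- (cv$f2[-nrow(cv)] * cv$n[-nrow(cv)] + cv$f2[-1] * cv$n[-1]) /
      (cv$n[-nrow(cv)] + cv$n[-1])
    tol <- 3 * sqrt(pmax(pool * (1 - pool), 1e-4) *
                      (1 / cv$n[-nrow(cv)] + 1 / cv$n[-1]))
    expect_true(all(diff(cv$f2) > -tol), label = ch)
    # and the trend over well-occupied bins is upward
    big <- cv$n >= 200
    expect_gt(stats::cor(cv$bin_mid[big], cv$f2[big], method = "spearman"),
              0.8)
  }
})

test_that("opposite-replichore loci colocalize more than same-replichore pairs", {
  cfg <- sim_config("citrate", 4000, seed = 37,
                    channels = c(r327 = "327-R", l488 = "488-L",
                                 r1509 = "1,509-R"))
  tab <- sample_population(cfg)
  inter <- interfocal_analysis(tab, "l488", "r327")   # same offsets, opposite arms
  intra <- interfocal_analysis(tab, "r327", "r1509")  # same arm, different offsets
  expect_lt(inter$mean_um, intra$mean_um)
  expect_gt(inter$coloc_fraction, intra$coloc_fraction)
})

test_that("segregation-curve crossings recover the replication period", {
  offsets <- c(700, 1040, 1380, 1720, 2060)
  chans <- stats::setNames(sprintf("%s-R", formatC(offsets, format = "d",
                                                   big.mark = ",")),
                           paste0("x", offsets))
  cfg <- sim_config("citrate", 20000, seed = 39, channels = chans)
  tab <- sample_population(cfg)
  curves <- lapply(names(chans), function(ch) segregation_curves(tab, ch))
  est <- estimate_c_period(curves, offsets, cfg$params)
  expect_lt(abs(est$C_min - cfg$params$C_min) / cfg$params$C_min, 0.15)
})

test_that("region classification recovers the generating labels for the panel", {
  panel <- pao1_loci()
  chans <- stats::setNames(names(panel), sprintf("ch%02d", seq_along(panel)))
  cfg <- sim_config("citrate", 5000, seed = 41, channels = chans)
  tab <- sample_population(cfg)
  ot <- orient(tab, names(chans)[chans == "3,028-R"])
  p <- cfg$params
  truth <- vapply(panel, function(lc) {
    if (lc$offset_kb <= p$ori_edge_kb) "Ori"
    else if (lc$offset_kb >= p$ter_edge_kb) "Ter"
    else "Arm"
  }, character(1))
  calls <- vapply(names(chans), function(ch) {
    classify_region(segregation_curves(tab, ch), position_summary(ot, ch))$call
  }, character(1))
  expect_gte(sum(calls == unname(truth[chans])), 19L)
})

test_that("oriented summaries stay inside the unit cell", {
  cfg <- sim_config("citrate", 3000, seed = 43, channels = citrate_channels)
  ot <- orient(sample_population(cfg), "ref")
  expect_true(all(ot$rel_pos >= 0 & ot$rel_pos <= 1, na.rm = TRUE))
  for (ch in c("ori", "arm", "dif")) {
    ps <- position_summary(ot, ch)
    expect_true(all(ps$q25 >= 0 & ps$q75 <= 1))
    expect_true(all(ps$q25 <= ps$median & ps$median <= ps$q75))
  }
})

test_that("the switching-rule profile agrees with the size-class summaries", {
  cfg <- sim_config("citrate", 6000, seed = 45, channels = citrate_channels)
  tab <- sample_population(cfg)
  ot <- orient(tab, "ref")
  # large cells of an Ori locus are dominated by two-focus cells: the profile
  # bins inside the large class must take the two-focus branch and agree with
  # the class-level medians to within binning error
  pr <- segregation_profile_curve(ot, "ori")
  ps <- position_summary(ot, "ori")
  lg_bins <- pr[pr$reported & pr$bin_lo >= 3.5, ]
  expect_true(all(lg_bins$branch == "two"))
  prox_class <- ps$median[ps$size_class == "large" & ps$series == "proximal"]
  expect_lt(abs(stats::median(lg_bins$median_lo) - prox_class), 0.05)
  # small cells of a Ter locus: one-focus branch, polar medians
  prd <- segregation_profile_curve(ot, "dif")
  sm_bins <- prd[prd$reported & prd$bin_hi <= 2.8, ]
  expect_true(all(sm_bins$branch == "one"))
  expect_true(all(sm_bins$median_lo < 0.2))
})
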