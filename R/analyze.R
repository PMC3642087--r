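#' Cell-size classes used throughout the analysis
#'
#' Small cells are shorter than `small_max_um`, large cells longer than
#' `large_min_um`, medium cells in between; size-resolved curves use
#' `profile_bin_um` wide bins.
#'
#' @param small_max_um upper bound of the small class (um).
#' @param large_min_um lower bound of the large class (um).
#' @param profile_bin_um bin width for size-resolved curves (um).
#' @return A list of class `size_classes`.
#' @export
size_classes <- function(small_max_um = 2.8, large_min_um = 3.5,
                         profile_bin_um = 0.2) {
  stopifnot(small_max_um < large_min_um, profile_bin_um > 0)
  structure(list(small_max_um = small_max_um, large_min_um = large_min_um,
                 profile_bin_um = profile_bin_um),
            class = "size_classes")
}

size_class_of <- function(length_um, classes) {
  ifelse(length_um < classes$small_max_um, "small",
         ifelse(length_um > classes$large_min_um, "large", "medium"))
}

# Per-cell view of one channel: counts and position lists. Cells whose row
# has position_um = NA are zero-focus cells.
channel_cells <- function(tab, channel) {
  stopifnot(is.data.frame(tab))
  sub <- tab[tab$channel == channel, , drop = FALSE]
  if (!nrow(sub)) stop("channel '", channel, "' not present in the table")
  ids <- unique(sub$cell_id)
  pos <- split(sub$position_um, factor(sub$cell_id, levels = ids))
  pos <- lapply(pos, function(x) x[!is.na(x)])
  len <- vapply(split(sub$length_um, factor(sub$cell_id, levels = ids)),
                `[`, numeric(1), 1)
  data.frame(cell_id = ids, length_um = unname(len),
             n_foci = vapply(pos, length, integer(1)),
             positions = I(unname(pos)), stringsAsFactors = FALSE)
}

#' Count observed foci per cell in one channel
#'
#' Zero-focus cells are flagged `excluded` (they are removed from all focus
#' fraction statistics downstream, following standard practice in foci
#' counting).
#'
#' @param tab a foci table ([sample_population()] or [read_cell_table()]).
#' @param channel channel name.
#' @return A `data.frame` with `cell_id`, `length_um`, `n_foci`, `excluded`.
#' @export
count_foci <- function(tab, channel) {
  cc <- channel_cells(tab, channel)
  data.frame(cell_id = cc$cell_id, length_um = cc$length_um,
             n_foci = cc$n_foci, excluded = cc$n_foci == 0L,
             stringsAsFactors = FALSE)
}

#' Orient cells using a terminus-proximal reference channel
#'
#' The new pole is identified as the cell end closer to the mean position of
#' the reference-channel foci (a locus near the terminus stays close to the
#' new pole for most of the cycle). Cells without reference foci are dropped;
#' cells whose reference mean lies within `ambiguity` relative units of
#' mid-cell are flagged ambiguous and excluded from oriented statistics. All
#' channels are then re-expressed in relative coordinates with 0 at the new
#' pole.
#'
#' @param tab a foci table.
#' @param ref_channel name of the reference channel.
#' @param ambiguity half-width of the mid-cell exclusion zone (relative
#'   units).
#' @return An oriented foci table (class `oriented_foci`): the input rows for
#'   retained cells plus `rel_pos` (relative position from the new pole) and
#'   `inferred_new_pole_end`. Orientation provenance (reference channel, rule,
#'   ambiguity threshold, exclusion counts) is stored in
#'   `attr(, "orientation")`.
#' @export
orient <- function(tab, ref_channel, ambiguity = 0.05) {
  if (!ref_channel %in% tab$channel) {
    stop("reference channel '", ref_channel, "' absent from the table")
  }
  ref <- channel_cells(tab, ref_channel)
  ref <- ref[ref$n_foci > 0L, , drop = FALSE]
  m_rel <- vapply(seq_len(nrow(ref)),
                  function(i) mean(ref$positions[[i]]) / ref$length_um[i],
                  numeric(1))
  ambiguous <- abs(m_rel - 0.5) <= ambiguity
  keep <- ref$cell_id[!ambiguous]
  new_pole_end <- ifelse(m_rel[!ambiguous] < 0.5, 0L, 1L)
  names(new_pole_end) <- keep
  out <- tab[tab$cell_id %in% keep, , drop = FALSE]
  npe <- new_pole_end[out$cell_id]
  out$rel_pos <- ifelse(npe == 0L, out$position_um / out$length_um,
                        1 - out$position_um / out$length_um)
  out$inferred_new_pole_end <- unname(npe)
  rownames(out) <- NULL
  structure(out,
            channels = attr(tab, "channels"),
            orientation = list(ref_channel = ref_channel,
                               rule = "mean of reference foci",
                               ambiguity = ambiguity,
                               n_input_cells = length(unique(tab$cell_id)),
                               n_no_ref = length(unique(tab$cell_id)) - nrow(ref),
                               n_ambiguous = sum(ambiguous)),
            class = c("oriented_foci", "foci_table", "data.frame"))
}

bin_breaks <- function(length_um, bin_um) {
  lo <- floor(min(length_um) / bin_um + 1e-9) * bin_um
  hi <- ceiling(max(length_um) / bin_um - 1e-9) * bin_um
  if (hi <= lo) hi <- lo + bin_um
  seq(lo, hi + bin_um / 2, by = bin_um)
}

#' Size-binned segregation curve (focus-count fractions by cell size)
#'
#' Among cells with at least one visible focus, the fractions of one-, two-
#' and more-than-two-focus cells in each cell-size bin. Bins with fewer than
#' `min_n` contributing cells are flagged `reported = FALSE` rather than
#' silently dropped.
#'
#' @inheritParams count_foci
#' @param bin_um size-bin width (um).
#' @param min_n minimum bin occupancy for a reported fraction.
#' @return A `data.frame` with `channel`, `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `f1`, `f2`, `f_gt2`, `reported`.
#' @export
segregation_curves <- function(tab, channel, bin_um = 0.2, min_n = 20) {
  cc <- channel_cells(tab, channel)
  cc <- cc[cc$n_foci > 0L, , drop = FALSE]
  if (!nrow(cc)) stop("no cells with visible foci in channel '", channel, "'")
  br <- bin_breaks(cc$length_um, bin_um)
  idx <- findInterval(cc$length_um, br, rightmost.closed = TRUE)
  res <- lapply(sort(unique(idx)), function(b) {
    n <- cc$n_foci[idx == b]
    data.frame(channel = channel, bin_lo = br[b], bin_hi = br[b + 1],
               bin_mid = (br[b] + br[b + 1]) / 2, n = length(n),
               f1 = mean(n == 1L), f2 = mean(n == 2L), f_gt2 = mean(n > 2L),
               reported = length(n) >= min_n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Median and quartile focus positions by size class and focus count
#'
#' For each size class and focus-count stratum, the median and 25th/75th
#' percentile relative positions (0 = new pole). In two-focus cells the foci
#' are ranked per cell (pole-proximal vs pole-distal) before pooling, so the
#' two reported series are order statistics, not raw pools.
#'
#' @param oriented an oriented foci table from [orient()].
#' @param channel channel name.
#' @param classes a [size_classes()].
#' @return A `data.frame` with `channel`, `size_class`, `stratum` (1 or 2),
#'   `series` (`"single"`, `"proximal"`, `"distal"`), `n`, `q25`, `median`,
#'   `q75`.
#' @export
position_summary <- function(oriented, channel, classes = size_classes()) {
  stopifnot(inherits(oriented, "oriented_foci"))
  sub <- oriented[oriented$channel == channel & !is.na(oriented$position_um), ,
                  drop = FALSE]
  ids <- unique(sub$cell_id)
  rel <- split(sub$rel_pos, factor(sub$cell_id, levels = ids))
  len <- vapply(split(sub$length_um, factor(sub$cell_id, levels = ids)),
                `[`, numeric(1), 1)
  k <- vapply(rel, length, integer(1))
  cls <- size_class_of(len, classes)
  rows <- list()
  for (sc in c("small", "medium", "large")) {
    one <- unlist(rel[k == 1L & cls == sc], use.names = FALSE)
    if (length(one)) {
      q <- stats::quantile(one, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = channel, size_class = sc, stratum = 1L, series = "single",
        n = length(one), q25 = q[1], median = q[2], q75 = q[3],
        stringsAsFactors = FALSE)
    }
    two <- rel[k == 2L & cls == sc]
    if (length(two)) {
      prox <- vapply(two, min, numeric(1))
      dist <- vapply(two, max, numeric(1))
      for (ser in c("proximal", "distal")) {
        v <- if (ser == "proximal") prox else dist
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          channel = channel, size_class = sc, stratum = 2L, series = ser,
          n = length(v), q25 = q[1], median = q[2], q75 = q[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(channel = character(0), size_class = character(0),
                      stratum = integer(0), series = character(0),
                      n = integer(0), q25 = numeric(0), median = numeric(0),
                      q75 = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Size-resolved median-position profile with the majority switching rule
#'
#' For each size bin: when one-focus cells are the majority (strictly more
#' than 50% of cells with one or two foci), the median position of the single
#' focus is reported; otherwise the medians of the pole-proximal and
#' pole-distal foci of two-focus cells are reported. The branch taken is
#' recorded per bin.
#'
#' @inheritParams position_summary
#' @inheritParams segregation_curves
#' @return A `data.frame` with `channel`, `bin_lo`, `bin_hi`, `bin_mid`,
#'   `n1`, `n2`, `branch` (`"one"`/`"two"`), `median_lo`, `median_hi`
#'   (`median_hi` is `NA` on the one-focus branch), `reported`.
#' @export
segregation_profile_curve <- function(oriented, channel, bin_um = 0.2,
                                      min_n = 20) {
  stopifnot(inherits(oriented, "oriented_foci"))
  sub <- oriented[oriented$channel == channel & !is.na(oriented$position_um), ,
                  drop = FALSE]
  ids <- unique(sub$cell_id)
  rel <- split(sub$rel_pos, factor(sub$cell_id, levels = ids))
  len <- vapply(split(sub$length_um, factor(sub$cell_id, levels = ids)),
                `[`, numeric(1), 1)
  k <- vapply(rel, length, integer(1))
  use <- k %in% c(1L, 2L)
  rel <- rel[use]; len <- len[use]; k <- k[use]
  br <- bin_breaks(len, bin_um)
  idx <- findInterval(len, br, rightmost.closed = TRUE)
  res <- lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    n1 <- sum(k[sel] == 1L); n2 <- sum(k[sel] == 2L)
    one_branch <- n1 > (n1 + n2) / 2
    if (one_branch) {
      med_lo <- stats::median(unlist(rel[sel][k[sel] == 1L], use.names = FALSE))
      med_hi <- NA_real_
    } else {
      two <- rel[sel][k[sel] == 2L]
      med_lo <- stats::median(vapply(two, min, numeric(1)))
      med_hi <- stats::median(vapply(two, max, numeric(1)))
    }
    data.frame(channel = channel, bin_lo = br[b], bin_hi = br[b + 1],
               bin_mid = (br[b] + br[b + 1]) / 2, n1 = n1, n2 = n2,
               branch = if (one_branch) "one" else "two",
               median_lo = med_lo, median_hi = med_hi,
               reported = (n1 + n2) >= min_n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Interfocal distances between two locus channels
#'
#' Distances between the foci of two channels in the same cells, restricted
#' to cells with equal focus counts in both channels. With
#' `pairing = "one_one"` (default) only one-focus cells contribute, each with
#' its single pairwise distance. With `pairing = "matched"` two-focus cells
#' also contribute: the two foci of channel A are matched to the two of
#' channel B by minimal-sum matching and both matched distances are pooled.
#'
#' @inheritParams count_foci
#' @param chanA,chanB the two channel names.
#' @param pairing `"one_one"` or `"matched"`.
#' @param coloc_um distance threshold (um) below which a pair is counted as
#'   colocalized.
#' @return A list with `distances` (um), `mean_um`, `coloc_fraction`,
#'   `n_cells`, `pairing`, `coloc_um`.
#' @export
interfocal_analysis <- function(tab, chanA, chanB,
                                pairing = c("one_one", "matched"),
                                coloc_um = 0.3) {
  pairing <- match.arg(pairing)
  a <- channel_cells(tab, chanA)
  b <- channel_cells(tab, chanB)
  common <- intersect(a$cell_id, b$cell_id)
  a <- a[match(common, a$cell_id), ]; b <- b[match(common, b$cell_id), ]
  same <- a$n_foci == b$n_foci & a$n_foci > 0L
  max_k <- if (pairing == "one_one") 1L else 2L
  dists <- numeric(0); n_cells <- 0L
  for (i in which(same & a$n_foci <= max_k)) {
    pa <- a$positions[[i]]; pb <- b$positions[[i]]
    if (length(pa) == 1L) {
      dists <- c(dists, abs(pa - pb))
    } else {
      parallel <- abs(pa[1] - pb[1]) + abs(pa[2] - pb[2])
      crossed <- abs(pa[1] - pb[2]) + abs(pa[2] - pb[1])
      dists <- c(dists, if (parallel <= crossed) {
        c(abs(pa[1] - pb[1]), abs(pa[2] - pb[2]))
      } else {
        c(abs(pa[1] - pb[2]), abs(pa[2] - pb[1]))
      })
    }
    n_cells <- n_cells + 1L
  }
  list(distances = dists, mean_um = mean(dists),
       coloc_fraction = mean(dists < coloc_um),
       n_cells = n_cells, pairing = pairing, coloc_um = coloc_um)
}

#' Replisome focus summaries: counts by size, positions, pair splitting
#'
#' The replisome analysis runs unoriented: one-focus positions are reported
#' both as raw relative positions (from the arbitrary recorded end) and
#' folded about mid-cell; two-focus pairs are classified `"together"` when
#' their relative separation is below `split_threshold` and `"apart"`
#' otherwise.
#'
#' @inheritParams segregation_curves
#' @param split_threshold relative-separation threshold of the two-focus
#'   split classification.
#' @return A list with `counts` (per-bin histogram of 0/1/2/3+ focus cells),
#'   `one_focus` (per-cell relative positions, raw and folded),
#'   `pairs` (per-cell relative separations and classes), and
#'   `frac_one_among_positive`.
#' @export
replisome_summary <- function(tab, channel, bin_um = 0.2,
                              split_threshold = 0.35, min_n = 20) {
  cc <- channel_cells(tab, channel)
  br <- bin_breaks(cc$length_um, bin_um)
  idx <- findInterval(cc$length_um, br, rightmost.closed = TRUE)
  counts <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    n <- cc$n_foci[idx == b]
    data.frame(bin_lo = br[b], bin_hi = br[b + 1],
               bin_mid = (br[b] + br[b + 1]) / 2, n = length(n),
               n0 = sum(n == 0L), n1 = sum(n == 1L), n2 = sum(n == 2L),
               n3plus = sum(n >= 3L), reported = length(n) >= min_n)
  }))
  one <- cc[cc$n_foci == 1L, , drop = FALSE]
  one_rel <- vapply(seq_len(nrow(one)),
                    function(i) one$positions[[i]] / one$length_um[i],
                    numeric(1))
  one_focus <- data.frame(cell_id = one$cell_id, length_um = one$length_um,
                          rel = one_rel, rel_mid = abs(one_rel - 0.5),
                          stringsAsFactors = FALSE)
  two <- cc[cc$n_foci == 2L, , drop = FALSE]
  sep_rel <- vapply(seq_len(nrow(two)), function(i) {
    abs(diff(two$positions[[i]])) / two$length_um[i]
  }, numeric(1))
  pairs <- data.frame(cell_id = two$cell_id, length_um = two$length_um,
                      sep_rel = sep_rel,
                      class = ifelse(sep_rel < split_threshold,
                                     "together", "apart"),
                      stringsAsFactors = FALSE)
  positive <- cc$n_foci > 0L
  list(counts = counts, one_focus = one_focus, pairs = pairs,
       frac_one_among_positive = mean(cc$n_foci[positive] == 1L),
       split_threshold = split_threshold)
}

#' Fraction of cells matching an exact joint focus-count pattern
#'
#' Fraction of cells showing exactly `countA` foci in `chanA` and exactly
#' `countB` foci in `chanB`. Unless a zero count is requested, the
#' denominator is restricted to cells with at least one visible focus in each
#' channel (the usual exclusion of no-focus cells).
#'
#' @inheritParams interfocal_analysis
#' @param countA,countB requested exact counts.
#' @return A list with `fraction`, `n_matching`, `n_cells`.
#' @export
joint_pattern_fraction <- function(tab, chanA, countA, chanB, countB) {
  a <- channel_cells(tab, chanA)
  b <- channel_cells(tab, chanB)
  common <- intersect(a$cell_id, b$cell_id)
  na <- a$n_foci[match(common, a$cell_id)]
  nb <- b$n_foci[match(common, b$cell_id)]
  if (countA > 0L && countB > 0L) {
    den <- na >= 1L & nb >= 1L
  } else {
    den <- rep(TRUE, length(na))
  }
  hit <- den & na == countA & nb == countB
  list(fraction = sum(hit) / sum(den), n_matching = sum(hit),
       n_cells = sum(den))
}

#' Ratio between two joint focus-count patterns
#'
#' Ratio of the fractions of two exact joint patterns over the same
#' denominator, e.g. (4 Ori, 1 Ter) versus (4 Ori, 2 Ter).
#'
#' @inheritParams joint_pattern_fraction
#' @param pattern1,pattern2 integer vectors `c(countA, countB)`.
#' @return A list with `ratio` and the two component results.
#' @export
joint_pattern_ratio <- function(tab, chanA, chanB, pattern1, pattern2) {
  f1 <- joint_pattern_fraction(tab, chanA, pattern1[1], chanB, pattern1[2])
  f2 <- joint_pattern_fraction(tab, chanA, pattern2[1], chanB, pattern2[2])
  list(ratio = f1$fraction / f2$fraction, pattern1 = f1, pattern2 = f2)
}

#' Default thresholds for the Ori/Arm/Ter region classifier
#' @param ter_max_f2 maximum two-focus fraction compatible with Ter.
#' @param ter_small_median maximum small-cell one-focus median compatible
#'   with Ter (relative units).
#' @param ori_target,ori_tol large-cell two-focus medians must lie within
#'   `ori_tol` of `ori_target` and `1 - ori_target` for an Ori call.
#' @param min_n minimum stratum size for the evidence to be usable.
#' @return A named list.
#' @export
region_thresholds <- function(ter_max_f2 = 0.5, ter_small_median = 0.2,
                              ori_target = 0.2, ori_tol = 0.06, min_n = 10) {
  list(ter_max_f2 = ter_max_f2, ter_small_median = ter_small_median,
       ori_target = ori_target, ori_tol = ori_tol, min_n = min_n)
}

#' Classify a locus into the Ori, Arm or Ter region from its statistics
#'
#' Applies the descriptive rules that define the two distinctive chromosomal
#' regions: a locus is `Ter` when its two-focus fraction never exceeds 50% in
#' any reported size bin and its single focus sits within 0.2 of the new pole
#' in small cells; it is `Ori` when the two-focus medians in large cells lie
#' at 0.2/0.8 (within tolerance); otherwise it is `Arm`. Each call carries
#' the evidence values used; loci with insufficient cells in a required
#' stratum are returned `uncallable` with a reason.
#'
#' @param curves output of [segregation_curves()] for the locus.
#' @param summary output of [position_summary()] for the locus.
#' @param thresholds a [region_thresholds()] list.
#' @return A list with `call` (`"Ori"`, `"Arm"`, `"Ter"` or `"uncallable"`),
#'   `evidence` (named numerics) and `reason` (for uncallable loci).
#' @export
classify_region <- function(curves, summary, thresholds = region_thresholds()) {
  rep_bins <- curves[curves$reported, , drop = FALSE]
  if (!nrow(rep_bins)) {
    return(list(call = "uncallable", evidence = NULL,
                reason = "no size bin reaches the minimum occupancy"))
  }
  max_f2 <- max(rep_bins$f2)
  sm1 <- summary[summary$size_class == "small" & summary$stratum == 1L, ,
                 drop = FALSE]
  lg2 <- summary[summary$size_class == "large" & summary$stratum == 2L, ,
                 drop = FALSE]
  small_median <- if (nrow(sm1) && sm1$n[1] >= thresholds$min_n) {
    sm1$median[1]
  } else NA_real_
  prox <- lg2$median[lg2$series == "proximal"]
  dist <- lg2$median[lg2$series == "distal"]
  n_lg2 <- if (nrow(lg2)) lg2$n[1] else 0L
  ev <- c(max_two_focus_fraction = max_f2,
          small_single_median = small_median,
          large_proximal_median = if (length(prox)) prox else NA_real_,
          large_distal_median = if (length(dist)) dist else NA_real_)
  if (max_f2 <= thresholds$ter_max_f2) {
    if (is.na(small_median)) {
      return(list(call = "uncallable", evidence = ev,
                  reason = "too few small one-focus cells to test the Ter rule"))
    }
    if (small_median <= thresholds$ter_small_median) {
      return(list(call = "Ter", evidence = ev, reason = NULL))
    }
  }
  if (!length(prox) || !length(dist) || n_lg2 < thresholds$min_n) {
    return(list(call = "uncallable", evidence = ev,
                reason = "too few large two-focus cells to test the Ori rule"))
  }
  ori <- abs(prox - thresholds$ori_target) <= thresholds$ori_tol &&
    abs(dist - (1 - thresholds$ori_target)) <= thresholds$ori_tol
  list(call = if (ori) "Ori" else "Arm", evidence = ev, reason = NULL)
}

#' Estimate the replication (C) period from segregation-curve crossings
#'
#' For each locus, the cell size at which the two-focus fraction crosses 50%
#' is found by linear interpolation on its segregation curve; the crossing
#' size is converted to a cell age through the growth law
#' `age = tau * log2(L / L0)`, and a straight-line fit of crossing age
#' against chromosomal offset recovers the fork speed, hence the C period
#' (`slope * half_genome_kb`).
#'
#' Because the two copies only become separable once their physical distance
#' exceeds the optical merge distance, the apparent crossing is delayed by an
#' offset-dependent optical lag: copies of terminus-ward loci separate more
#' slowly (their final positions are closer together), so their pairs take
#' longer to exceed `d_res_um`. The estimator removes this lag using the
#' calibrated observation model (`optical_correction = TRUE`, the default):
#' the lag is `d_res_um * seg_dur_min / (separation at the crossing size)`.
#'
#' @param curves_list list of [segregation_curves()] outputs, one per locus.
#' @param offsets_kb numeric vector of the loci's offsets (kb), same order.
#' @param params the [choreo_params()] describing the growth law and
#'   observation model.
#' @param optical_correction subtract the model-based optical resolution lag
#'   from each crossing age before fitting.
#' @return A list with `C_min` (estimated C period), `crossings`
#'   (`data.frame` of offset, crossing size and age) and `fit` (the `lm`).
#' @export
estimate_c_period <- function(curves_list, offsets_kb, params,
                              optical_correction = TRUE) {
  stopifnot(length(curves_list) == length(offsets_kb))
  cross <- vapply(curves_list, function(cv) {
    cv <- cv[cv$reported, , drop = FALSE]
    above <- cv$f2 >= 0.5
    if (!any(above) || all(above)) return(NA_real_)
    i <- which(above)[1]
    if (i == 1L) return(cv$bin_mid[1])
    x0 <- cv$bin_mid[i - 1]; x1 <- cv$bin_mid[i]
    y0 <- cv$f2[i - 1]; y1 <- cv$f2[i]
    x0 + (0.5 - y0) / (y1 - y0) * (x1 - x0)
  }, numeric(1))
  ok <- !is.na(cross)
  if (sum(ok) < 2L) stop("fewer than two loci with a 50% crossing")
  age <- params$tau_min * log2(cross[ok] / params$L0_um)
  if (optical_correction) {
    lag <- vapply(seq_along(offsets_kb)[ok], function(i) {
      fp <- final_positions(locus_spec(offsets_kb[i], "R",
                                       half_genome_kb = params$half_genome_kb),
                            params)
      sep_um <- (fp["old"] - fp["new"]) * cross[i]
      if (sep_um <= params$d_res_um) return(NA_real_)
      params$d_res_um * params$seg_dur_min / sep_um
    }, numeric(1))
    age <- age - lag
  }
  fit <- stats::lm(age ~ offset, data.frame(age = age, offset = offsets_kb[ok]))
  list(C_min = unname(stats::coef(fit)[2]) * params$half_genome_kb,
       crossings = data.frame(offset_kb = offsets_kb[ok],
                              crossing_um = cross[ok],
                              crossing_age_min = age),
       fit = fit)
}
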