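#' Configure a simulated snapshot experiment
#'
#' A simulation configuration bundles the growth-condition mode, the number of
#' cells, the master seed, the fluorescent channels (each tagging one
#' chromosomal locus, or the replisome) and any parameter overrides.
#'
#' @param mode `"citrate"`, `"glucose_caa"` or `"par_null"` (the
#'   partition-defective, disorganized mode).
#' @param n_cells number of cells to sample (>= 1).
#' @param seed integer master seed; every random draw descends from it.
#' @param channels named character vector mapping channel names to locus
#'   labels (see [parse_locus()]) or the special value `"REPLISOME"`. Unnamed
#'   entries are named after themselves.
#' @param params optional [choreo_params()] overrides, as a named list.
#' @param keep_truth keep hidden ground-truth columns (`age_min`,
#'   `new_pole_end`, `true_count`) in the output for testing.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config("citrate", 100, seed = 1, channels = c(ori = "82-R"))
#' @export
sim_config <- function(mode = c("citrate", "glucose_caa", "par_null"),
                       n_cells, seed,
                       channels = c("82-R", "3,090-L"),
                       params = list(), keep_truth = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(names(channels))) names(channels) <- channels
  names(channels)[names(channels) == ""] <-
    channels[names(channels) == ""]
  if (anyDuplicated(names(channels))) stop("channel names must be unique")
  base_mode <- if (mode == "glucose_caa") "glucose_caa" else "citrate"
  p <- do.call(choreo_params, c(list(mode = base_mode), params))
  structure(
    list(mode = mode, n_cells = as.integer(n_cells), seed = as.integer(seed),
         channels = channels, params = p, keep_truth = isTRUE(keep_truth)),
    class = "sim_config"
  )
}

#' Observation model: from true focus positions to reported foci
#'
#' Applies, in order: per-focus detection (`p_det`), Gaussian axial
#' localization noise (`sigma_pos_um`), sub-resolution merging (surviving foci
#' are single-linkage clustered at `d_res_um` and each cluster reported at its
#' centroid), whole-cell detection failure (`p_cellfail`), clipping to
#' `[0, length_um]`, and reporting from a randomly chosen cell end so that
#' polarity is hidden.
#'
#' @param true_rel true focus positions in relative coordinates
#'   (0 = new pole).
#' @param length_um cell length (um).
#' @param params a [choreo_params()].
#' @param flip logical; if `TRUE` positions are reported from the old-pole
#'   end. The default `NULL` draws the reporting end at random; the simulator
#'   passes one per-cell value so all channels share a frame.
#' @return Numeric vector of observed axial positions (um), possibly empty.
#' @export
observe <- function(true_rel, length_um, params, flip = NULL) {
  stopifnot(all(true_rel >= 0), all(true_rel <= 1))
  if (is.null(flip)) flip <- stats::runif(1) < 0.5
  pos <- true_rel[stats::runif(length(true_rel)) < params$p_det] * length_um
  if (length(pos) && params$sigma_pos_um > 0) {
    pos <- pos + stats::rnorm(length(pos), 0, params$sigma_pos_um)
  }
  pos <- merge_foci(pos, params$d_res_um)
  if (stats::runif(1) < params$p_cellfail) pos <- numeric(0)
  pos <- pmin(length_um, pmax(0, pos))
  if (flip) pos <- length_um - pos
  sort(pos)
}

# Single-linkage clustering on a line: sort, cut at gaps > d_res, report
# cluster centroids. d_res = 0 merges only exactly coincident foci.
merge_foci <- function(pos, d_res) {
  if (length(pos) <= 1L) return(pos)
  pos <- sort(pos)
  grp <- cumsum(c(1, diff(pos) > d_res))
  as.numeric(tapply(pos, grp, mean))
}

#' True replisome focus positions at a given cell age
#'
#' In the single-round (`citrate`) condition the two forks travel together as
#' one focus at mid-cell throughout the replication window
#' `[max(0, a_init), a_init + C]`; with probability `p_fork_split` they are
#' transiently resolved as two nearby foci (relative separation drawn in
#' `[fork_split_min, fork_split_max]`, below the 0.35 "together" threshold).
#' Cells within `next_round_min` of division additionally show the next
#' round's replisomes at the `p_ori`/`1 - p_ori` positions. In the
#' overlapping-rounds (`glucose_caa`) condition, cells past second initiation
#' (`a2_init_min`) show the two quarter-position replisome pairs with
#' probability `p_rep2_two`, otherwise a single merged focus at mid-cell.
#'
#' @param age cell age (min).
#' @param length_um cell length (um); unused by the position model itself but
#'   part of the channel contract.
#' @param mode `"citrate"` or `"glucose_caa"`.
#' @param params a [choreo_params()].
#' @return Numeric vector of true relative coordinates (possibly empty).
#' @export
replisome_channel <- function(age, length_um, mode = c("citrate", "glucose_caa"),
                              params) {
  mode <- match.arg(mode)
  active_lo <- max(0, params$a_init_min)
  active_hi <- params$a_init_min + params$C_min
  one_round <- function() {
    if (age >= active_lo && age <= active_hi) {
      if (stats::runif(1) < params$p_fork_split) {
        sep <- stats::runif(1, params$fork_split_min, params$fork_split_max)
        c(0.5 - sep / 2, 0.5 + sep / 2)
      } else 0.5
    } else numeric(0)
  }
  if (mode == "citrate") {
    pos <- one_round()
    if (age >= params$tau_min - params$next_round_min) {
      pos <- c(pos, params$p_ori, 1 - params$p_ori)
    }
    return(pos)
  }
  # glucose_caa: one round finishing at mid-cell, then two rounds at quarters
  if (age < params$a2_init_min) {
    one_round()
  } else if (stats::runif(1) < params$p_rep2_two) {
    c(0.25, 0.75)
  } else {
    0.5
  }
}

#' True locus copy positions under overlapping replication rounds
#'
#' Phenomenological two-generation schedule for the rich (`glucose_caa`)
#' condition. The current generation's copies follow [locus_position()]
#' (which, with initiation in the mother, has Ori-region loci already
#' segregated at birth). After the second-round replication of an Ori-region
#' locus (`a2_init_min + C * offset / half_genome + t_coh`), each of its two
#' copies duplicates in place and the four copies segregate within their half
#' cells toward the 0.1/0.4 and 0.6/0.9 positions. Arm loci never reach their
#' second-round replication before division and so cap at two copies; Ter
#' loci remain one cohesive mid-cell position, separating (about mid-cell by
#' `ter_sep_offset`) in cells past second initiation carrying the per-cell
#' separation flag.
#'
#' @inheritParams locus_position
#' @return A list with `pos` (1 to 4 relative coordinates) and `state`.
#' @export
overlapping_rounds_schedule <- function(locus, age, params, ter_sep = FALSE) {
  off <- if (is_locus_spec(locus)) locus$offset_kb else as.numeric(locus)
  is_ter <- off >= params$ter_edge_kb
  if (is_ter) {
    if (isTRUE(ter_sep) && age >= params$a2_init_min) {
      d <- params$ter_sep_offset
      return(list(pos = c(0.5 - d, 0.5 + d), state = "SEGREGATED"))
    }
    return(locus_position(locus, age, params, ter_sep = FALSE))
  }
  base <- locus_position(locus, age, params, ter_sep = FALSE)
  if (off > params$ori_edge_kb) return(base)  # arm loci cap at 2 copies
  t_rep2 <- params$a2_init_min + params$C_min * off / params$half_genome_kb
  if (age <= t_rep2 + params$t_coh_min) return(base)
  f <- min(1, (age - t_rep2 - params$t_coh_min) / params$seg_dur_min)
  lo <- base$pos[1]; hi <- base$pos[length(base$pos)]
  # each copy re-segregates within its half cell: 0.2 -> 0.1/0.4, 0.8 -> 0.6/0.9
  pos <- c(lo + f * (c(lo / 2, 0.5 - lo / 2) - lo),
           hi + f * (c(0.5 + (1 - hi) / 2, 1 - (1 - hi) / 2) - hi))
  list(pos = sort(pos), state = "SEGREGATED")
}

#' Sample a steady-state snapshot population of cells with observed foci
#'
#' Draws `n_cells` from the steady-state exponential age distribution, grows
#' each cell as `L = L0 * 2^(age/tau)` with lognormal newborn-length noise,
#' places every channel's true foci according to the mode's choreography, and
#' passes them through the [observe()] model. The result is an unoriented
#' foci table of the kind exported by cell-segmentation tools, with hidden
#' ground truth attached when `keep_truth` is set.
#'
#' Reproducibility: one master seed; per-cell substreams are keyed by cell
#' index, so adding or removing channels does not perturb other cells' draws.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with one row per observed focus (cells with zero
#'   observed foci in a channel contribute one row with `position_um = NA`):
#'   columns `cell_id`, `length_um`, `channel`, `position_um`, plus truth
#'   columns `age_min`, `new_pole_end` (0 if the new pole is the coordinate
#'   origin, 1 otherwise) and `true_count` when requested. Channel
#'   declarations are kept in `attr(, "channels")`.
#' @examples
#' cfg <- sim_config("citrate", 50, seed = 1,
#'                   channels = c(ori = "82-R", rep = "REPLISOME"))
#' tab <- sample_population(cfg)
#' head(tab)
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode == "par_null") return(par_null_population(config))
  p <- config$params
  chans <- config$channels
  loci <- lapply(chans, function(lb) {
    if (identical(lb, "REPLISOME")) "REPLISOME"
    else parse_locus(lb, half_genome_kb = p$half_genome_kb)
  })
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, config$n_cells)
  sdlog <- sqrt(log(1 + p$len_cv^2))
  meanlog <- log(p$L0_um) - sdlog^2 / 2
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(cell_seeds[i])
    age <- sample_steady_state_age(stats::runif(1), p)
    L0 <- stats::rlnorm(1, meanlog, sdlog)
    len <- L0 * 2^(age / p$tau_min)
    flip <- stats::runif(1) < 0.5
    ter_sep <- stats::runif(1) < (
      if (config$mode == "glucose_caa") p$p_ter_sep_rich else p$p_ter_sep)
    ch_name <- character(0); ch_pos <- numeric(0); ch_tc <- integer(0)
    for (j in seq_along(loci)) {
      lc <- loci[[j]]
      true_rel <- if (identical(lc, "REPLISOME")) {
        replisome_channel(age, len, mode = config$mode, params = p)
      } else if (config$mode == "glucose_caa") {
        overlapping_rounds_schedule(lc, age, p, ter_sep = ter_sep)$pos
      } else {
        locus_position(lc, age, p, ter_sep = ter_sep)$pos
      }
      obs <- observe(true_rel, len, p, flip = flip)
      k <- length(obs)
      if (k == 0L) {
        ch_name <- c(ch_name, names(chans)[j]); ch_pos <- c(ch_pos, NA_real_)
        ch_tc <- c(ch_tc, length(true_rel))
      } else {
        ch_name <- c(ch_name, rep(names(chans)[j], k)); ch_pos <- c(ch_pos, obs)
        ch_tc <- c(ch_tc, rep(length(true_rel), k))
      }
    }
    out[[i]] <- list(cell_id = sprintf("cell%05d", i), length_um = len,
                     channel = ch_name, position_um = ch_pos,
                     age_min = age, new_pole_end = as.integer(flip),
                     true_count = ch_tc)
  }
  nper <- vapply(out, function(x) length(x$channel), integer(1))
  tab <- data.frame(
    cell_id = rep(vapply(out, `[[`, character(1), "cell_id"), nper),
    length_um = rep(vapply(out, `[[`, numeric(1), "length_um"), nper),
    channel = unlist(lapply(out, `[[`, "channel")),
    position_um = unlist(lapply(out, `[[`, "position_um")),
    stringsAsFactors = FALSE
  )
  if (config$keep_truth) {
    tab$age_min <- rep(vapply(out, `[[`, numeric(1), "age_min"), nper)
    tab$new_pole_end <- rep(vapply(out, `[[`, integer(1), "new_pole_end"), nper)
    tab$true_count <- unlist(lapply(out, `[[`, "true_count"))
  }
  structure(tab, channels = chans, mode = config$mode, seed = config$seed,
            class = c("foci_table", "data.frame"))
}

#' Sample a disorganized (partition-defective) population
#'
#' Descriptive model of a ParABS-null population: per-channel focus counts are
#' drawn from the categorical distribution `par_null_count_probs` (defaults
#' put more than half the mass on zero foci, matching the prevalence of cells
#' without visible foci in such mutants) and positions are uniform on
#' `[0.05, 0.95]` of the cell, with no polarity structure. Lengths are drawn
#' from the same steady-state growth model as the wild type.
#'
#' @param config a [sim_config()] with `mode = "par_null"`.
#' @return A foci table as in [sample_population()]; `new_pole_end` is `NA`
#'   (the mode has no polarity) and `true_count` is the drawn count.
#' @export
par_null_population <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$mode == "par_null")
  p <- config$params
  probs <- p$par_null_count_probs
  counts_support <- as.integer(names(probs))
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, config$n_cells)
  sdlog <- sqrt(log(1 + p$len_cv^2))
  meanlog <- log(p$L0_um) - sdlog^2 / 2
  chans <- config$channels
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(cell_seeds[i])
    age <- sample_steady_state_age(stats::runif(1), p)
    len <- stats::rlnorm(1, meanlog, sdlog) * 2^(age / p$tau_min)
    ch_name <- character(0); ch_pos <- numeric(0); ch_tc <- integer(0)
    for (j in seq_along(chans)) {
      k <- sample(counts_support, 1, prob = probs)
      if (k == 0L) {
        ch_name <- c(ch_name, names(chans)[j]); ch_pos <- c(ch_pos, NA_real_)
        ch_tc <- c(ch_tc, 0L)
      } else {
        pos <- sort(stats::runif(k, 0.05, 0.95) * len)
        ch_name <- c(ch_name, rep(names(chans)[j], k)); ch_pos <- c(ch_pos, pos)
        ch_tc <- c(ch_tc, rep(k, k))
      }
    }
    out[[i]] <- list(cell_id = sprintf("cell%05d", i), length_um = len,
                     channel = ch_name, position_um = ch_pos,
                     age_min = age, true_count = ch_tc)
  }
  nper <- vapply(out, function(x) length(x$channel), integer(1))
  tab <- data.frame(
    cell_id = rep(vapply(out, `[[`, character(1), "cell_id"), nper),
    length_um = rep(vapply(out, `[[`, numeric(1), "length_um"), nper),
    channel = unlist(lapply(out, `[[`, "channel")),
    position_um = unlist(lapply(out, `[[`, "position_um")),
    stringsAsFactors = FALSE
  )
  if (config$keep_truth) {
    tab$age_min <- rep(vapply(out, `[[`, numeric(1), "age_min"), nper)
    tab$new_pole_end <- NA_integer_
    tab$true_count <- unlist(lapply(out, `[[`, "true_count"))
  }
  structure(tab, channels = chans, mode = "par_null", seed = config$seed,
            class = c("foci_table", "data.frame"))
}
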