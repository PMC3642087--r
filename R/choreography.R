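#' Age at which a locus is replicated
#'
#' Replication initiates at age `a_init_min` (possibly in the mother, if
#' negative) and the forks progress at constant speed, so a locus at
#' `offset_kb` from oriC is replicated at
#' `a_init_min + C_min * offset_kb / half_genome_kb`. Both replichores are
#' replicated in parallel, so the timing depends only on the offset, not on
#' the side.
#'
#' @param locus a [locus_spec()] (or a numeric offset in kb).
#' @param params a [choreo_params()].
#' @return Replication age in minutes (may be negative for origin-proximal
#'   loci when initiation happens before birth).
#' @export
replication_age <- function(locus, params) {
  off <- if (is_locus_spec(locus)) locus$offset_kb else as.numeric(locus)
  params$a_init_min + params$C_min * off / params$half_genome_kb
}

#' Final intracellular positions of the two copies of a locus
#'
#' After segregation the two copies of a locus sit at mirror-image relative
#' positions. The new-pole coordinate is a piecewise-linear function of the
#' chromosomal offset: Ori-region loci (offset <= `ori_edge_kb`) all land at
#' `p_ori`; Ter-region loci (offset >= `ter_edge_kb`) stay at mid-cell; arm
#' loci interpolate linearly in between. This encodes the longitudinal
#' organization of the chromosome between the two distinctive regions.
#'
#' @inheritParams replication_age
#' @return Numeric of length 2: `c(new = ..., old = ...)`, the new-pole-side
#'   and old-pole-side copies; always mirror-symmetric about 0.5.
#' @export
final_positions <- function(locus, params) {
  off <- if (is_locus_spec(locus)) locus$offset_kb else as.numeric(locus)
  shift <- if (is_locus_spec(locus)) locus$pole_shift else 0
  p <- if (off <= params$ori_edge_kb) {
    params$p_ori
  } else if (off >= params$ter_edge_kb) {
    0.5
  } else {
    f <- (off - params$ori_edge_kb) / (params$ter_edge_kb - params$ori_edge_kb)
    params$p_ori + f * (0.5 - params$p_ori)
  }
  p <- max(0, p - shift)
  c(new = p, old = 1 - p)
}

#' Map a mother-frame coordinate into a daughter's frame
#'
#' At division the mother is split at mid-cell and each daughter's new pole is
#' the former division plane. A position `p_mother` in the distal half
#' (`[0.5, 1]`) maps to `2 p - 1` in the distal daughter; a position in the
#' proximal half (`[0, 0.5]`) maps to `1 - 2 p` in the proximal daughter. In
#' both cases mid-cell maps to 0 (the daughter's new pole) and the mother's
#' pole maps to 1 (the daughter's old pole).
#'
#' @param p_mother relative coordinate in the mother, in the half selected by
#'   `daughter_side`.
#' @param daughter_side `"distal"` (mother half `[0.5, 1]`) or `"proximal"`
#'   (mother half `[0, 0.5]`).
#' @return Relative coordinate in the daughter frame, in `[0, 1]`.
#' @export
daughter_coordinate <- function(p_mother, daughter_side = c("distal", "proximal")) {
  daughter_side <- match.arg(daughter_side)
  stopifnot(all(p_mother >= 0), all(p_mother <= 1))
  tol <- 1e-9
  if (daughter_side == "distal") {
    if (any(p_mother < 0.5 - tol)) {
      stop("p_mother must lie in [0.5, 1] for the distal daughter")
    }
    pmin(1, pmax(0, 2 * p_mother - 1))
  } else {
    if (any(p_mother > 0.5 + tol)) {
      stop("p_mother must lie in [0, 0.5] for the proximal daughter")
    }
    pmin(1, pmax(0, 1 - 2 * p_mother))
  }
}

# Position inherited at birth: the daughter-frame image of the mother's final
# position. Both daughters yield the same value (1 - 2 * p_new).
inherited_position <- function(locus, params) {
  fp <- final_positions(locus, params)
  unname(daughter_coordinate(fp["old"], "distal"))
}

#' Deterministic position(s) of a locus at a given cell age
#'
#' Implements the single-round choreography: a locus rests at its inherited
#' position, relocates linearly to mid-cell during the `reloc_lead_min`
#' minutes preceding its replication, stays as one (cohesive) focus at
#' mid-cell for `t_coh_min` after replication, then the two copies move
#' linearly to their [final_positions()] over `seg_dur_min` minutes.
#'
#' Ter-region loci (offset >= `ter_edge_kb`) are the exception: their copies
#' remain cohesive at mid-cell for the rest of the cycle and only separate --
#' symmetrically about mid-cell by `ter_sep_offset` -- within the last
#' `ter_late_min` minutes, and only when the per-cell separation flag
#' `ter_sep` (drawn by the simulator) is set.
#'
#' @inheritParams replication_age
#' @param age cell age in minutes, in `[0, tau_min]`.
#' @param ter_sep logical; per-cell Ter-separation flag.
#' @return A list with `pos` (numeric vector of 1 or 2 relative coordinates)
#'   and `state` (one of `"UNREPLICATED"`, `"COHESIVE"`, `"SEGREGATING"`,
#'   `"SEGREGATED"`).
#' @export
locus_position <- function(locus, age, params, ter_sep = FALSE) {
  stopifnot(length(age) == 1L)
  if (age < 0 || age > params$tau_min) {
    stop("age must lie in [0, tau_min] = [0, ", params$tau_min, "]")
  }
  off <- if (is_locus_spec(locus)) locus$offset_kb else as.numeric(locus)
  t_rep <- replication_age(locus, params)
  inh <- inherited_position(locus, params)
  is_ter <- off >= params$ter_edge_kb

  if (is_ter) {
    if (isTRUE(ter_sep) && age >= params$tau_min - params$ter_late_min) {
      d <- params$ter_sep_offset
      return(list(pos = c(0.5 - d, 0.5 + d), state = "SEGREGATED"))
    }
    if (age < t_rep - params$reloc_lead_min) {
      return(list(pos = inh, state = "UNREPLICATED"))
    }
    if (age < t_rep) {
      f <- (age - (t_rep - params$reloc_lead_min)) / params$reloc_lead_min
      return(list(pos = inh + f * (0.5 - inh), state = "UNREPLICATED"))
    }
    return(list(pos = 0.5, state = "COHESIVE"))
  }

  fp <- final_positions(locus, params)
  if (age < t_rep - params$reloc_lead_min) {
    list(pos = inh, state = "UNREPLICATED")
  } else if (age < t_rep) {
    f <- (age - (t_rep - params$reloc_lead_min)) / params$reloc_lead_min
    list(pos = inh + f * (0.5 - inh), state = "UNREPLICATED")
  } else if (age < t_rep + params$t_coh_min) {
    list(pos = 0.5, state = "COHESIVE")
  } else if (age < t_rep + params$t_coh_min + params$seg_dur_min) {
    f <- (age - t_rep - params$t_coh_min) / params$seg_dur_min
    list(pos = unname(0.5 + f * (fp - 0.5)), state = "SEGREGATING")
  } else {
    list(pos = unname(fp), state = "SEGREGATED")
  }
}

#' Steady-state cell-age density of an exponentially growing population
#'
#' In balanced exponential growth the density of cell ages is
#' `(2 log 2 / tau) * 2^(-age / tau)` on `[0, tau]`: newborn cells are exactly
#' twice as frequent as dividing cells.
#'
#' @param age age(s) in minutes, in `[0, tau_min]`.
#' @inheritParams replication_age
#' @return Probability density per minute, same length as `age`.
#' @export
steady_state_age_density <- function(age, params) {
  if (any(age < 0 | age > params$tau_min)) {
    stop("age must lie in [0, tau_min]")
  }
  (2 * log(2) / params$tau_min) * 2^(-age / params$tau_min)
}

#' Cumulative steady-state age distribution (exact inverse used for sampling)
#' @inheritParams steady_state_age_density
#' @return `P(A <= age)` under the steady-state age law.
#' @export
steady_state_age_cdf <- function(age, params) {
  if (any(age < 0 | age > params$tau_min)) {
    stop("age must lie in [0, tau_min]")
  }
  2 * (1 - 2^(-age / params$tau_min))
}

# Inverse-CDF sampler for steady-state ages; u in [0,1).
sample_steady_state_age <- function(u, params) {
  -params$tau_min * log2(1 - u / 2)
}
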