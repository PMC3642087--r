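#' Model constants for the chromosome-segregation choreography
#'
#' Bundles every constant of the single-chromosome choreography model and of
#' the microscopy observation model. Two named calibrations are provided,
#' matching the two growth conditions of the underlying study system:
#' `"citrate"` (minimal medium + citrate: one replication round per cycle,
#' doubling time ~50 min) and `"glucose_caa"` (minimal medium + glucose and
#' casamino acids: overlapping rounds, doubling time ~45 min, slightly larger
#' cells).
#'
#' Time is in minutes, length in micrometers, chromosomal coordinates in kb
#' from oriC along a replichore, and intracellular positions in relative cell
#' length (0 = new pole, 1 = old pole).
#'
#' @param mode `"citrate"` or `"glucose_caa"`; selects the default calibration.
#' @param ... individual overrides of any field listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{tau_min}{doubling time (min).}
#'   \item{L0_um, len_cv}{mean newborn length (um) and its lognormal
#'     coefficient of variation. Division-septum placement noise is folded
#'     into this CV (a snapshot model cannot separate the two sources).}
#'   \item{C_min}{replication (C) period (min).}
#'   \item{a_init_min}{initiation age (min); negative means the round was
#'     initiated in the mother, before division.}
#'   \item{half_genome_kb}{replichore length (kb).}
#'   \item{ori_edge_kb, ter_edge_kb}{chromosomal extent of the Ori region
#'     (offsets <= ori_edge_kb) and of the Ter region (offsets >=
#'     ter_edge_kb). The edges are parameters bracketed by the marker panel,
#'     not measured quantities.}
#'   \item{p_ori}{final relative position of the new-pole copy of Ori-region
#'     loci (the old-pole copy sits at `1 - p_ori`).}
#'   \item{t_coh_min}{post-replication cohesion time for Ori/arm loci (min).}
#'   \item{seg_dur_min}{duration of the move from mid-cell to the final
#'     positions (min).}
#'   \item{reloc_lead_min}{lead time before replication during which a locus
#'     relocates from its inherited position to mid-cell (min).}
#'   \item{p_ter_sep}{probability that a Ter-region locus pair separates
#'     visibly before division (citrate).}
#'   \item{ter_sep_offset, ter_late_min}{when a Ter pair separates it does so
#'     symmetrically about mid-cell by this fixed relative offset, within the
#'     last `ter_late_min` minutes of the cycle.}
#'   \item{sigma_pos_um}{focus localization noise SD (um).}
#'   \item{p_det}{per-focus detection probability.}
#'   \item{d_res_um}{optical merge distance (um): foci closer than this are
#'     reported as one.}
#'   \item{p_cellfail}{whole-cell detection-failure probability.}
#'   \item{p_fork_split}{probability that the two replication forks are
#'     transiently resolved as two nearby replisome foci.}
#'   \item{fork_split_min, fork_split_max}{relative separation range of a
#'     split fork pair (kept below the 0.35 "together" threshold).}
#'   \item{next_round_min}{window before division (min) during which
#'     next-round replisome foci appear at the `p_ori`/`1 - p_ori` positions.}
#'   \item{a2_init_min}{second-round initiation age (glucose_caa); defaults to
#'     `tau_min + a_init_min`, i.e. the next round initiates at the same cycle
#'     phase every generation.}
#'   \item{p_rep2_two}{probability that a cell past second initiation shows
#'     the two quarter-position replisome foci rather than a single merged
#'     focus (glucose_caa; fitted so the observed two-foci fraction among
#'     cells > 3.5 um lands at ~65%, accounting for large cells whose second
#'     round has not yet initiated).}
#'   \item{p_ter_sep_rich}{probability that the Ter pair separates in cells
#'     past second initiation (glucose_caa; fitted so one-Ter cells are about
#'     twice as frequent as two-Ter cells among four-Ori cells).}
#'   \item{par_null_count_probs}{named categorical distribution of per-channel
#'     focus counts in the partition-defective (`par_null`) mode.}
#' }
#'
#' @return An object of class `choreo_params` (a validated named list).
#' @examples
#' p <- choreo_params("citrate")
#' p$tau_min
#' choreo_params("citrate", p_det = 1, sigma_pos_um = 0)$p_det
#' @export
choreo_params <- function(mode = c("citrate", "glucose_caa"), ...) {
  mode <- match.arg(mode)
  p <- list(
    tau_min = 50, L0_um = 2.09, len_cv = 0.10,
    C_min = 45, a_init_min = -5,
    half_genome_kb = 3150, ori_edge_kb = 900, ter_edge_kb = 2600,
    p_ori = 0.2, t_coh_min = 2, seg_dur_min = 4, reloc_lead_min = 10,
    p_ter_sep = 0.40, ter_sep_offset = 0.10, ter_late_min = 5,
    sigma_pos_um = 0.08, p_det = 0.96, d_res_um = 0.30, p_cellfail = 0.05,
    p_fork_split = 0.06, fork_split_min = 0.15, fork_split_max = 0.35,
    next_round_min = 2,
    a2_init_min = NA_real_, p_rep2_two = NA_real_, p_ter_sep_rich = NA_real_,
    par_null_count_probs = c("0" = 0.55, "1" = 0.25, "2" = 0.13,
                             "3" = 0.05, "4" = 0.02)
  )
  if (mode == "glucose_caa") {
    p$tau_min <- 45
    p$L0_um <- 2.2
    p$a_init_min <- -14.8
    p$p_fork_split <- 0.20
    p$p_rep2_two <- 0.85
    p$p_ter_sep_rich <- 1 / 3
  }
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown choreo_params field(s): ", paste(unknown, collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  if (is.na(p$a2_init_min)) p$a2_init_min <- p$tau_min + p$a_init_min
  p$mode <- mode
  class(p) <- "choreo_params"
  validate_choreo_params(p)
  p
}

validate_choreo_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid choreo_params: ", msg)
  for (f in c("tau_min", "L0_um", "C_min", "t_coh_min", "seg_dur_min",
              "reloc_lead_min", "ter_late_min", "sigma_pos_um", "d_res_um",
              "next_round_min")) {
    chk(is.numeric(p[[f]]) && p[[f]] >= 0, paste(f, "must be >= 0"))
  }
  for (f in c("p_det", "p_cellfail", "p_ter_sep", "p_fork_split")) {
    chk(p[[f]] >= 0 && p[[f]] <= 1, paste(f, "must be in [0, 1]"))
  }
  chk(p$p_ori > 0 && p$p_ori < 0.5, "p_ori must be in (0, 0.5)")
  chk(p$ori_edge_kb < p$ter_edge_kb, "ori_edge_kb must be < ter_edge_kb")
  chk(p$ter_edge_kb <= p$half_genome_kb, "ter_edge_kb must be <= half_genome_kb")
  chk(p$a_init_min + p$C_min <= p$tau_min,
      "replication must end before division (a_init_min + C_min <= tau_min)")
  chk(p$fork_split_min <= p$fork_split_max, "fork split range inverted")
  chk(abs(sum(p$par_null_count_probs) - 1) < 1e-8,
      "par_null_count_probs must sum to 1")
  invisible(p)
}

#' @export
print.choreo_params <- function(x, ...) {
  cat("<choreo_params: mode", x$mode, ">\n")
  flds <- setdiff(names(x), c("mode", "par_null_count_probs"))
  cat(paste0("  ", flds, " = ",
             vapply(x[flds], function(v) paste(signif(v, 5), collapse = ","),
                    character(1)), collapse = "\n"), "\n")
  invisible(x)
}
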