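#' Define a chromosomal locus by its replichore offset
#'
#' A locus is identified by its distance from the replication origin (oriC)
#' along one of the two replichores, following the field convention of naming
#' loci `"<offset kb>-<R|L>"` (e.g. `"82-R"` is 82 kb from oriC on the right
#' replichore). Offsets are measured in kb and must lie within one replichore,
#' i.e. in `[0, half_genome_kb]`.
#'
#' @param offset_kb distance from oriC along the replichore, in kb.
#' @param replichore `"R"` or `"L"`.
#' @param name optional display name; defaults to the conventional
#'   `"<offset>-<side>"` label with a thousands separator (e.g. `"1,509-R"`).
#' @param pole_shift optional per-locus shift of the final new-pole position
#'   (relative units, positive values move the locus poleward). Defaults to 0;
#'   provided as a hook for loci reported slightly closer to the pole than the
#'   region consensus.
#' @param half_genome_kb replichore length used to validate the offset.
#'
#' @return An object of class `locus_spec` with fields `name`, `replichore`,
#'   `offset_kb` and `pole_shift`.
#' @examples
#' locus_spec(82, "R")
#' parse_locus("3,090-L")
#' @export
locus_spec <- function(offset_kb, replichore = c("R", "L"), name = NULL,
                       pole_shift = 0, half_genome_kb = 3150) {
  replichore <- match.arg(replichore)
  stopifnot(is.numeric(offset_kb), length(offset_kb) == 1L, offset_kb >= 0)
  if (offset_kb > half_genome_kb) {
    stop("offset_kb (", offset_kb, ") exceeds the replichore length (",
         half_genome_kb, " kb)")
  }
  if (is.null(name)) {
    name <- paste0(formatC(offset_kb, format = "d", big.mark = ","),
                   "-", replichore)
  }
  structure(
    list(name = name, replichore = replichore, offset_kb = offset_kb,
         pole_shift = pole_shift),
    class = "locus_spec"
  )
}

#' Parse a conventional locus label back into a locus specification
#'
#' Inverse of the naming convention used by [locus_spec()]: `"82-R"` or
#' `"3,090-L"` parse to their offset and replichore side. The special label
#' `"REPLISOME"` is rejected here; replisome channels are declared as such in
#' the simulation configuration, not as loci.
#'
#' @param x character label.
#' @inheritParams locus_spec
#' @return A `locus_spec`.
#' @export
parse_locus <- function(x, half_genome_kb = 3150) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([0-9,]+)-([RL])$", x))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse locus label '", x,
         "'; expected the form '<offset kb>-<R|L>', e.g. '82-R'")
  }
  offset <- as.numeric(gsub(",", "", m[2]))
  locus_spec(offset, m[3], name = x, half_genome_kb = half_genome_kb)
}

#' @export
format.locus_spec <- function(x, ...) {
  sprintf("<locus %s: %g kb from oriC, replichore %s>",
          x$name, x$offset_kb, x$replichore)
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

is_locus_spec <- function(x) inherits(x, "locus_spec")

#' Reference panel of 20 tagged chromosomal loci
#'
#' A panel of twenty loci spanning both replichores of the 6.3 Mb PAO1
#' chromosome, of the kind used in fluorescent repressor-operator / ParB-parS
#' localization studies: three Ori-region loci and a terminus-proximal cluster
#' on each replichore, with arm loci in between. Fourteen are the classical
#' published marker positions (82, 327, 628, 1,509, 2,499, 2,672, 2,957 and
#' 3,028 kb on the right replichore; 92, 488, 851, 1,812, 2,784 and 3,090 kb
#' on the left); the remaining six are synthetic fill-in offsets chosen to
#' sample the arms away from the region boundaries.
#'
#' @return A named list of [locus_spec()] objects.
#' @export
pao1_loci <- function() {
  labels <- c("82-R", "327-R", "628-R", "1,300-R", "1,509-R", "2,010-R",
              "2,499-R", "2,672-R", "2,957-R", "3,028-R",
              "92-L", "488-L", "851-L", "1,391-L", "1,700-L", "2,100-L",
              "2,355-L", "1,812-L", "2,784-L", "3,090-L")
  loci <- lapply(labels, parse_locus)
  names(loci) <- labels
  loci
}
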