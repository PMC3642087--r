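#' Write a foci table to a delimited text file
#'
#' Tab-delimited, one row per observed focus; cells with no focus in a
#' channel appear as a single row with an empty position field. Channel
#' declarations (and whether hidden-truth columns are present) live in a
#' commented header block so the file is self-describing. Numbers are written
#' with fixed precision so that a parse/serialize round trip is
#' byte-identical.
#'
#' @param tab a foci table from [sample_population()] or
#'   [read_cell_table()].
#' @param path output file path.
#' @param truth write the hidden ground-truth columns (only honoured when
#'   present in `tab`).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path, truth = FALSE) {
  chans <- attr(tab, "channels")
  if (is.null(chans)) {
    chans <- stats::setNames(unique(tab$channel), unique(tab$channel))
  }
  chans <- vapply(chans, function(x) {
    if (is_locus_spec(x)) x$name else as.character(x)
  }, character(1))
  truth <- isTRUE(truth) && all(c("age_min", "new_pole_end", "true_count")
                                %in% names(tab))
  num <- function(x, digits = 5) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  }
  header <- c(
    "# fociseg cell table v1",
    paste0("# channels: ",
           paste(names(chans), chans, sep = "=", collapse = " ")),
    paste0("# truth: ", if (truth) "yes" else "no"),
    paste(c("cell_id", "length_um", "channel", "position_um",
            if (truth) c("age_min", "new_pole_end", "true_count")),
          collapse = "\t")
  )
  body_cols <- list(tab$cell_id, num(tab$length_um), tab$channel,
                    num(tab$position_um))
  if (truth) {
    body_cols <- c(body_cols, list(
      num(tab$age_min, 4),
      ifelse(is.na(tab$new_pole_end), "", as.character(tab$new_pole_end)),
      as.character(tab$true_count)))
  }
  body <- do.call(paste, c(body_cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a foci table written by [write_cell_table()]
#'
#' Parses and validates a cell/foci table: every `cell_id` must carry a
#' single consistent length, and every position must lie within
#' `[0, length_um]`. Malformed rows are reported with their line numbers.
#'
#' @section Converting segmentation-tool exports:
#' Mesh-based segmentation suites (MicrobeTracker, Oufti) export per-cell
#' meshes plus spot lists with a position along the cell midline. To build a
#' table this package reads: one row per spot with `cell_id` (the tool's
#' cell number), `length_um` (midline length times the pixel size),
#' `channel` (one name per fluorophore) and `position_um` (the spot's
#' arc-length coordinate along the midline, in um from one pole — the end
#' does not matter, orientation is inferred downstream); plus one
#' `position_um`-empty row for every cell/channel combination without
#' spots. Declare the channels in a `# channels:` header line as
#' `name=<offset kb>-<R|L>` or `name=REPLISOME`.
#'
#' @param path file path.
#' @return A foci table (`data.frame` of class `foci_table`), with channel
#'   declarations in `attr(, "channels")`.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  chan_line <- grep("^# channels:", lines, value = TRUE)
  chans <- character(0)
  if (length(chan_line)) {
    decls <- strsplit(sub("^# channels:\\s*", "", chan_line[1]), "\\s+")[[1]]
    kv <- strsplit(decls, "=", fixed = TRUE)
    chans <- stats::setNames(vapply(kv, `[`, character(1), 2),
                             vapply(kv, `[`, character(1), 1))
  }
  body_idx <- which(!is_comment)
  if (!length(body_idx)) stop("no data rows in ", path)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  required <- c("cell_id", "length_um", "channel", "position_um")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  rows_idx <- body_idx[-1]
  fields <- strsplit(lines[rows_idx], "\t", fixed = TRUE)
  bad_len <- which(lengths(fields) != length(header))
  if (length(bad_len)) {
    stop("malformed row(s) (wrong field count) at line(s): ",
         paste(rows_idx[bad_len], collapse = ", "))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- header
  tonum <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  tab <- data.frame(cell_id = m[, "cell_id"],
                    length_um = tonum(m[, "length_um"]),
                    channel = m[, "channel"],
                    position_um = tonum(m[, "position_um"]),
                    stringsAsFactors = FALSE)
  for (tc in c("age_min", "new_pole_end", "true_count")) {
    if (tc %in% header) tab[[tc]] <- tonum(m[, tc])
  }
  bad <- which(is.na(tab$length_um) | tab$length_um <= 0)
  if (length(bad)) {
    stop("non-positive or missing length_um at line(s): ",
         paste(rows_idx[bad], collapse = ", "))
  }
  bad <- which(!is.na(tab$position_um) &
                 (tab$position_um < 0 | tab$position_um > tab$length_um))
  if (length(bad)) {
    stop("position_um outside [0, length_um] at line(s): ",
         paste(rows_idx[bad], collapse = ", "))
  }
  len_by_cell <- tapply(tab$length_um, tab$cell_id,
                        function(x) length(unique(x)))
  if (any(len_by_cell > 1)) {
    stop("conflicting length_um for cell(s): ",
         paste(names(len_by_cell)[len_by_cell > 1], collapse = ", "))
  }
  if (!length(chans)) {
    chans <- stats::setNames(unique(tab$channel), unique(tab$channel))
  }
  structure(tab, channels = as.list(chans),
            class = c("foci_table", "data.frame"))
}

run_config_fields <- c("mode", "seed", "n_cells", "channels", "params",
                       "analysis", "out_dir")

#' Read a simulation/analysis run configuration (YAML)
#'
#' A run configuration holds the mode, seed, cell count, channel map,
#' choreography-parameter overrides, analysis thresholds and output
#' directory. Unknown top-level keys are rejected; the configuration
#' round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$mode) || is.null(cfg$seed) || is.null(cfg$n_cells)) {
    stop("run config must define mode, seed and n_cells")
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param cfg a `run_config` (named list with the documented fields).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full analysis pipeline and write tidy summary tables
#'
#' Convenience wrapper used by the command-line interface: computes, for every
#' locus channel, the focus-count fractions, segregation curves, oriented
#' position summaries and switching-rule profiles, plus the replisome summary
#' when a replisome channel is declared, and writes one TSV per analysis into
#' `out_dir`.
#'
#' @param tab a foci table.
#' @param ref_channel reference channel for orientation (`NULL` to skip the
#'   oriented analyses).
#' @param out_dir output directory (created if missing).
#' @param classes a [size_classes()].
#' @return Invisibly, the list of written file paths.
#' @export
analyze_all <- function(tab, ref_channel = NULL, out_dir = ".",
                        classes = size_classes()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chans <- attr(tab, "channels")
  labels <- vapply(chans, function(x) {
    if (is_locus_spec(x)) x$name else as.character(x)
  }, character(1))
  locus_chans <- names(labels)[labels != "REPLISOME"]
  rep_chans <- names(labels)[labels == "REPLISOME"]
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  counts <- do.call(rbind, lapply(locus_chans, function(ch) {
    n <- count_foci(tab, ch)
    k <- n$n_foci[!n$excluded]
    data.frame(channel = ch, n = length(k), f1 = mean(k == 1L),
               f2 = mean(k == 2L), f_gt2 = mean(k > 2L))
  }))
  wr(counts, "focus_count_fractions.tsv")
  wr(do.call(rbind, lapply(locus_chans, function(ch) {
    segregation_curves(tab, ch, bin_um = classes$profile_bin_um)
  })), "segregation_curves.tsv")
  if (!is.null(ref_channel)) {
    otab <- orient(tab, ref_channel)
    wr(do.call(rbind, lapply(locus_chans, function(ch) {
      position_summary(otab, ch, classes)
    })), "position_summaries.tsv")
    wr(do.call(rbind, lapply(locus_chans, function(ch) {
      segregation_profile_curve(otab, ch, bin_um = classes$profile_bin_um)
    })), "segregation_profiles.tsv")
  }
  for (ch in rep_chans) {
    rs <- replisome_summary(tab, ch, bin_um = classes$profile_bin_um)
    wr(rs$counts, paste0("replisome_counts_", ch, ".tsv"))
    wr(rs$one_focus, paste0("replisome_one_focus_", ch, ".tsv"))
    wr(rs$pairs, paste0("replisome_pairs_", ch, ".tsv"))
  }
  invisible(written)
}
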