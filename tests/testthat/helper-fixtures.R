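# Shared fixtures: parameter sets and small simulated populations built in
# code at test time.

noise_off <- list(sigma_pos_um = 0, p_det = 1, d_res_um = 0, p_cellfail = 0)

# A one-bin oriented table built by hand: all cells have length 1 um and an
# unambiguous polar reference focus, so relative positions equal raw
# positions.
tiny_oriented <- function(analyte_foci) {
  rows <- list()
  for (i in seq_along(analyte_foci)) {
    cid <- sprintf("c%02d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cid, length_um = 1, channel = "ref", position_um = 0.05)
    for (p in analyte_foci[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid, length_um = 1, channel = "locus", position_um = p)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "channels") <- c(ref = "3,028-R", locus = "1,509-R")
  class(tab) <- c("foci_table", "data.frame")
  orient(tab, "ref")
}

citrate_channels <- c(ori = "82-R", arm = "1,509-R", ter = "2,957-R",
                      ref = "3,028-R", dif = "3,090-L")
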