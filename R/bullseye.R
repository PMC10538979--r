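## AHA 17-segment bullseye export of per-segment report quantities.

#' Export a bullseye table for one report quantity
#'
#' Maps a per-segment quantity of a perfusion report onto the AHA
#' 17-segment bullseye layout (ring, sector, coronary territory) and
#' optionally writes CSV and JSON files.
#'
#' @param report Per-segment report from [perfusionReport()] (or
#'   `run@report`).
#' @param quantity Column name to map (e.g. `"MFR"`, `"VO2_den"`,
#'   `"thickness"`, `"t_act"`).
#' @param csv,json Optional output paths.
#' @return The bullseye `data.frame` (invisibly if files are written).
#' @export
exportBullseye <- function(report, quantity, csv = NULL, json = NULL) {
  if (!quantity %in% names(report))
    stop("unknown quantity: ", quantity)
  lv <- report[report$wall %in% c("LV", "SEP"), , drop = FALSE]
  sector <- sub("^(basal|mid|apical) ", "", lv$name)
  out <- data.frame(segment = lv$segment, ring = lv$ring, sector = sector,
                    territory = lv$territory, value = lv[[quantity]],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$ring, c("basal", "mid", "apical", "apex")),
                   out$segment), ]
  rownames(out) <- NULL
  wrote <- FALSE
  if (!is.null(csv)) {
    utils::write.csv(out, csv, row.names = FALSE)
    wrote <- TRUE
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(quantity = quantity, segments = out), json,
                         auto_unbox = TRUE, digits = NA)
    wrote <- TRUE
  }
  if (wrote) invisible(out) else out
}

#' Export per-vessel flow and per-layer intramyocardial pressure waveforms
#'
#' Writes one beat's proximal coronary flow waveforms and, when recorded,
#' the per-segment-layer intramyocardial pressure series to CSV.
#'
#' @param out A beat series (e.g. `run@rest$out`).
#' @param path CSV path.
#' @return The waveform `data.frame`, invisibly.
#' @export
exportWaveforms <- function(out, path) {
  df <- data.frame(t = out$t,
                   q_LM = out$corQ[, 1], q_LAD = out$corQ[, 2],
                   q_LCx = out$corQ[, 3], q_RCA = out$corQ[, 4],
                   p_LV = out$hemo[, 1], p_RV = out$hemo[, 2],
                   P_peri = out$hemo[, 9])
  if (!is.null(out$imp)) {
    imp <- as.data.frame(out$imp)
    names(imp) <- paste0("IMP_", seq_len(ncol(imp)))
    df <- cbind(df, imp)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
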