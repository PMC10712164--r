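CYTO_CHANNELS <- c("FSC-H", "SSC-H", "BL1-H", "BL1-A", "BL3-H", "RL1-H")

#' Construct a cytometry event table
#'
#' Per-event scatter and fluorescence channels plus acquisition metadata.
#' Channel naming follows the instrument convention: SYBR Green I on BL1
#' (height and area), propidium iodide on BL3, SYTO 62 nucleic-acid stain
#' on RL1; all values in arbitrary fluorescence units.
#'
#' @param events data frame with (at least) columns `FSC-H`, `SSC-H`,
#'   `BL1-H`, `BL1-A`, `BL3-H`, `RL1-H`; values non-negative.
#' @param volume_mL recorded acquisition volume in mL (default 0.075 mL,
#'   i.e. 75 microlitres).
#' @param dilution_factor sample dilution factor (>= 1).
#' @param panel staining panel label (`SG`, `SGPI` or `BODIPY_SYTO62`).
#' @return An `event_table` data frame with metadata attributes.
#' @export
event_table <- function(events, volume_mL = 0.075, dilution_factor = 1,
                        panel = "SG") {
  stopifnot(is.data.frame(events))
  have <- intersect(CYTO_CHANNELS, names(events))
  if (nrow(events) > 0 && any(vapply(events[have], function(v) any(v < 0), logical(1))))
    stop("channel values must be non-negative")
  if (volume_mL <= 0) stop("recorded volume must be positive")
  if (dilution_factor < 1) stop("dilution factor must be >= 1")
  structure(events, volume_mL = volume_mL,
            dilution_factor = dilution_factor, panel = panel,
            class = c("event_table", "data.frame"))
}

.require_channels <- function(events, channels) {
  miss <- setdiff(channels, names(events))
  if (length(miss) > 0)
    stop("missing channel(s): ", paste(miss, collapse = ", "))
}

#' Singlet discrimination on the primary fluorescence channel
#'
#' Events are kept when their area-to-height ratio on the primary
#' fluorescence channel (BL1) lies within `[r_lo, r_hi]` of the
#' population median ratio. Aggregates (doublets) carry roughly doubled
#' area at near-single height, so their relative ratio falls outside the
#' default bounds.
#'
#' @param events an [event_table()].
#' @param r_lo,r_hi relative ratio bounds (defaults 0.7 and 1.3).
#' @return A `gate_result`: list with logical `mask`, `name`, `params`.
#' @export
gate_singlets <- function(events, r_lo = 0.7, r_hi = 1.3) {
  stopifnot(inherits(events, "event_table"))
  if (nrow(events) == 0)
    return(structure(list(mask = logical(0), name = "singlets",
                          params = list(r_lo = r_lo, r_hi = r_hi)),
                     class = "gate_result"))
  .require_channels(events, c("BL1-H", "BL1-A"))
  ratio <- events[["BL1-A"]] / events[["BL1-H"]]
  rel <- ratio / stats::median(ratio)
  structure(list(mask = rel >= r_lo & rel <= r_hi, name = "singlets",
                 params = list(r_lo = r_lo, r_hi = r_hi)),
            class = "gate_result")
}

#' Cell concentrations from a stained event table
#'
#' Counts singlet events above the stain threshold on BL1 and converts to
#' cells/mL using the recorded volume and dilution factor. For the SGPI
#' panel the stained events are additionally split into intact
#' (propidium-iodide negative, `BL3-H <= pi_threshold`) and damaged
#' (`BL3-H > pi_threshold`); intact + damaged = total exactly.
#'
#' @param events an [event_table()].
#' @param gate optional `gate_result` (defaults to [gate_singlets()]).
#' @param threshold_BL1 stain threshold on BL1-H.
#' @param pi_threshold propidium-iodide threshold on BL3-H (SGPI panel).
#' @return List with `total`, and for the SGPI panel `intact` and
#'   `damaged`, in cells/mL, plus `n_events`.
#' @export
cell_concentration <- function(events, gate = gate_singlets(events),
                               threshold_BL1 = 0, pi_threshold = Inf) {
  stopifnot(inherits(events, "event_table"))
  vol <- attr(events, "volume_mL")
  dil <- attr(events, "dilution_factor")
  if (is.null(vol) || vol <= 0) stop("recorded volume must be positive")
  .require_channels(events, "BL1-H")
  sel <- gate$mask & events[["BL1-H"]] > threshold_BL1
  per_mL <- dil / vol
  out <- list(total = sum(sel) * per_mL, n_events = sum(sel))
  if (identical(attr(events, "panel"), "SGPI")) {
    .require_channels(events, "BL3-H")
    intact <- sel & events[["BL3-H"]] <= pi_threshold
    out$intact <- sum(intact) * per_mL
    out$damaged <- out$total - out$intact
  }
  out
}

#' Triple-threshold storage-compound gate
#'
#' Identifies storage-compound-positive (e.g. PHA-positive) cells by a
#' sequential triple threshold: a low side-scatter threshold, a SYTO 62
#' nucleic-acid counterstain threshold on RL1 (keeps cells, rejects
#' debris), and a minor threshold on the selective stain fluorescence on
#' BL1. Per-stage retained counts are logged in the result.
#'
#' @param events an [event_table()].
#' @param ssc_thresh SSC-H threshold.
#' @param syto62_thresh RL1-H threshold.
#' @param bodipy_thresh BL1-H threshold.
#' @return A `gate_result` with additional fields `positive_fraction`
#'   (positives over events passing the cell gates) and `stage_counts`.
#' @export
pha_positive <- function(events, ssc_thresh = 0, syto62_thresh = 0,
                         bodipy_thresh = 0) {
  stopifnot(inherits(events, "event_table"))
  if (any(c(ssc_thresh, syto62_thresh, bodipy_thresh) < 0))
    stop("thresholds must be non-negative")
  .require_channels(events, c("SSC-H", "RL1-H", "BL1-H"))
  s1 <- events[["SSC-H"]] > ssc_thresh
  s2 <- s1 & events[["RL1-H"]] > syto62_thresh
  s3 <- s2 & events[["BL1-H"]] > bodipy_thresh
  structure(list(mask = s3, name = "pha_positive",
                 params = list(ssc_thresh = ssc_thresh,
                               syto62_thresh = syto62_thresh,
                               bodipy_thresh = bodipy_thresh),
                 stage_counts = c(input = nrow(events), ssc = sum(s1),
                                  syto62 = sum(s2), bodipy = sum(s3)),
                 positive_fraction = if (sum(s2) > 0) sum(s3) / sum(s2) else NA_real_),
            class = "gate_result")
}

#' Median intensity over gated events
#'
#' Median of a fluorescence channel over the events passing a gate,
#' reported in arbitrary units. Stain intensity is used as a linear proxy
#' for compound content (nucleic acid on RL1, PHA/neutral lipid on BL1),
#' an assumption recorded in the result.
#'
#' @param events an [event_table()].
#' @param gate a `gate_result`.
#' @param channel channel name.
#' @return List with `median` (NA with a warning when the gate is empty),
#'   `n`, `channel`, `units`, `assumption`.
#' @export
intensity_summary <- function(events, gate, channel) {
  stopifnot(inherits(events, "event_table"))
  .require_channels(events, channel)
  v <- events[[channel]][gate$mask]
  if (length(v) == 0) {
    warning("empty gate: no events for intensity summary")
    med <- NA_real_
  } else med <- stats::median(v)
  list(median = med, n = length(v), channel = channel, units = "A.U.",
       assumption = "intensity assumed linear in compound content")
}

#' Automatic valley threshold between the two largest density modes
#'
#' Kernel-density estimate of log-intensities; the threshold is placed at
#' the minimum-density valley between the two highest modes. Intended for
#' setting stain thresholds on bimodal negative/positive mixtures.
#'
#' @param x positive intensity values.
#' @return Threshold on the original intensity scale.
#' @export
valley_threshold <- function(x) {
  x <- x[x > 0]
  if (length(x) < 10) stop("too few positive values for a density estimate")
  d <- stats::density(log(x))
  dy <- diff(d$y)
  peaks <- which(diff(sign(dy)) == -2) + 1L
  if (length(peaks) < 2) stop("fewer than two density modes found")
  top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(d$y[seq(top2[1], top2[2])]) - 1L
  exp(d$x[valley])
}

#' Write an event table as CSV with a JSON metadata sidecar
#'
#' @param events an [event_table()].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  meta <- list(volume_mL = attr(events, "volume_mL"),
               dilution_factor = attr(events, "dilution_factor"),
               panel = attr(events, "panel"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path CSV path with `<path>.json` sidecar.
#' @return An [event_table()].
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  event_table(df, volume_mL = meta$volume_mL,
              dilution_factor = meta$dilution_factor, panel = meta$panel)
}
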