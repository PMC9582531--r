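#' EEG recording container
#'
#' Lightweight in-memory container for a continuous multichannel EEG
#' recording: a channels-by-samples matrix in microvolts, the sampling rate,
#' the electrode montage, an event table, the reference state, and the set of
#' channels currently marked bad.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz.
#' @param montage data.frame as returned by [montage_1020()]; one row per
#'   data row, same order.
#' @param events data.frame with columns `label` (character) and `onset`
#'   (seconds from recording start); may be empty.
#' @param ref reference state label, e.g. `"FCz"` or `"CAR"`.
#' @param bads character vector of bad-channel labels.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, montage,
                          events = data.frame(label = character(0),
                                              onset = numeric(0)),
                          ref = "FCz", bads = character(0)) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), srate > 0,
            nrow(data) == nrow(montage))
  if (nrow(events) && any(events$onset < 0 |
                          events$onset > ncol(data) / srate)) {
    stop("event onsets must lie within the recording duration")
  }
  rownames(data) <- montage$label
  structure(list(data = data, srate = srate, montage = montage,
                 events = events, ref = ref, bads = bads),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat(sprintf("  reference: %s; bads: %s; events: %d\n", x$ref,
              if (length(x$bads)) paste(x$bads, collapse = ",") else "none",
              nrow(x$events)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

rec_duration <- function(rec) ncol(rec$data) / rec$srate

rec_channel <- function(rec, label) {
  i <- match(label, rec$montage$label)
  if (is.na(i)) stop("channel not found: ", label)
  rec$data[i, ]
}

#' Events falling inside labelled spans
#'
#' Spans are encoded in the event table as `<label>_start` / `<label>_end`
#' pairs (e.g. `walk_start`/`walk_end`, `standing_start`/`standing_end`).
#'
#' @param events event data.frame (`label`, `onset`).
#' @param label span label.
#' @return two-column matrix of span start/end times in seconds.
#' @export
event_spans <- function(events, label) {
  s <- sort(events$onset[events$label == paste0(label, "_start")])
  e <- sort(events$onset[events$label == paste0(label, "_end")])
  if (length(s) != length(e) || any(e < s)) {
    stop("malformed ", label, " spans in event table")
  }
  cbind(start = s, end = e)
}

# ---- BrainVision I/O ------------------------------------------------------
# Minimal reader/writer for the BrainVision triplet (.vhdr/.vmrk/.eeg),
# multiplexed IEEE float32, unit microvolt. Covers exactly what this package
# writes; not a general-purpose parser.

#' Write a recording as a BrainVision triplet
#'
#' @param rec [eeg_recording()].
#' @param basename path without extension; `.vhdr`, `.vmrk` and `.eeg` are
#'   created next to each other.
#' @return invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg  <- paste0(basename, ".eeg")
  nchan <- nrow(rec$data)
  stem <- basename(basename)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nchan),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nchan), rec$montage$label)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (nrow(rec$events)) {
    pos <- round(rec$events$onset * rec$srate) + 1L
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L,
                          rec$events$label, pos))
  }
  writeLines(mrk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision triplet written by [write_brainvision()]
#'
#' @param vhdr path to the `.vhdr` file.
#' @param montage optional montage to attach; by default positions are looked
#'   up by label in the full [montage_1020()] table.
#' @return [eeg_recording()].
#' @export
read_brainvision <- function(vhdr, montage = NULL) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  grab <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  nchan <- as.integer(grab("NumberOfChannels"))
  srate <- 1e6 / as.numeric(grab("SamplingInterval"))
  ch <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch), ","),
                   `[[`, character(1), 1L)
  dir <- dirname(vhdr)
  eeg <- file.path(dir, grab("DataFile"))
  vmrk <- file.path(dir, grab("MarkerFile"))
  nbytes <- file.info(eeg)$size
  n <- as.integer(nbytes / 4 / nchan)
  con <- file(eeg, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n * nchan, size = 4, endian = "little")
  data <- matrix(x, nrow = nchan, ncol = n)
  events <- data.frame(label = character(0), onset = numeric(0))
  if (file.exists(vmrk)) {
    mk <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk), value = TRUE)
    if (length(mk)) {
      parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", mk), ",")
      events <- data.frame(
        label = vapply(parts, `[[`, character(1), 1L),
        onset = (as.numeric(vapply(parts, `[[`, character(1), 2L)) - 1) / srate
      )
    }
  }
  if (is.null(montage)) {
    full <- montage_table()
    idx <- match(labels, full$label)
    if (anyNA(idx)) stop("unknown channel labels: ",
                         paste(labels[is.na(idx)], collapse = ", "))
    montage <- full[idx, ]
  }
  eeg_recording(data, srate, montage, events = events)
}
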