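# Recording I/O.
#
# CSV: signal file `time_s,O1,O2` plus a companion marker file
# `<stem>_markers.csv` with `onset_s,image_index,is_target,trial`.
#
# EDF: minimal EDF+C writer/reader implemented here because no EDF package
# is available in the supported dependency set.  Signals are stored as
# 16-bit integers over a fixed physical range of -327.68..327.67 uV, i.e. a
# quantization step of exactly 0.01 uV; flash events go into a standard
# "EDF Annotations" TAL channel, one 1-second data record.

#' Write an EEG recording to disk
#'
#' @param recording an `eeg_recording`.
#' @param path output file path; for `"csv"` a companion
#'   `<stem>_markers.csv` is written next to it.
#' @param format `"csv"` or `"edf"`.
#' @return Invisibly, the paths written.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path, format = c("csv", "edf")) {
  if (!is.character(format) || !all(format %in% c("csv", "edf"))) {
    stopf("unsupported format '%s'; supported formats: csv, edf",
          paste(format, collapse = ","))
  }
  format <- match.arg(format)
  if (!inherits(recording, "eeg_recording") ||
      is.null(recording$samples) || nrow(recording$samples) == 0L) {
    stopf("cannot write an empty recording")
  }
  switch(format,
         csv = write_recording_csv(recording, path),
         edf = write_recording_edf(recording, path))
}

#' Read an EEG recording from disk
#'
#' @param path file written by [write_recording()].
#' @param format `"csv"` or `"edf"`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("csv", "edf")) {
  if (!is.character(format) || !all(format %in% c("csv", "edf"))) {
    stopf("unsupported format '%s'; supported formats: csv, edf",
          paste(format, collapse = ","))
  }
  format <- match.arg(format)
  switch(format,
         csv = read_recording_csv(path),
         edf = read_recording_edf(path))
}

marker_path <- function(path) {
  sub("(\\.[^.]*)?$", "_markers.csv", path)
}

write_recording_csv <- function(recording, path) {
  fs <- recording$sampling_rate
  n <- nrow(recording$samples)
  sig <- data.frame(time_s = (seq_len(n) - 1) / fs,
                    O1 = recording$samples[, 1],
                    O2 = recording$samples[, 2])
  utils::write.csv(format(sig, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  mk <- recording$schedule
  mpath <- marker_path(path)
  utils::write.csv(
    data.frame(onset_s = mk$onset_s, image_index = mk$image_index,
               is_target = as.integer(mk$is_target), trial = mk$trial),
    mpath, row.names = FALSE, quote = FALSE)
  invisible(c(path, mpath))
}

read_recording_csv <- function(path) {
  sig <- utils::read.csv(path)
  if (!all(c("time_s", "O1", "O2") %in% names(sig))) {
    stopf("'%s' is not a recording CSV (expected columns time_s,O1,O2)", path)
  }
  fs <- if (nrow(sig) > 1) 1 / stats::median(diff(sig$time_s)) else 128
  mk <- utils::read.csv(marker_path(path))
  sched <- data.frame(onset_s = mk$onset_s, image_index = mk$image_index,
                      is_target = as.logical(mk$is_target), trial = mk$trial)
  if (nrow(sched) > 1) attr(sched, "soa") <- min(diff(sched$onset_s))
  class(sched) <- c("stimulus_schedule", "data.frame")
  structure(
    list(samples = cbind(O1 = sig$O1, O2 = sig$O2),
         sampling_rate = round(fs, 6), channel_names = c("O1", "O2"),
         schedule = sched),
    class = "eeg_recording")
}

## ---- EDF ----

.EDF_PHYS_MIN <- -327.68
.EDF_PHYS_MAX <- 327.67
.EDF_ANNOT_SAMPLES <- 128L  # 256 bytes of TAL space per 1 s record

edf_field <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stopf("EDF header field too long: '%s'", s)
  formatC(s, width = -width)
}

write_recording_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stopf("EDF output requires an integer sampling rate (got %g)", fs)
  fs <- as.integer(fs)
  x <- recording$samples
  n <- nrow(x)
  n_rec <- as.integer(ceiling(n / fs))
  if (any(abs(x) > .EDF_PHYS_MAX)) {
    warnf("samples outside +/-%.2f uV clipped for EDF storage", .EDF_PHYS_MAX)
  }
  dig <- matrix(pmin(32767L, pmax(-32768L, as.integer(round(x * 100)))),
                nrow = n)
  pad <- n_rec * fs - n
  if (pad > 0) dig <- rbind(dig, matrix(0L, pad, 2))

  ns <- 3L  # O1, O2, annotations
  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, eos = NULL)
  # fixed header (256 bytes)
  wch(edf_field("0", 8))
  wch(edf_field("X X X X", 80))
  wch(edf_field("Startdate 01-JAN-2000 X X X", 80))
  wch(edf_field("01.01.00", 8))
  wch(edf_field("00.00.00", 8))
  wch(edf_field(256 * (ns + 1), 8))
  wch(edf_field("EDF+C", 44))
  wch(edf_field(n_rec, 8))
  wch(edf_field("1", 8))
  wch(edf_field(ns, 4))
  # signal headers (field-major layout)
  labels <- c(recording$channel_names[1:2], "EDF Annotations")
  for (l in labels) wch(edf_field(l, 16))
  for (i in 1:ns) wch(edf_field("", 80))                       # transducer
  for (d in c("uV", "uV", "")) wch(edf_field(d, 8))            # phys dim
  for (v in c(.EDF_PHYS_MIN, .EDF_PHYS_MIN, -1)) wch(edf_field(v, 8))
  for (v in c(.EDF_PHYS_MAX, .EDF_PHYS_MAX, 1)) wch(edf_field(v, 8))
  for (i in 1:ns) wch(edf_field("-32768", 8))                  # dig min
  for (i in 1:ns) wch(edf_field("32767", 8))                   # dig max
  for (i in 1:ns) wch(edf_field("", 80))                       # prefilter
  for (v in c(fs, fs, .EDF_ANNOT_SAMPLES)) wch(edf_field(v, 8))
  for (i in 1:ns) wch(edf_field("", 32))

  sched <- recording$schedule
  for (r in seq_len(n_rec) - 1L) {
    idx <- (r * fs + 1):((r + 1) * fs)
    writeBin(dig[idx, 1], con, size = 2, endian = "little")
    writeBin(dig[idx, 2], con, size = 2, endian = "little")
    writeBin(edf_annotation_record(sched, r), con)
  }
  invisible(path)
}

# Build one record's TAL bytes: a record-start timestamp TAL followed by one
# TAL per flash whose onset falls inside [r, r+1) seconds.
edf_annotation_record <- function(sched, r) {
  tal <- c(charToRaw(sprintf("+%d", r)), as.raw(c(0x14, 0x14, 0x00)))
  if (!is.null(sched) && nrow(sched) > 0) {
    ev <- sched[sched$onset_s >= r & sched$onset_s < r + 1, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      desc <- sprintf("flash image=%d target=%d trial=%d",
                      ev$image_index[i], as.integer(ev$is_target[i]),
                      ev$trial[i])
      tal <- c(tal, charToRaw(sprintf("+%.4f", ev$onset_s[i])),
               as.raw(0x14), charToRaw(desc), as.raw(c(0x14, 0x00)))
    }
  }
  nbytes <- 2L * .EDF_ANNOT_SAMPLES
  if (length(tal) > nbytes) {
    stopf("EDF annotation record overflow (%d > %d bytes)", length(tal), nbytes)
  }
  c(tal, raw(nbytes - length(tal)))
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rch <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rch(8); rch(80); rch(80); rch(8); rch(8)
  rch(8)                      # header bytes
  rch(44)
  n_rec <- as.integer(rch(8))
  rec_dur <- as.numeric(rch(8))
  ns <- as.integer(rch(4))
  labels <- vapply(1:ns, function(i) rch(16), "")
  for (i in 1:ns) rch(80)
  dims <- vapply(1:ns, function(i) rch(8), "")
  pmin_ <- as.numeric(vapply(1:ns, function(i) rch(8), ""))
  pmax_ <- as.numeric(vapply(1:ns, function(i) rch(8), ""))
  dmin_ <- as.numeric(vapply(1:ns, function(i) rch(8), ""))
  dmax_ <- as.numeric(vapply(1:ns, function(i) rch(8), ""))
  for (i in 1:ns) rch(80)
  spr <- as.integer(vapply(1:ns, function(i) rch(8), ""))
  for (i in 1:ns) rch(32)

  annot_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), annot_idx)
  out <- lapply(sig_idx, function(i) numeric(n_rec * spr[i]))
  names(out) <- labels[sig_idx]
  tal_raw <- raw(0)
  for (r in seq_len(n_rec) - 1L) {
    for (i in seq_len(ns)) {
      if (i %in% annot_idx) {
        tal_raw <- c(tal_raw, readBin(con, "raw", 2L * spr[i]))
      } else {
        d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        k <- match(i, sig_idx)
        scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
        out[[k]][(r * spr[i] + 1):((r + 1) * spr[i])] <-
          (d - dmin_[i]) * scale + pmin_[i]
      }
    }
  }
  sched <- parse_edf_annotations(tal_raw)
  fs <- spr[sig_idx[1]] / rec_dur
  structure(
    list(samples = do.call(cbind, out), sampling_rate = fs,
         channel_names = labels[sig_idx], schedule = sched),
    class = "eeg_recording")
}

parse_edf_annotations <- function(tal_raw) {
  txt <- rawToChar(tal_raw[tal_raw != as.raw(0)], multiple = FALSE)
  tals <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
  events <- list()
  i <- 1
  while (i < length(tals)) {
    onset <- suppressWarnings(as.numeric(tals[i]))
    desc <- tals[i + 1]
    if (!is.na(onset) && nzchar(desc) && grepl("^flash ", desc)) {
      m <- regmatches(desc, regexec(
        "flash image=(\\d+) target=(\\d+) trial=(\\d+)", desc))[[1]]
      if (length(m) == 4) {
        events[[length(events) + 1]] <- data.frame(
          onset_s = onset, image_index = as.integer(m[2]),
          is_target = m[3] == "1", trial = as.integer(m[4]))
      }
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) return(NULL)
  sched <- do.call(rbind, events)
  sched <- sched[order(sched$onset_s), , drop = FALSE]
  rownames(sched) <- NULL
  if (nrow(sched) > 1) attr(sched, "soa") <- min(diff(sched$onset_s))
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}
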