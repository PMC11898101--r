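# Minimal EDF/EDF+ support: 16-bit signals, one-second data records, and
# (for EDF+) a time-stamped annotation channel carrying seizure intervals
# as TALs. Covers what the pipeline needs; not a general-purpose EDF
# library.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording as EDF+ (or plain EDF)
#'
#' Signals are scaled per channel to the 16-bit digital range; with
#' `annotations = TRUE` an EDF Annotations channel is added holding a
#' time-keeping TAL per record plus one TAL per annotated interval
#' (onset, duration, label). Record duration is 1 s, so `fs` must be a
#' whole number of samples per second.
#'
#' @param rec An [eeg_recording()]; its duration is truncated to whole
#'   records.
#' @param path Output file.
#' @param annotations Write the EDF+ annotation channel.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, annotations = TRUE) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n_rec <- ncol(rec$signals) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)",
                       call. = FALSE)
  nch <- nrow(rec$signals)
  sig <- rec$signals[, seq_len(n_rec * fs), drop = FALSE]
  pmaxs <- pmax(apply(abs(sig), 1, max), 1) * 1.0001
  dig <- 32767
  ann_tals <- if (annotations) build_tals(rec$annotations, n_rec) else NULL
  ann_len <- if (annotations) {
    max(64L, 2L * ceiling(max(vapply(ann_tals, length, 1L)) / 2L))
  } else 0L
  ns <- nch + as.integer(annotations)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_pad("0", 8))
  wr(edf_pad(paste("X X X", rec$id), 80))
  wr(edf_pad("Startdate 01-JAN-2000 X X X", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (1 + ns), 8))
  wr(edf_pad(if (annotations) "EDF+C" else "", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_pad(1, 8)); wr(edf_pad(ns, 4))
  lab <- c(rec$channel_names, if (annotations) "EDF Annotations")
  for (l in lab) wr(edf_pad(l, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))                 # transducer
  wr(paste(vapply(seq_len(ns), function(i)
    edf_pad(if (i <= nch) "uV" else "", 8), "")
    , collapse = ""))
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) -pmaxs[i] else -1, 8))
  for (i in seq_len(ns)) wr(edf_num(if (i <= nch) pmaxs[i] else 1, 8))
  for (i in seq_len(ns)) wr(edf_pad(if (i <= nch) -dig else -32768, 8))
  for (i in seq_len(ns)) wr(edf_pad(dig, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))                 # prefilter
  for (i in seq_len(ns)) {
    wr(edf_pad(if (i <= nch) fs else ann_len %/% 2L, 8))
  }
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  scale <- dig / pmaxs
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch)) {
      writeBin(as.integer(round(sig[i, idx] * scale[i])), con,
               size = 2, endian = "little")
    }
    if (annotations) {
      tal <- ann_tals[[r]]
      pad <- raw(ann_len - length(tal))
      writeBin(c(tal, pad), con)
    }
  }
  invisible(path)
}

# per-record TAL byte strings: record r carries its timestamp TAL and any
# annotation whose onset falls inside [r-1, r) seconds
build_tals <- function(ann, n_rec) {
  lapply(seq_len(n_rec), function(r) {
    t0 <- r - 1L
    bytes <- charToRaw(sprintf("+%d", t0))
    bytes <- c(bytes, as.raw(c(0x14, 0x14, 0x00)))
    if (nrow(ann)) {
      inside <- which(ann$onset_s >= t0 & ann$onset_s < t0 + 1)
      for (i in inside) {
        ev <- sprintf("+%.3f\x15%.3f\x14%s\x14", ann$onset_s[i],
                      ann$offset_s[i] - ann$onset_s[i], ann$label[i])
        bytes <- c(bytes, charToRaw(ev), as.raw(0x00))
      }
    }
    bytes
  })
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, decodes the 16-bit signals back to physical units,
#' and (for EDF+) collects annotations from the TAL records. A sidecar
#' CSV with columns `onset_s`, `offset_s`, `label` can be supplied for
#' plain EDF files.
#'
#' @param path EDF file.
#' @param annotations_csv Optional sidecar annotation CSV.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, annotations_csv = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (length(s) == 0) stop("truncated EDF header", call. = FALSE)
    trimws(s)
  }
  rd(8)                                    # version
  pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)                                   # reserved / EDF+ flag
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  out <- lapply(sig_idx, function(i) numeric(n_rec * spr[i]))
  names(out) <- labels[sig_idx]
  tal_bytes <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        tal_bytes <- c(tal_bytes, readBin(con, "raw", 2L * spr[i]))
      } else {
        v <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        if (length(v) < spr[i]) stop("truncated EDF data", call. = FALSE)
        j <- match(i, sig_idx)
        out[[j]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
          pmin_[i] + (v - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      }
    }
  }
  fs <- spr[sig_idx[1]] / rec_dur
  ann <- parse_tals(tal_bytes)
  if (!is.null(annotations_csv)) {
    extra <- utils::read.csv(annotations_csv, stringsAsFactors = FALSE)
    ann <- rbind(ann, extra[, c("onset_s", "offset_s", "label")])
  }
  sigm <- do.call(rbind, out)
  eeg_recording(sigm, fs, labels[sig_idx], ann,
                id = sub("^X X X ?", "", pid))
}

# events are written as "+onset\x15duration\x14label\x14"; time-keeping
# TALs ("+t\x14\x14") carry no \x15 and are skipped by the pattern
parse_tals <- function(bytes) {
  ann <- empty_annotations()
  if (!length(bytes)) return(ann)
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  m <- regmatches(txt, gregexpr("[+-][0-9.]+\x15[0-9.]+\x14[^\x14]+", txt))[[1]]
  for (ev in m) {
    f <- strsplit(ev, "[\x14\x15]")[[1]]
    onset <- as.numeric(f[1]); duration <- as.numeric(f[2])
    ann <- rbind(ann, data.frame(onset_s = onset,
                                 offset_s = onset + duration,
                                 label = f[3]))
  }
  unique(ann)
}
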