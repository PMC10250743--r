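# Minimal EDF/EDF+ reader and writer (16-bit, equal-rate EEG signals).
# Written in base R because no EDF package ships with the analysis stack;
# covers the subset of the format this pipeline needs: one common sampling
# rate, amplitude units uV/mV/V, 1-second data records.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records and per-channel symmetric
#' physical ranges in uV. If the sample count is not a whole number of
#' seconds, the final record is padded by repeating the last sample (the
#' reader cannot distinguish padding; keep whole-second recordings for
#' lossless round trips up to 16-bit quantization).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @export
write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer fs")
  fs <- as.integer(round(fs))
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- as.integer(ceiling(n / fs))
  data <- rec$data
  if (n_rec * fs > n) {                      # pad final partial record
    pad <- matrix(data[, n], nrow = n_ch, ncol = n_rec * fs - n)
    data <- cbind(data, pad)
  }
  pmax_v <- pmax(apply(abs(data), 1, max), 1)
  pmin_v <- -pmax_v
  dmax <- 32767L; dmin <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(paste("X X X", ifelse(is.na(rec$subject_id), "X", rec$subject_id)), 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 + 256 * n_ch, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_names, 16)
  field(rep("", n_ch), 80)                      # transducer
  field(rep("uV", n_ch), 8)                     # physical dimension
  writeChar(paste0(vapply(pmin_v, .edf_num, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(vapply(pmax_v, .edf_num, "", width = 8), collapse = ""),
            con, eos = NULL)
  field(rep(dmin, n_ch), 8)
  field(rep(dmax, n_ch), 8)
  field(rep("", n_ch), 80)                      # prefiltering
  field(rep(fs, n_ch), 8)                       # samples per record
  field(rep("", n_ch), 32)

  scale <- (pmax_v - pmin_v) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(n_ch)) {
      dig <- round((data[ch, cols] - pmin_v[ch]) / scale[ch]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the EDF header, requires all signals to share one sampling rate
#' (annotation-only channels are not supported), and converts amplitudes to
#' microvolts using the header physical dimension (uV, mV or V).
#'
#' @param path EDF file path.
#' @param subject_id,device,task Metadata to attach (EDF patient field is
#'   ignored for pipeline purposes).
#' @return An `eeg_recording` in uV.
#' @export
read_recording_edf <- function(path, subject_id = NA_character_,
                               device = NA_character_, task = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) {
    rawToChar(readBin(con, "raw", nbytes))
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient/recording/date/time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  n_ch <- as.integer(trimws(rd(4)))
  if (is.na(n_ch) || n_ch < 1) stop("invalid EDF header: signal count")

  rdv <- function(width) {
    vapply(seq_len(n_ch), function(i) trimws(rd(width)), "")
  }
  labels <- rdv(16)
  rdv(80)                                 # transducer
  dims <- rdv(8)
  pmin_v <- as.numeric(rdv(8))
  pmax_v <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                                 # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)

  if (length(unique(spr)) != 1L) {
    stop("unsupported layout: signals with mixed sampling rates (",
         paste(unique(spr), collapse = ", "), " samples/record)")
  }
  to_uv <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
           stop("unit error: unknown physical dimension '", d, "'"))
  }, 0)
  fs <- spr[1] / rec_dur
  scale <- (pmax_v - pmin_v) / (dmax - dmin)

  data <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      phys <- (dig - dmin[ch]) * scale[ch] + pmin_v[ch]
      data[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- phys * to_uv[ch]
    }
  }
  new_recording(data, fs = fs,
                channel_names = normalize_channel_names(labels),
                subject_id = subject_id, device = device, task = task)
}
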