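#' Construct a recording object
#'
#' A multi-channel sampled EEG segment in microvolts with an annotation
#' track. Annotations are rows of (onset, duration, label) in seconds from
#' recording start; labels used by the pipeline are `STIM_BLOCK`,
#' `POST_WINDOW` and `STAGE_*`.
#'
#' @param samples channels x time numeric matrix (uV); rownames are
#'   channel labels (10-20 names)
#' @param fs sampling rate in Hz
#' @param annotations data frame with columns onset, duration, label
#' @param subject,condition metadata
#' @return an object of class `psg_recording`
#' @export
recording <- function(samples, fs, annotations = NULL, subject = NA_character_,
                      condition = NA_character_) {
  if (is.null(dim(samples))) {
    samples <- matrix(samples, nrow = 1, dimnames = list("Fz", NULL))
  }
  stopifnot(is.matrix(samples), fs > 0)
  if (is.null(rownames(samples))) {
    rownames(samples) <- paste0("ch", seq_len(nrow(samples)))
  }
  if (anyDuplicated(rownames(samples))) stop("channel labels must be unique")
  if (is.null(annotations)) {
    annotations <- data.frame(onset = numeric(0), duration = numeric(0),
                              label = character(0), stringsAsFactors = FALSE)
  }
  dur <- ncol(samples) / fs
  if (nrow(annotations) && any(annotations$onset < 0 |
                               annotations$onset > dur)) {
    stop("annotation onsets must lie within the recording")
  }
  structure(list(samples = samples, fs = fs,
                 channels = rownames(samples),
                 annotations = annotations,
                 meta = list(subject = subject, condition = condition)),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d ch x %.1f s @ %g Hz (%s / %s), %d annotations\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
              x$meta$subject, x$meta$condition, nrow(x$annotations)))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$samples) / rec$fs

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

sidecar_path <- function(path) sub("\\.edf$", "_annotations.csv", path,
                                   ignore.case = TRUE)

#' Write a recording to EDF with a sidecar annotation file
#'
#' Writes a standard 16-bit EDF file (one-second data records, physical
#' units uV) plus a sidecar CSV (`*_annotations.csv` with columns onset_s,
#' duration_s, label). The trailing partial record, if any, is zero-padded;
#' the true sample count is kept in the header reserved field so that
#' [read_recording()] restores the exact length.
#'
#' @param rec a [recording()]
#' @param path output path (`.edf`)
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  spr <- round(rec$fs)  # samples per 1-s record
  if (abs(spr - rec$fs) > 1e-9) stop("EDF writer requires integer fs")
  nrec <- ceiling(n / spr)
  pmaxs <- pmax(apply(abs(rec$samples), 1, max), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field(sprintf("subject=%s condition=%s", rec$meta$subject,
                      rec$meta$condition), 80),
    pad_field("sleeposc synthetic recording", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field(sprintf("NSAMP=%d", n), 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(ns, 4)),
    con, eos = NULL)
  writeChar(paste0(
    paste0(pad_field(rec$channels, 16), collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),
    paste0(rep(pad_field("uV", 8), ns), collapse = ""),
    paste0(pad_field(sprintf("%.6g", -pmaxs), 8), collapse = ""),
    paste0(pad_field(sprintf("%.6g", pmaxs), 8), collapse = ""),
    paste0(rep(pad_field("-32767", 8), ns), collapse = ""),
    paste0(rep(pad_field("32767", 8), ns), collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),
    paste0(rep(pad_field(spr, 8), ns), collapse = ""),
    paste0(rep(pad_field("", 32), ns), collapse = "")),
    con, eos = NULL)
  padded <- cbind(rec$samples,
                  matrix(0, ns, nrec * spr - n))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(padded[ch, idx] / pmaxs[ch] * 32767))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  utils::write.csv(
    data.frame(onset_s = rec$annotations$onset,
               duration_s = rec$annotations$duration,
               label = rec$annotations$label),
    sidecar_path(path), row.names = FALSE)
  invisible(path)
}

read_header_field <- function(raw, at, width) {
  trimws(rawToChar(raw[(at + 1):(at + width)]))
}

#' Read a recording from EDF plus sidecar annotations
#'
#' @param path path to an `.edf` file written by [write_recording()] (or
#'   any single-rate, uV-scaled 16-bit EDF)
#' @return a [recording()]
#' @export
read_recording <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 256) stop("corrupt EDF header: file too short")
  patient <- read_header_field(raw, 8, 80)
  reserved <- read_header_field(raw, 184, 44)
  nrec <- as.integer(read_header_field(raw, 236, 8))
  rec_dur <- as.numeric(read_header_field(raw, 244, 8))
  ns <- as.integer(read_header_field(raw, 252, 4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: bad signal count")
  hend <- 256 + 256 * ns
  if (length(raw) < hend) stop("corrupt EDF header: truncated signal headers")
  # per-signal header blocks: label 16, transducer 80, phys dim 8,
  # phys min 8, phys max 8, dig min 8, dig max 8, prefilter 80, nsamp 8
  gf <- function(off, w) vapply(seq_len(ns) - 1L, function(i) {
    read_header_field(raw, 256 + off * ns + i * w, w)
  }, character(1))
  labels <- gf(0, 16)
  pmin_ <- as.numeric(gf(104, 8))
  pmax_ <- as.numeric(gf(112, 8))
  dmin_ <- as.numeric(gf(120, 8))
  dmax_ <- as.numeric(gf(128, 8))
  spr <- as.integer(gf(216, 8))
  if (length(unique(spr)) != 1L) stop("channels disagree on sampling rate")
  fs <- spr[1] / rec_dur
  expected <- hend + nrec * sum(spr) * 2
  if (length(raw) < expected) stop("corrupt EDF: data shorter than header claims")
  dat <- readBin(raw[(hend + 1):expected], "integer", n = nrec * sum(spr),
                 size = 2, signed = TRUE, endian = "little")
  sig <- matrix(0, ns, nrec * spr[1], dimnames = list(labels, NULL))
  pos <- 0L
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      sig[ch, idx] <- dat[(pos + 1L):(pos + spr[ch])]
      pos <- pos + spr[ch]
    }
  }
  for (ch in seq_len(ns)) {
    scale <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
    sig[ch, ] <- (sig[ch, ] - dmin_[ch]) * scale + pmin_[ch]
  }
  nsamp <- suppressWarnings(
    as.integer(sub("NSAMP=", "", reserved, fixed = TRUE)))
  if (!is.na(nsamp) && nsamp <= ncol(sig)) sig <- sig[, seq_len(nsamp),
                                                      drop = FALSE]
  subj <- sub(".*subject=(\\S+).*", "\\1", patient)
  cond <- sub(".*condition=(\\S+).*", "\\1", patient)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    a <- utils::read.csv(sc, stringsAsFactors = FALSE)
    ann <- data.frame(onset = a$onset_s, duration = a$duration_s,
                      label = a$label, stringsAsFactors = FALSE)
  } else {
    warning("no sidecar annotation file found; annotations empty")
    ann <- NULL
  }
  recording(sig, fs, annotations = ann, subject = subj, condition = cond)
}

# Biquad notch coefficients (RBJ cookbook), centre f0, quality Q.
notch_biquad <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter at a base frequency and its harmonics
#'
#' Cascaded second-order IIR notches (Q = 30) at `base`, `2*base`, ... up
#' to Nyquist, applied forward-backward (zero phase).
#'
#' @param rec a [recording()] or a numeric signal
#' @param base base (line) frequency in Hz
#' @param fs sampling rate, required when `rec` is a plain signal
#' @param Q notch quality factor
#' @return filtered recording or signal
#' @export
notch_filter <- function(rec, base = 50, fs = NULL, Q = 30) {
  if (inherits(rec, "psg_recording")) {
    out <- rec
    out$samples <- t(apply(rec$samples, 1, notch_filter, base = base,
                           fs = rec$fs, Q = Q))
    dimnames(out$samples) <- dimnames(rec$samples)
    return(out)
  }
  if (is.null(fs)) stop("fs required for plain signals")
  if (base >= fs / 2) stop("notch base frequency must be below Nyquist")
  x <- as.numeric(rec)
  for (f0 in seq(base, fs / 2 - 1e-9, by = base)) {
    co <- notch_biquad(f0, fs, Q)
    x <- signal::filtfilt(signal::Arma(b = co$b, a = co$a), x)
  }
  x
}

# Anti-aliased resampling: zero-phase windowed-sinc lowpass at 0.45 * target
# rate, then cubic-spline regridding. Annotation times stay in seconds.
resample_signal <- function(x, fs, target_fs) {
  if (target_fs > fs) stop("upsampling is not supported")
  if (target_fs == fs) return(as.numeric(x))
  fc <- 0.45 * target_fs
  ntaps <- ceiling(3.3 / (0.1 * 2 * fc / fs))
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  ntaps <- min(ntaps, 2L * floor((length(x) - 1L) / 2L) + 1L)
  y <- filt_zero_phase(as.numeric(x), fir_lowpass(fc, fs, ntaps))
  tin <- (seq_along(x) - 1) / fs
  tout <- seq(0, tin[length(tin)], by = 1 / target_fs)
  stats::spline(tin, y, xout = tout)$y
}

#' Resample a recording
#'
#' @param rec a [recording()] or numeric signal
#' @param target_fs target sampling rate in Hz (must not exceed fs)
#' @param fs sampling rate when `rec` is a plain signal
#' @return resampled recording or signal
#' @export
resample <- function(rec, target_fs = 200, fs = NULL) {
  if (inherits(rec, "psg_recording")) {
    if (target_fs == rec$fs) return(rec)
    sig <- t(apply(rec$samples, 1, resample_signal, fs = rec$fs,
                   target_fs = target_fs))
    rownames(sig) <- rec$channels
    out <- recording(sig, target_fs, rec$annotations,
                     rec$meta$subject, rec$meta$condition)
    return(out)
  }
  if (is.null(fs)) stop("fs required for plain signals")
  resample_signal(rec, fs, target_fs)
}

#' Extract post-block analysis intervals and the pre-stimulation baseline
#'
#' One 60-s `post_block` interval starting at each stimulation block
#' offset (clipped at the next block onset or the recording end; clipped
#' intervals are flagged and excluded by default), plus one 60-s
#' `pre_stim_baseline` ending at the first block onset.
#'
#' @param rec a [recording()] with `STIM_BLOCK` annotations
#' @param include_clipped keep clipped post windows instead of dropping them
#' @param window_len interval length in seconds
#' @return data frame with columns start, stop, kind, block_index, clipped
#' @export
extract_intervals <- function(rec, include_clipped = FALSE,
                              window_len = 60) {
  stopifnot(inherits(rec, "psg_recording"))
  ann <- rec$annotations
  blocks <- ann[ann$label == "STIM_BLOCK", , drop = FALSE]
  if (nrow(blocks) == 0) {
    warning("no stimulation blocks annotated; no intervals extracted")
    return(data.frame(start = numeric(0), stop = numeric(0),
                      kind = character(0), block_index = integer(0),
                      clipped = logical(0)))
  }
  blocks <- blocks[order(blocks$onset), ]
  offs <- blocks$onset + blocks$duration
  next_onset <- c(blocks$onset[-1], Inf)
  stop_t <- pmin(offs + window_len, next_onset, rec_duration(rec))
  post <- data.frame(start = offs, stop = stop_t, kind = "post_block",
                     block_index = seq_len(nrow(blocks)),
                     clipped = (stop_t - offs) < window_len - 1e-9,
                     stringsAsFactors = FALSE)
  b0 <- max(0, blocks$onset[1] - window_len)
  base <- data.frame(start = b0, stop = blocks$onset[1],
                     kind = "pre_stim_baseline", block_index = 0L,
                     clipped = (blocks$onset[1] - b0) < window_len - 1e-9,
                     stringsAsFactors = FALSE)
  if (!include_clipped) post <- post[!post$clipped, , drop = FALSE]
  out <- rbind(base, post)
  rownames(out) <- NULL
  out
}

#' Select the analysis channel
#'
#' Returns the first channel in the preference order that is present and
#' not flagged bad (fronto-central derivation: Fz, falling back to FC1 or
#' FC2 on noise).
#'
#' @param rec a [recording()]
#' @param preference channel labels in preference order
#' @param bad labels flagged as bad
#' @return list with `channel` (label) and `signal` (numeric vector)
#' @export
select_channel <- function(rec, preference = c("Fz", "FC1", "FC2"),
                           bad = character(0)) {
  stopifnot(inherits(rec, "psg_recording"))
  ok <- preference[preference %in% rec$channels & !(preference %in% bad)]
  if (length(ok) == 0) stop("no usable channel among: ",
                            paste(preference, collapse = ", "))
  list(channel = ok[1], signal = as.numeric(rec$samples[ok[1], ]))
}

# Cut a signal segment [start, stop) in seconds from a recording channel.
cut_segment <- function(signal, fs, start, stop) {
  i0 <- max(1L, floor(start * fs) + 1L)
  i1 <- min(length(signal), floor(stop * fs))
  signal[i0:i1]
}
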