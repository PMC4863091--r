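# Minimal EDF+ writer/reader: 16-bit signals, one data record per second,
# cue/arm markers as EDF+ annotation TALs. Covers exactly what this package
# writes (continuous blocks of equal-length cue-referenced trials); it is not
# a general-purpose EDF library.

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf(sprintf("%%-%ds", width), s)
}

fmt_tal_time <- function(t) {
  if (abs(t - round(t)) < 1e-9) sprintf("%+d", round(t))
  else sub("\\+?", "+", formatC(t, digits = 7, format = "fg", flag = ""))
}

ANNOT_NS <- 80L  # 160 bytes of annotation space per record

write_session_edf <- function(session, path) {
  trs <- session$trials
  if (!length(trs)) {
    # an empty session still yields a valid (trial-less) sidecar marker
    writeLines("moveintent-edf-v1 empty", file.path(path, "blocks.txt"))
    return(invisible(path))
  }
  if (any(vapply(trs, `[[`, "", "time_ref") != "cue"))
    stop("EDF export requires cue-referenced trials")
  ns_trial <- ncol(trs[[1]]$eeg)
  if (any(vapply(trs, function(x) ncol(x$eeg), 0L) != ns_trial))
    stop("EDF export requires equal-length trials")
  fs <- session$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  trial_dur <- ns_trial / fs
  if (abs(trial_dur - round(trial_dur)) > 1e-9)
    stop("EDF export requires whole-second trials")
  blocks <- split(seq_along(trs), vapply(trs, `[[`, 1L, "block"))
  files <- character(0)
  for (b in names(blocks)) {
    f <- file.path(path, sprintf("block%02d.edf", as.integer(b)))
    edf_write_block(session, blocks[[b]], f)
    files <- c(files, basename(f))
  }
  writeLines(c("moveintent-edf-v1", files), file.path(path, "blocks.txt"))
  invisible(path)
}

edf_write_block <- function(session, idx, file) {
  trs <- session$trials[idx]
  fs <- round(session$fs)
  labels <- c(session$eeg_labels, session$emg_labels)
  nsig <- length(labels) + 1L                  # + annotations
  ns_trial <- ncol(trs[[1]]$eeg)
  trial_dur <- ns_trial / fs
  n_rec <- as.integer(length(trs) * trial_dur)  # 1-s records
  data <- do.call(cbind, lapply(trs, function(tr) rbind(tr$eeg, tr$emg)))

  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # physical bounds rounded outward to 3 decimals: representable in the
  # 8-char header field (amplitudes here are well below 1000 uV) and
  # guaranteed to bound the data, so the reader sees the exact same scale
  pmin_h <- floor(pmin * 1000) / 1000
  pmax_h <- ceiling(pmax * 1000) / 1000
  if (any(abs(c(pmin_h, pmax_h)) >= 9999))
    stop("signal amplitude too large for the EDF physical-range field")
  pmin_s <- vapply(pmin_h, function(v) edf_pad(sprintf("%.3f", v), 8), "")
  pmax_s <- vapply(pmax_h, function(v) edf_pad(sprintf("%.3f", v), 8), "")
  pmin_h <- as.numeric(pmin_s)
  pmax_h <- as.numeric(pmax_s)

  con <- file(file, "wb")
  on.exit(close(con))
  wc <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wc(edf_pad("0", 8))
  wc(edf_pad(session$subject, 80))
  wc(edf_pad("Startdate 01-JAN-2000 moveintent block", 80))
  wc("01.01.00"); wc("00.00.00")
  wc(edf_pad(as.character(256L * (nsig + 1L)), 8))
  wc(edf_pad("EDF+C", 44))
  wc(edf_pad(as.character(n_rec), 8))
  wc(edf_pad("1", 8))
  wc(edf_pad(as.character(nsig), 4))
  wc(paste0(vapply(c(labels, "EDF Annotations"), edf_pad, "", width = 16),
            collapse = ""))
  wc(strrep(" ", 80 * nsig))                   # transducer
  wc(paste0(c(rep(edf_pad("uV", 8), length(labels)), edf_pad("", 8)),
            collapse = ""))
  wc(paste0(c(pmin_s, edf_pad("-1", 8)), collapse = ""))
  wc(paste0(c(pmax_s, edf_pad("1", 8)), collapse = ""))
  wc(paste0(rep(edf_pad("-32768", 8), nsig), collapse = ""))
  wc(paste0(rep(edf_pad("32767", 8), nsig), collapse = ""))
  wc(strrep(" ", 80 * nsig))                   # prefiltering
  wc(paste0(vapply(c(rep(fs, length(labels)), ANNOT_NS), function(v)
    edf_pad(as.character(v), 8), ""), collapse = ""))
  wc(strrep(" ", 32 * nsig))                   # reserved

  scale <- (pmax_h - pmin_h) / 65535
  events <- list()
  for (j in seq_along(trs)) {
    t_start <- (j - 1) * trial_dur
    tr <- trs[[j]]
    events[[length(events) + 1]] <-
      list(t = t_start, text = sprintf("trial arm=%s", tr$arm))
    for (ci in seq_along(tr$cues))
      events[[length(events) + 1]] <-
        list(t = t_start + unname(tr$cues[ci]), text = names(tr$cues)[ci])
  }
  ev_t <- vapply(events, `[[`, 0, "t")
  for (r in seq_len(n_rec)) {
    t0 <- r - 1L
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_along(labels)) {
      dig <- as.integer(round((data[s, cols] - pmin_h[s]) / scale[s])) - 32768L
      dig <- pmax(pmin(dig, 32767L), -32768L)
      writeBin(dig, con, size = 2, endian = "little")
    }
    tals <- list(paste0(fmt_tal_time(t0), "\x14\x14"))
    in_rec <- which(ev_t >= t0 & ev_t < t0 + 1)
    for (i in in_rec)
      tals <- c(tals, paste0(fmt_tal_time(ev_t[i]), "\x14",
                             events[[i]]$text, "\x14"))
    raw <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
    if (length(raw) > 2L * ANNOT_NS) stop("annotation record overflow")
    writeBin(c(raw, raw(2L * ANNOT_NS - length(raw))), con)
  }
  invisible(file)
}

read_session_edf <- function(path) {
  listing <- file.path(path, "blocks.txt")
  files <- if (file.exists(listing)) {
    lines <- readLines(listing)
    if (identical(lines, "moveintent-edf-v1 empty"))
      return(new_session(list(), fs = 0, subject = "unknown",
                         eeg_labels = character(0), emg_labels = character(0)))
    file.path(path, lines[-1])
  } else {
    sort(Sys.glob(file.path(path, "*.edf")))
  }
  trials <- list()
  fs <- NULL; subject <- NULL; eeg_labels <- NULL; emg_labels <- NULL
  for (bi in seq_along(files)) {
    blk <- edf_read_block(files[bi])
    if (is.null(fs)) {
      fs <- blk$fs; subject <- blk$subject
      is_emg <- blk$labels %in% EMG_LABELS_4
      eeg_labels <- blk$labels[!is_emg]
      emg_labels <- blk$labels[is_emg]
    }
    starts <- blk$events$t[grepl("^trial ", blk$events$text)]
    arms <- sub("^trial arm=", "", blk$events$text[grepl("^trial ", blk$events$text)])
    n_total <- ncol(blk$data)
    bounds <- c(starts, n_total / fs)
    for (j in seq_along(starts)) {
      cols <- (round(starts[j] * fs) + 1L):round(bounds[j + 1] * fs)
      cue_ev <- blk$events[blk$events$t >= starts[j] &
                             blk$events$t < bounds[j + 1] &
                             grepl("^cue", blk$events$text), ]
      cues <- cue_ev$t - starts[j]
      names(cues) <- cue_ev$text
      trials[[length(trials) + 1]] <- new_trial(
        blk$data[!blk$labels %in% EMG_LABELS_4, cols, drop = FALSE],
        blk$data[blk$labels %in% EMG_LABELS_4, cols, drop = FALSE],
        fs, t0 = 0, cues = cues[order(cues)], arm = arms[j],
        time_ref = "cue", block = bi)
    }
  }
  new_session(trials, fs, subject = subject,
              eeg_labels = eeg_labels, emg_labels = emg_labels)
}

edf_read_block <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rc <- function(n) readChar(con, n, useBytes = TRUE)
  rc(8)
  subject <- trimws(rc(80))
  rc(80); rc(8); rc(8)
  rc(8)                                        # header bytes
  rc(44)
  n_rec <- as.integer(rc(8))
  rec_dur <- as.numeric(rc(8))
  nsig <- as.integer(rc(4))
  rd_field <- function(width) {
    vapply(seq_len(nsig), function(i) trimws(rc(width)), "")
  }
  labels <- rd_field(16)
  rd_field(80)
  rd_field(8)                                  # dimension
  pmin <- as.numeric(rd_field(8))
  pmax <- as.numeric(rd_field(8))
  dmin <- as.numeric(rd_field(8))
  dmax <- as.numeric(rd_field(8))
  rd_field(80)
  ns <- as.integer(rd_field(8))
  rd_field(32)
  if (any(is.na(ns)) || any(is.na(n_rec)))
    stop("parse error in EDF header of ", basename(file))
  is_annot <- labels == "EDF Annotations"
  data_rows <- which(!is_annot)
  fs <- ns[data_rows[1]] / rec_dur
  data <- matrix(0, length(data_rows), n_rec * ns[data_rows[1]])
  ev_t <- numeric(0); ev_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(nsig)) {
      if (is_annot[s]) {
        raw <- readBin(con, "raw", n = 2L * ns[s])
        # TALs are NUL-separated; split the raw bytes on 0x00
        zero <- raw == as.raw(0)
        grp <- cumsum(zero)
        pieces <- split(raw[!zero], grp[!zero])
        tals <- vapply(pieces, rawToChar, "")
        tals <- tals[nzchar(tals)]
        for (tal in tals) {
          parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
          if (length(parts) < 2) next           # record timestamp TAL
          onset <- as.numeric(strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1])
          for (txt in parts[-1]) if (nzchar(txt)) {
            ev_t <- c(ev_t, onset); ev_text <- c(ev_text, txt)
          }
        }
      } else {
        dig <- readBin(con, "integer", n = ns[s], size = 2, signed = TRUE,
                       endian = "little")
        row <- match(s, data_rows)
        cols <- ((r - 1L) * ns[s] + 1L):(r * ns[s])
        data[row, cols] <- (dig - dmin[s]) * (pmax[s] - pmin[s]) /
          (dmax[s] - dmin[s]) + pmin[s]
      }
    }
  }
  rownames(data) <- labels[data_rows]
  ord <- order(ev_t)
  list(subject = subject, fs = fs, labels = labels[data_rows], data = data,
       events = data.frame(t = ev_t[ord], text = ev_text[ord],
                           stringsAsFactors = FALSE))
}
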