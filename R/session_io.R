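#' Write a session to disk
#'
#' Two formats are supported. `"bundle"` is the canonical lossless
#' interchange: one little-endian 32-bit float binary per trial and signal
#' type plus a JSON sidecar with sampling rate, labels, cue times, arm,
#' onset and provenance; it round-trips exactly (at float32 precision).
#' `"edf"` writes one EDF+ file per block (trials concatenated, cue/arm
#' markers as EDF+ annotations) for interoperability with standard EEG
#' tooling; EDF stores 16-bit integers, so signals round-trip within the
#' quantization step of the stored physical range.
#'
#' @param session an [new_session()].
#' @param path directory to write into (created if needed).
#' @param format `"bundle"` or `"edf"`.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, format = c("bundle", "edf")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "edf") return(write_session_edf(session, path))
  meta <- list(
    format = "moveintent-bundle-v1",
    subject = session$subject,
    fs = session$fs,
    eeg_labels = session$eeg_labels,
    emg_labels = session$emg_labels,
    provenance = session$provenance,
    trials = lapply(seq_along(session$trials), function(k) {
      tr <- session$trials[[k]]
      list(eeg_file = sprintf("trial%03d_eeg.bin", k),
           emg_file = sprintf("trial%03d_emg.bin", k),
           n_samples = ncol(tr$eeg), t0 = tr$t0,
           cues = as.list(tr$cues), arm = tr$arm, onset = tr$onset,
           time_ref = tr$time_ref, block = tr$block)
    })
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (k in seq_along(session$trials)) {
    tr <- session$trials[[k]]
    for (part in c("eeg", "emg")) {
      con <- file(file.path(path, sprintf("trial%03d_%s.bin", k, part)), "wb")
      writeBin(as.numeric(tr[[part]]), con, size = 4, endian = "little")
      close(con)
    }
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Inverse of [write_session()] for both formats.
#'
#' @param path directory written by [write_session()].
#' @param format `"bundle"` or `"edf"`.
#' @return An [new_session()].
#' @export
read_session <- function(path, format = c("bundle", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_session_edf(path))
  sidecar <- file.path(path, "session.json")
  if (!file.exists(sidecar)) stop("no session.json sidecar found in ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      stop(sprintf("parse error in %s: missing field \"%s\"", where, field))
    obj[[field]]
  }
  fs <- need(meta, "fs", "session.json")
  eeg_labels <- unlist(need(meta, "eeg_labels", "session.json"))
  emg_labels <- unlist(need(meta, "emg_labels", "session.json"))
  trials <- lapply(meta$trials, function(m) {
    ns <- need(m, "n_samples", "trial entry")
    read_f32 <- function(f, nch) {
      con <- file(file.path(path, f), "rb")
      on.exit(close(con))
      matrix(readBin(con, "numeric", n = nch * ns, size = 4,
                     endian = "little"), nrow = nch)
    }
    eeg <- read_f32(need(m, "eeg_file", "trial entry"), length(eeg_labels))
    emg <- read_f32(need(m, "emg_file", "trial entry"), length(emg_labels))
    rownames(eeg) <- eeg_labels
    rownames(emg) <- emg_labels
    new_trial(eeg, emg, fs, t0 = need(m, "t0", "trial entry"),
              cues = unlist(m$cues), arm = m$arm,
              onset = if (is.null(m$onset)) NA_real_ else m$onset,
              time_ref = m$time_ref %||% "cue",
              block = m$block %||% 1L)
  })
  new_session(trials, fs, subject = meta$subject %||% "unknown",
              eeg_labels = eeg_labels, emg_labels = emg_labels,
              provenance = meta$provenance %||% list())
}
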