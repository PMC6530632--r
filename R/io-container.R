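## Session container I/O.
##
## Epoched sessions persist in a single-file container: an uncompressed RDS
## payload wrapped with an explicit format tag and version so foreign files
## fail fast with a useful message. Uncompressed serialization keeps writes
## byte-deterministic for identical sessions and metadata.

CONTAINER_FORMAT <- "phasekin-session"
CONTAINER_VERSION <- 1L

#' Write an epoched session to a container file
#'
#' Refuses to serialize invalid state: the session is re-validated first.
#' Two writes of the same session produce byte-identical files.
#'
#' @param session An [eeg_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  validate_session(session)
  payload <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
                  session = unclass_session(session))
  tryCatch(saveRDS(payload, path, compress = FALSE),
           error = function(e) {
             pk_stop("cannot write '%s': %s", path, conditionMessage(e))
           },
           warning = function(w) {
             pk_stop("cannot write '%s': %s", path, conditionMessage(w))
           })
  invisible(path)
}

#' Read an epoched session
#'
#' @param path For `format = "container"`, a file written by
#'   [write_session()]. For `format = "edf+csv"`, a directory containing
#'   `eeg.edf`, `kinematics.csv` (columns `t, dx, dy, sx, sy`) and
#'   `events.csv` (columns `onset_s, end_s, direction, block`).
#' @param format Input dialect.
#' @param montage Montage to attach (and to reorder EDF channels against);
#'   defaults to [default_montage()].
#' @param pre_onset_s Epoch length before movement onset for `edf+csv`.
#' @return A validated [eeg_session()].
#' @export
read_session <- function(path, format = c("container", "edf+csv"),
                         montage = NULL, pre_onset_s = 1) {
  format <- match.arg(format)
  if (format == "edf+csv") {
    return(read_session_edf_csv(path, montage = montage, pre_onset_s = pre_onset_s))
  }
  if (!file.exists(path)) pk_stop("no such file: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    pk_stop("'%s' is not a readable session container: %s", path, conditionMessage(e))
  })
  if (!is.list(payload) || !identical(payload$format, CONTAINER_FORMAT)) {
    pk_stop("'%s' is not a %s container", path, CONTAINER_FORMAT)
  }
  if (!identical(payload$version, CONTAINER_VERSION)) {
    pk_stop("container version %s unsupported (expected %d)",
            format(payload$version), CONTAINER_VERSION)
  }
  s <- reclass_session(payload$session)
  validate_session(s)
  s
}

## Strip S3 classes for serialization so the on-disk layout is plain lists,
## then restore them on read; keeps the format independent of class internals.
unclass_session <- function(session) {
  list(subject_id = session$subject_id, session_id = session$session_id,
       sample_rate = session$sample_rate,
       montage = list(channel = session$montage$channel,
                      region = session$montage$region),
       trials = lapply(session$trials, function(tr) {
         list(eeg = tr$eeg, kin = unclass(tr$kin), direction = tr$direction,
              block = tr$block, onset_index = tr$onset_index,
              sample_rate = tr$sample_rate)
       }))
}

reclass_session <- function(x) {
  mont <- montage(x$montage$channel, x$montage$region)
  trials <- lapply(x$trials, function(tr) {
    eeg_trial(tr$eeg, do.call(kinematics_track, tr$kin[c("sx", "sy", "dx", "dy")]),
              tr$direction, tr$block, tr$onset_index, tr$sample_rate)
  })
  eeg_session(trials, mont, x$subject_id, x$session_id, x$sample_rate)
}

read_session_edf_csv <- function(dir, montage = NULL, pre_onset_s = 1) {
  if (!dir.exists(dir)) pk_stop("no such directory: %s", dir)
  edf_path <- file.path(dir, "eeg.edf")
  kin_path <- file.path(dir, "kinematics.csv")
  ev_path <- file.path(dir, "events.csv")
  for (p in c(edf_path, kin_path, ev_path)) {
    if (!file.exists(p)) pk_stop("edf+csv layout is missing '%s'", p)
  }
  mont <- montage %||% default_montage()
  edf <- read_edf(edf_path)
  missing <- setdiff(mont$channel, edf$labels)
  if (length(missing) > 0L) {
    pk_stop("EDF is missing montage channels: %s", paste(missing, collapse = ", "))
  }
  sig <- edf$signal[match(mont$channel, edf$labels), , drop = FALSE]

  kin_df <- utils::read.csv(kin_path)
  need <- c("t", "dx", "dy", "sx", "sy")
  if (!all(need %in% names(kin_df))) {
    pk_stop("kinematics.csv must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(kin_df) != ncol(sig)) {
    pk_stop("kinematics (%d samples) and EEG (%d samples) are on different clocks",
            nrow(kin_df), ncol(sig))
  }
  dt <- diff(kin_df$t)
  if (length(dt) > 1L && abs(1 / stats::median(dt) - edf$sample_rate) > 1e-6 * edf$sample_rate) {
    pk_stop("kinematics sample rate %.6g Hz does not match EDF rate %.6g Hz",
            1 / stats::median(dt), edf$sample_rate)
  }
  kin <- kinematics_track(kin_df$sx, kin_df$sy, kin_df$dx, kin_df$dy)

  ev_df <- utils::read.csv(ev_path)
  need <- c("onset_s", "end_s", "direction", "block")
  if (!all(need %in% names(ev_df))) {
    pk_stop("events.csv must have columns %s", paste(need, collapse = ", "))
  }
  events <- data.frame(onset = as.integer(round(ev_df$onset_s * edf$sample_rate)),
                       end = as.integer(round(ev_df$end_s * edf$sample_rate)),
                       direction = as.character(ev_df$direction),
                       block = as.integer(ev_df$block))
  rec <- continuous_recording(sig, edf$sample_rate, events)
  epoch_trials(rec, kin, pre_onset_s = pre_onset_s, montage = mont)
}
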