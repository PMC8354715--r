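#' Write a session (and optionally its ground truth) to the native HDF5 layout
#'
#' Layout: `/signal/data` (channels x samples, microvolts; attributes `rate_hz`,
#' `unit`), `/events` (`onset_s`, `intensity_uA`), `/channels` (`label`, `x_mm`,
#' `y_mm`), root attributes `state`, `reference`, `subject_id` and `seed`.
#' Synthetic sessions may carry a `/ground_truth` group (JSON-serialized
#' generator draws); it is omitted for non-synthetic sessions.
#'
#' @param session an [eeg_session()] object.
#' @param path output file; overwritten if present.
#' @param ground_truth optional ground-truth list from [simulate_session()].
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, ground_truth = NULL) {
  validate_session(session)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "signal")
  rhdf5::h5write(session$signal, path, "signal/data")
  h5_attr_write(path, "signal", list(rate_hz = session$rate, unit = "uV"))
  rhdf5::h5createGroup(path, "events")
  rhdf5::h5write(as.numeric(session$events$onset_s), path, "events/onset_s")
  rhdf5::h5write(as.numeric(session$events$intensity_uA), path, "events/intensity_uA")
  rhdf5::h5createGroup(path, "channels")
  rhdf5::h5write(session$channel_labels, path, "channels/label")
  rhdf5::h5write(as.numeric(session$channel_xy[, 1]), path, "channels/x_mm")
  rhdf5::h5write(as.numeric(session$channel_xy[, 2]), path, "channels/y_mm")
  root_attrs <- list(state = session$state, reference = session$reference)
  if (!is.null(session$subject_id)) root_attrs$subject_id <- session$subject_id
  if (!is.null(session$seed)) root_attrs$seed <- session$seed
  h5_attr_write(path, "/", root_attrs)
  if (!is.null(ground_truth)) {
    rhdf5::h5createGroup(path, "ground_truth")
    rhdf5::h5write(
      as.character(jsonlite::toJSON(ground_truth, digits = NA, auto_unbox = TRUE)),
      path, "ground_truth/json")
  }
  invisible(path)
}

h5_attr_write <- function(path, obj, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- if (identical(obj, "/")) fid else rhdf5::H5Gopen(fid, obj)
  if (!identical(obj, "/")) on.exit(rhdf5::H5Gclose(oid), add = TRUE)
  for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], oid, nm)
  invisible(NULL)
}

#' Read a session from disk
#'
#' @param path file path.
#' @param format `"native"` (HDF5 layout written by [write_session()]) or
#'   `"edf"` (European Data Format continuous recording; events must then be
#'   supplied separately, e.g. via [read_events()]).
#' @param events optional events data.frame attached to an EDF import.
#' @return An [eeg_session()]; for native files with a `/ground_truth` group the
#'   ground truth is attached as attribute `"ground_truth"`.
#' @export
read_session <- function(path, format = c("native", "edf"), events = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    s <- read_edf(path)
    if (!is.null(events)) s$events <- events
    validate_session(s)
    return(s)
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  have <- file.path(gsub("^/$", "", ls$group), ls$name)
  need <- c("/signal/data", "/events/onset_s", "/events/intensity_uA",
            "/channels/label", "/channels/x_mm", "/channels/y_mm")
  missing <- setdiff(need, have)
  if (length(missing))
    stop("native session format error: missing ", paste(missing, collapse = ", "))
  sig <- rhdf5::h5read(path, "signal/data")
  sa <- rhdf5::h5readAttributes(path, "signal")
  ra <- rhdf5::h5readAttributes(path, "/")
  if (is.null(sa$rate_hz)) stop("native session format error: missing attribute rate_hz")
  ev <- data.frame(onset_s = as.numeric(rhdf5::h5read(path, "events/onset_s")),
                   intensity_uA = as.numeric(rhdf5::h5read(path, "events/intensity_uA")))
  labels <- as.character(rhdf5::h5read(path, "channels/label"))
  xy <- cbind(as.numeric(rhdf5::h5read(path, "channels/x_mm")),
              as.numeric(rhdf5::h5read(path, "channels/y_mm")))
  s <- eeg_session(sig, rate = as.numeric(sa$rate_hz), channel_labels = labels,
                   channel_xy = xy, events = ev,
                   state = if (is.null(ra$state)) "synthetic" else as.character(ra$state),
                   reference = if (is.null(ra$reference)) "raw" else as.character(ra$reference),
                   subject_id = if (is.null(ra$subject_id)) NULL else as.character(ra$subject_id),
                   seed = if (is.null(ra$seed)) NULL else as.numeric(ra$seed))
  if ("/ground_truth/json" %in% have) {
    attr(s, "ground_truth") <- jsonlite::fromJSON(
      as.character(rhdf5::h5read(path, "ground_truth/json")), simplifyVector = TRUE)
  }
  s
}

#' Write an epoch set to the native HDF5 layout
#'
#' Stored under `/epochs`: `data` (trials x channels x time), `time_axis_s`,
#' `kept_mask`, `/channels`, root attributes `state` and `rate_hz`, plus the
#' provenance list as JSON.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "epochs")
  rhdf5::h5write(epochs$data, path, "epochs/data")
  rhdf5::h5write(epochs$time_axis, path, "epochs/time_axis_s")
  rhdf5::h5write(as.integer(epochs$kept_mask), path, "epochs/kept_mask")
  rhdf5::h5createGroup(path, "channels")
  rhdf5::h5write(epochs$channel_labels, path, "channels/label")
  rhdf5::h5write(as.numeric(epochs$channel_xy[, 1]), path, "channels/x_mm")
  rhdf5::h5write(as.numeric(epochs$channel_xy[, 2]), path, "channels/y_mm")
  rhdf5::h5write(as.character(jsonlite::toJSON(epochs$provenance, digits = NA,
                                               auto_unbox = TRUE)),
                 path, "epochs/provenance_json")
  h5_attr_write(path, "epochs", list(rate_hz = epochs$rate, state = epochs$state))
  invisible(path)
}

#' Read an epoch set from the native HDF5 layout
#'
#' @param path file written by [write_epochs()].
#' @return An [eeg_epochs()] object.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  have <- file.path(gsub("^/$", "", ls$group), ls$name)
  need <- c("/epochs/data", "/epochs/time_axis_s", "/epochs/kept_mask")
  missing <- setdiff(need, have)
  if (length(missing))
    stop("native epochs format error: missing ", paste(missing, collapse = ", "))
  a <- rhdf5::h5readAttributes(path, "epochs")
  prov <- list()
  if ("/epochs/provenance_json" %in% have)
    prov <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "epochs/provenance_json")),
                               simplifyVector = TRUE)
  eeg_epochs(
    data = rhdf5::h5read(path, "epochs/data"),
    time_axis = as.numeric(rhdf5::h5read(path, "epochs/time_axis_s")),
    rate = as.numeric(a$rate_hz),
    channel_labels = as.character(rhdf5::h5read(path, "channels/label")),
    channel_xy = cbind(as.numeric(rhdf5::h5read(path, "channels/x_mm")),
                       as.numeric(rhdf5::h5read(path, "channels/y_mm"))),
    kept_mask = as.logical(rhdf5::h5read(path, "epochs/kept_mask")),
    state = if (is.null(a$state)) "synthetic" else as.character(a$state),
    provenance = prov
  )
}

#' Read stimulus events from delimited text
#'
#' Two columns, `onset_s` and `intensity_uA`; comma- or whitespace-delimited,
#' with or without a header line.
#'
#' @param path text file path.
#' @return data.frame with columns `onset_s`, `intensity_uA`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  d <- read.table(path, sep = sep, header = header)
  if (ncol(d) < 2) stop("events file must have two columns (onset_s, intensity_uA)")
  data.frame(onset_s = as.numeric(d[[1]]), intensity_uA = as.numeric(d[[2]]))
}

# --- EDF (European Data Format) continuous-signal import -----------------------

edf_field <- function(con, nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))

#' Read a continuous EDF recording
#'
#' Minimal reader for uninterrupted EDF recordings: parses the 256-byte fixed
#' header and the per-signal headers, then rescales the 16-bit samples to
#' physical units via the digital/physical min-max mapping. All signals must
#' share one sampling rate. Annotation channels ("EDF Annotations") are dropped.
#'
#' @param path EDF file path.
#' @return An [eeg_session()] with empty events (EDF carries none here).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  version <- edf_field(con, 8)
  if (!identical(version, "0")) stop("EDF format error: unsupported version '", version, "'")
  subject <- edf_field(con, 80)
  edf_field(con, 80)                       # recording id
  edf_field(con, 8); edf_field(con, 8)     # start date, start time
  header_bytes <- as.integer(edf_field(con, 8))
  edf_field(con, 44)                       # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF format error: bad signal count")
  rd <- function(nb) vapply(seq_len(ns), function(i) edf_field(con, nb), "")
  labels <- rd(16); rd(80); phys_dim <- rd(8)
  pmin <- as.numeric(rd(8)); pmax <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8)); rd(32)
  seek(con, header_bytes)
  keep <- !grepl("Annotations", labels)
  if (!any(keep)) stop("EDF format error: no signal channels")
  if (length(unique(spr[keep])) != 1)
    stop("EDF import requires a single sampling rate across channels")
  nch <- sum(keep)
  sig <- matrix(0, nch, n_records * spr[keep][1])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (keep[i]) {
        j <- sum(keep[seq_len(i)])
        scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        sig[j, ((r - 1) * spr[i] + 1):(r * spr[i])] <- (raw - dmin[i]) * scale + pmin[i]
      }
    }
  }
  eeg_session(sig, rate = spr[keep][1] / record_dur,
              channel_labels = make.unique(labels[keep]),
              state = "synthetic", reference = "raw",
              subject_id = if (nzchar(subject)) subject else NULL)
}
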