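#' Electrode montage of the 16-screw epidural grid
#'
#' Standard recording grid used throughout the package: eight bilateral electrode
#' pairs over secondary/primary motor (M2 anterior and posterior, M1),
#' somatosensory (S1), retrosplenial (RS), parietal association (PA) and visual
#' (V2, V1) cortices. Coordinates are in mm relative to bregma
#' (x: medial-lateral, negative = left; y: rostral-caudal, negative = caudal).
#'
#' @return A data.frame with columns `label`, `x_mm`, `y_mm`, `region`
#'   (frontal/parietal/occipital).
#' @export
rat_montage <- function() {
  grid <- rbind(
    c("M2aL", -1.5,  5), c("M2aR", 1.5,  5),
    c("M2pL", -1.5,  2), c("M2pR", 1.5,  2),
    c("M1L",  -1.5, -1), c("M1R",  1.5, -1),
    c("S1L",  -4.5, -1), c("S1R",  4.5, -1),
    c("RSL",  -1.5, -4), c("RSR",  1.5, -4),
    c("PAL",  -4.5, -4), c("PAR",  4.5, -4),
    c("V2L",  -1.5, -7), c("V2R",  1.5, -7),
    c("V1L",  -4.5, -7), c("V1R",  4.5, -7)
  )
  out <- data.frame(
    label = grid[, 1],
    x_mm = as.numeric(grid[, 2]),
    y_mm = as.numeric(grid[, 3]),
    stringsAsFactors = FALSE
  )
  out$region <- region_of_label(out$label)
  out
}

#' Map electrode labels to cortical regions
#'
#' frontal: M2, M1; parietal: S1, PA, RS; occipital: V2, V1.
#'
#' @param labels character vector of electrode labels.
#' @return character vector of regions.
#' @export
region_of_label <- function(labels) {
  out <- rep(NA_character_, length(labels))
  out[grepl("^M2|^M1", labels)] <- "frontal"
  out[grepl("^S1|^PA|^RS", labels)] <- "parietal"
  out[grepl("^V1|^V2", labels)] <- "occipital"
  out
}

# Coordinates of the bipolar stimulating electrode in right M2 (midpoint of the
# two wires: x = +1.2/+1.7 mm, y = +3.7 mm).
stim_site <- function() c(x_mm = 1.45, y_mm = 3.7)

#' Construct a continuous EEG session
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in samples/s.
#' @param channel_labels unique channel identifiers (default: [rat_montage()]).
#' @param channel_xy matrix/data.frame of grid coordinates (mm), one row per channel.
#' @param events data.frame with columns `onset_s` (stimulus onsets, seconds) and
#'   `intensity_uA`.
#' @param state one of "wake", "propofol", "sevoflurane", "ketamine", "synthetic".
#' @param reference reference scheme already applied: "raw", "common_average", or
#'   "bipolar(<a>-<b>)".
#' @param subject_id optional identifier.
#' @param seed master seed when the session is synthetic.
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(signal, rate, channel_labels = NULL, channel_xy = NULL,
                        events = NULL, state = "synthetic", reference = "raw",
                        subject_id = NULL, seed = NULL) {
  signal <- as.matrix(signal)
  if (is.null(channel_labels)) {
    m <- rat_montage()
    if (nrow(signal) != nrow(m))
      stop("channel_labels must be given when signal does not have ", nrow(m), " channels")
    channel_labels <- m$label
    if (is.null(channel_xy)) channel_xy <- as.matrix(m[, c("x_mm", "y_mm")])
  }
  if (is.null(channel_xy)) channel_xy <- matrix(NA_real_, nrow(signal), 2)
  channel_xy <- as.matrix(channel_xy)
  if (is.null(events)) events <- data.frame(onset_s = numeric(0), intensity_uA = numeric(0))
  x <- structure(list(
    signal = signal, rate = rate,
    channel_labels = as.character(channel_labels),
    channel_xy = channel_xy,
    events = events, state = state, reference = reference,
    subject_id = subject_id, seed = seed
  ), class = "eeg_session")
  validate_session(x)
  x
}

validate_session <- function(x) {
  stopifnot(inherits(x, "eeg_session"))
  if (!is.numeric(x$rate) || length(x$rate) != 1 || x$rate <= 0)
    stop("rate must be a positive scalar")
  if (nrow(x$signal) < 2) stop("a session needs at least 2 channels")
  if (anyDuplicated(x$channel_labels)) stop("channel labels must be unique")
  if (length(x$channel_labels) != nrow(x$signal))
    stop("integrity error: ", length(x$channel_labels), " labels for ",
         nrow(x$signal), " signal channels")
  dur <- ncol(x$signal) / x$rate
  if (nrow(x$events) > 0 && (any(x$events$onset_s < 0) || any(x$events$onset_s >= dur)))
    stop("event onsets must lie within [0, ", dur, ") s")
  invisible(x)
}

#' @export
print.eeg_session <- function(x, ...) {
  cat("<eeg_session> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$rate, " Hz (", sprintf("%.1f", ncol(x$signal) / x$rate),
      " s)\n", sep = "")
  cat("  state: ", x$state, "; reference: ", x$reference,
      "; events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Construct an epoch set
#'
#' @param data numeric array trials x channels x time (microvolts).
#' @param time_axis time in seconds relative to stimulus onset (0 s is the first
#'   response sample).
#' @param rate sampling rate of the epochs.
#' @param channel_labels,channel_xy channel metadata (see [eeg_session()]).
#' @param kept_mask logical per-trial flag; trials marked `FALSE` are ignored by
#'   every downstream computation.
#' @param state state label.
#' @param provenance named list of preprocessing parameters applied so far.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, time_axis, rate, channel_labels = NULL,
                       channel_xy = NULL, kept_mask = NULL, state = "synthetic",
                       provenance = list()) {
  stopifnot(length(dim(data)) == 3)
  if (length(time_axis) != dim(data)[3])
    stop("time_axis length does not match the time dimension")
  if (any(diff(time_axis) <= 0)) stop("time axis must be strictly increasing")
  if (!any(abs(time_axis) < 1e-9)) stop("time axis must include 0")
  if (is.null(channel_labels)) {
    m <- rat_montage()
    if (dim(data)[2] == nrow(m)) {
      channel_labels <- m$label
      if (is.null(channel_xy)) channel_xy <- as.matrix(m[, c("x_mm", "y_mm")])
    } else {
      channel_labels <- paste0("ch", seq_len(dim(data)[2]))
    }
  }
  if (is.null(channel_xy)) channel_xy <- matrix(NA_real_, dim(data)[2], 2)
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(data)[1])
  stopifnot(length(kept_mask) == dim(data)[1])
  structure(list(
    data = data, time_axis = as.numeric(time_axis), rate = rate,
    channel_labels = as.character(channel_labels),
    channel_xy = as.matrix(channel_xy),
    kept_mask = as.logical(kept_mask),
    state = state, provenance = provenance
  ), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials (", sum(x$kept_mask), " kept) x ", d[2],
      " channels x ", d[3], " samples @ ", x$rate, " Hz\n", sep = "")
  cat("  time: [", sprintf("%.3f", x$time_axis[1]), ", ",
      sprintf("%.3f", x$time_axis[d[3]]), "] s; state: ", x$state, "\n", sep = "")
  invisible(x)
}

# Kept-trial view of the data array.
kept_data <- function(epochs) {
  epochs$data[epochs$kept_mask, , , drop = FALSE]
}

#' Trial-averaged evoked response (ERP)
#'
#' Averages kept trials, returning a channels x time matrix.
#'
#' @param epochs an [eeg_epochs()] object.
#' @return numeric matrix channels x time with the epoch time axis as attribute
#'   `"times"`.
#' @export
erp_mean <- function(epochs) {
  x <- kept_data(epochs)
  if (dim(x)[1] == 0) stop("no kept trials")
  out <- colMeans(x)
  attr(out, "times") <- epochs$time_axis
  rownames(out) <- epochs$channel_labels
  out
}
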