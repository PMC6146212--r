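#' Synchronized single-trial container
#'
#' Holds the synchronized streams of one walking block: 3-D marker
#' trajectories (mm, typically 250 Hz), dual force-plate forces/moments
#' (N, N m, typically 1000 Hz), surface EMG (a.u.), optional joint-angle
#' streams (deg, marker rate), the stimulus log, and metadata (subject id,
#' standing heel-marker calibration heights, plate origins). All streams
#' share the time origin t = 0. Coordinate convention: x medial-lateral
#' (positive right), y anterior, z up; positions mm, angles deg, time s.
#'
#' @param markers list(time, data, rate): `data` is a time x channel matrix
#'   with columns like `LHEE_x`, `LHEE_y`, `LHEE_z`; NaN/NA encodes occluded
#'   samples
#' @param forces list(time, data, rate): columns `fz_left`, `mx_left`,
#'   `fz_right`, `mx_right` (additional channels allowed)
#' @param emg list(time, data, rate): one column per muscle/side
#' @param stimulus_log data.frame with `time_s`, `trigger_foot`, `direction`,
#'   `peak_angle_deg`
#' @param meta list with at least `subject`; optionally `standing_heel_height`
#'   (named, mm) and `plate_origin_x` (named, mm)
#' @param angles optional list(time, data, rate) of joint angles
#' @return object of class `trial_bundle`
#' @export
trial_bundle <- function(markers, forces, emg, stimulus_log, meta, angles = NULL) {
  check_stream <- function(s, nm) {
    if (is.null(s)) stop(sprintf("missing stream: %s", nm), call. = FALSE)
    if (!all(c("time", "data", "rate") %in% names(s)))
      stop(sprintf("stream '%s' needs fields time, data, rate", nm), call. = FALSE)
    if (s$rate <= 0) stop(sprintf("stream '%s': rate must be positive", nm), call. = FALSE)
    if (nrow(s$data) != length(s$time))
      stop(sprintf("stream '%s': time/data length mismatch", nm), call. = FALSE)
    dt <- diff(s$time)
    if (length(dt) && max(abs(dt - 1 / s$rate)) > 1e-6)
      stop(sprintf("stream '%s': sampling does not match declared rate %g Hz",
                   nm, s$rate), call. = FALSE)
    invisible(s)
  }
  check_stream(markers, "markers")
  check_stream(forces, "forces")
  check_stream(emg, "emg")
  if (!is.null(angles)) check_stream(angles, "angles")
  b <- structure(list(markers = markers, forces = forces, emg = emg,
                      angles = angles, stimulus_log = stimulus_log, meta = meta),
                 class = "trial_bundle")
  b
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf("<trial_bundle> subject %s\n", x$meta$subject %||% "?"))
  cat(sprintf("  markers: %d samples x %d channels @ %g Hz\n",
              nrow(x$markers$data), ncol(x$markers$data), x$markers$rate))
  cat(sprintf("  forces:  %d samples x %d channels @ %g Hz\n",
              nrow(x$forces$data), ncol(x$forces$data), x$forces$rate))
  cat(sprintf("  emg:     %d samples x %d channels @ %g Hz\n",
              nrow(x$emg$data), ncol(x$emg$data), x$emg$rate))
  if (!is.null(x$angles))
    cat(sprintf("  angles:  %d samples x %d channels @ %g Hz\n",
                nrow(x$angles$data), ncol(x$angles$data), x$angles$rate))
  cat(sprintf("  stimuli: %d\n", nrow(x$stimulus_log)))
  invisible(x)
}

#' Write / read a trial bundle on disk
#'
#' Canonical on-disk layout: a directory of tab-separated tables
#' (`markers.tsv`, `forces.tsv`, `emg.tsv`, optionally `angles.tsv`, and
#' `stimulus.tsv`; first column `time`) plus a `meta.yaml` sidecar holding
#' sampling rates and metadata. Round-tripping is lossless for finite values;
#' NA encodes occluded samples.
#'
#' @param bundle a [trial_bundle()]
#' @param path directory to create/read
#' @return `read_trial` returns a `trial_bundle`
#' @export
write_trial <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(s, f) {
    df <- data.frame(time = s$time, s$data, check.names = FALSE)
    data.table::fwrite(df, file.path(path, f), sep = "\t")
  }
  wr(bundle$markers, "markers.tsv")
  wr(bundle$forces, "forces.tsv")
  wr(bundle$emg, "emg.tsv")
  if (!is.null(bundle$angles)) wr(bundle$angles, "angles.tsv")
  data.table::fwrite(as.data.frame(bundle$stimulus_log),
                     file.path(path, "stimulus.tsv"), sep = "\t")
  meta <- bundle$meta
  meta$rates <- list(markers = bundle$markers$rate, forces = bundle$forces$rate,
                     emg = bundle$emg$rate,
                     angles = if (!is.null(bundle$angles)) bundle$angles$rate)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  need <- c("markers.tsv", "forces.tsv", "emg.tsv", "stimulus.tsv", "meta.yaml")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop(sprintf("missing stream: %s (%s not found)",
                   sub("\\..*$", "", f), f), call. = FALSE)
  }
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  rates <- meta$rates
  meta$rates <- NULL
  rd <- function(f, rate) {
    df <- as.data.frame(data.table::fread(file.path(path, f), sep = "\t"))
    list(time = df$time,
         data = as.matrix(df[, setdiff(names(df), "time"), drop = FALSE]),
         rate = rate)
  }
  angles <- NULL
  if (file.exists(file.path(path, "angles.tsv")))
    angles <- rd("angles.tsv", rates$angles)
  stim <- as.data.frame(data.table::fread(file.path(path, "stimulus.tsv"), sep = "\t"))
  if (nrow(stim)) {
    stim$trigger_foot <- as.character(stim$trigger_foot)
    stim$direction <- as.character(stim$direction)
  } else {
    stim <- data.frame(time_s = numeric(0), trigger_foot = character(0),
                       direction = character(0), peak_angle_deg = numeric(0),
                       stringsAsFactors = FALSE)
  }
  trial_bundle(markers = rd("markers.tsv", rates$markers),
               forces = rd("forces.tsv", rates$forces),
               emg = rd("emg.tsv", rates$emg),
               stimulus_log = stim, meta = meta, angles = angles)
}
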