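#' Electrode montage
#'
#' @param labels unique channel labels.
#' @param positions_mm channels x 3 matrix of electrode coordinates in mm.
#' @return Object of class `channel_montage`.
#' @export
channel_montage <- function(labels, positions_mm) {
  positions_mm <- as.matrix(positions_mm)
  stopifnot(length(labels) == nrow(positions_mm), ncol(positions_mm) == 3,
            all(is.finite(positions_mm)))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(list(labels = as.character(labels), positions_mm = positions_mm),
            class = "channel_montage")
}

#' Synthetic scalp montage on the upper hemisphere of a sphere
#'
#' Electrodes are spread quasi-uniformly (Fibonacci lattice) over the upper
#' half of a sphere of radius `radius_mm`, with +y anterior and +z superior,
#' emulating an extended 10-10 style cap.
#'
#' @param n_channels number of electrodes (default 64).
#' @param radius_mm head radius (default 90 mm).
#' @return A [channel_montage()] with labels `E001, E002, ...`.
#' @export
make_montage <- function(n_channels = 64L, radius_mm = 90) {
  stopifnot(n_channels >= 8)
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  z <- (i - 0.5) / n_channels          # in (0, 1): upper hemisphere
  r <- sqrt(1 - z^2)
  th <- golden * i
  pos <- radius_mm * cbind(x = r * cos(th), y = r * sin(th), z = z)
  channel_montage(sprintf("E%03d", i), pos)
}

#' Stimulus-locked epoch container
#'
#' @param data trials x channels x samples numeric array of voltages (uV).
#' @param montage a [channel_montage()] with one entry per channel.
#' @param srate_hz sampling rate.
#' @param window_ms length-2 `(start, end)` in ms, `start < 0 < end`.
#' @param condition condition tag (default "CR", correct rejections).
#' @return Object of class `epoch_set`. Sample times are
#'   `start + k / srate`, `k = 0 .. floor((end - start) * srate / 1000)`,
#'   both window edges included (so a -100..700 ms window at 1024 Hz holds
#'   820 samples).
#' @export
epoch_set <- function(data, montage, srate_hz, window_ms,
                      condition = "CR") {
  stopifnot(length(dim(data)) == 3, inherits(montage, "channel_montage"))
  stopifnot(window_ms[1] < 0, window_ms[2] > 0, srate_hz > 0)
  if (dim(data)[2] != length(montage$labels))
    stop("data has ", dim(data)[2], " channels but montage has ",
         length(montage$labels))
  n_expect <- n_epoch_samples(window_ms, srate_hz)
  if (dim(data)[3] != n_expect)
    stop("data has ", dim(data)[3], " samples but window/srate imply ",
         n_expect)
  structure(list(data = data, montage = montage,
                 srate_hz = as.numeric(srate_hz),
                 window_ms = as.numeric(window_ms),
                 condition = condition),
            class = "epoch_set")
}

#' @rdname epoch_set
#' @export
n_epoch_samples <- function(window_ms, srate_hz) {
  as.integer(floor((window_ms[2] - window_ms[1]) * srate_hz / 1000)) + 1L
}

#' @rdname epoch_set
#' @export
epoch_times_ms <- function(x) {
  n <- dim(x$data)[3]
  x$window_ms[1] + (seq_len(n) - 1L) * 1000 / x$srate_hz
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, %g Hz, %g..%g ms [%s]\n",
              d[1], d[2], d[3], x$srate_hz, x$window_ms[1], x$window_ms[2],
              x$condition))
  invisible(x)
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every trial and sample, the instantaneous mean over
#' channels, so the channel mean of the output is 0 everywhere.
#'
#' @param epochs an [epoch_set()] with >= 2 channels.
#' @return The re-referenced [epoch_set()].
#' @export
rereference_average <- function(epochs) {
  d <- epochs$data
  if (dim(d)[2] < 2L) stop("average reference needs >= 2 channels")
  m <- apply(d, c(1, 3), mean)            # trials x samples
  nc <- dim(d)[2]
  epochs$data <- d - aperm(array(m, c(dim(d)[1], dim(d)[3], nc)),
                           c(1, 3, 2))
  epochs
}

#' Baseline-correct epochs
#'
#' Per trial and channel, subtracts the mean voltage over the baseline
#' window (sample times in `[start, end]`, inclusive) from the whole epoch.
#' The default baseline is the pre-stimulus period.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window_ms length-2 window inside the epoch window;
#'   default `(window start, 0)`.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs,
                             baseline_window_ms = c(epochs$window_ms[1], 0)) {
  tms <- epoch_times_ms(epochs)
  sel <- tms >= baseline_window_ms[1] & tms <= baseline_window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  if (baseline_window_ms[1] < epochs$window_ms[1] ||
      baseline_window_ms[2] > epochs$window_ms[2])
    stop("baseline window must lie inside the epoch window")
  d <- epochs$data
  bl <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)  # trials x channels
  epochs$data <- d - array(bl, dim(d))
  epochs
}

#' Interpolate bad channels by multiquadric radial basis functions
#'
#' Each bad channel is reconstructed, sample by sample, from the good
#' channels' voltages via a multiquadric RBF interpolant
#' `phi(r) = sqrt(r^2 + eps^2)` over electrode positions, augmented with a
#' constant polynomial term so constant fields are reproduced exactly. Good
#' channels are untouched. The shape parameter `eps` defaults to the median
#' inter-electrode distance of the good channels.
#'
#' @param epochs an [epoch_set()].
#' @param bad_labels labels of channels to rebuild; fewer than
#'   `n_channels - 3`.
#' @param eps_mm RBF shape parameter; `NULL` for the median-distance default.
#' @return The [epoch_set()] with bad channels replaced.
#' @export
interpolate_bad_channels <- function(epochs, bad_labels, eps_mm = NULL) {
  if (!length(bad_labels)) return(epochs)
  labs <- epochs$montage$labels
  bad <- match(bad_labels, labs)
  if (anyNA(bad)) stop("unknown channel label(s): ",
                       paste(bad_labels[is.na(bad)], collapse = ", "))
  good <- setdiff(seq_along(labs), bad)
  if (length(bad) >= length(labs) - 3L)
    stop("too many bad channels (", length(bad), " of ", length(labs), ")")
  P <- epochs$montage$positions_mm
  Dg <- as.matrix(stats::dist(P[good, , drop = FALSE]))
  if (is.null(eps_mm)) eps_mm <- stats::median(Dg[upper.tri(Dg)])
  phi <- function(r) sqrt(r^2 + eps_mm^2)
  A <- phi(Dg)
  ng <- length(good)
  M <- rbind(cbind(A, 1), c(rep(1, ng), 0))
  cross <- sqrt(outer(rowSums(P[bad, , drop = FALSE]^2), rep(1, ng)) +
                  outer(rep(1, length(bad)), rowSums(P[good, , drop = FALSE]^2)) -
                  2 * P[bad, , drop = FALSE] %*% t(P[good, , drop = FALSE]))
  B <- cbind(phi(cross), 1)               # bad x (good + 1)
  d <- epochs$data
  nt <- dim(d)[1]; ns <- dim(d)[3]
  V <- matrix(aperm(d[, good, , drop = FALSE], c(2, 1, 3)), nrow = ng)
  rhs <- rbind(V, 0)
  W <- tryCatch(solve(M, rhs), error = function(e)
    stop("RBF system is singular for good-channel geometry (",
         length(good), " channels); check electrode positions: ",
         conditionMessage(e)))
  interp <- B %*% W                        # bad x (trials*samples)
  for (i in seq_along(bad))
    d[, bad[i], ] <- matrix(interp[i, ], nt, ns)
  epochs$data <- d
  epochs
}

#' Average epochs into an ERP
#'
#' @param epochs an [epoch_set()] with >= 1 trial.
#' @return channels x samples matrix (the event-related potential), with
#'   attributes `times_ms`, `montage`.
#' @export
average_epochs <- function(epochs) {
  if (dim(epochs$data)[1] < 1L) stop("no trials to average")
  erp <- apply(epochs$data, c(2, 3), mean)
  attr(erp, "times_ms") <- epoch_times_ms(epochs)
  attr(erp, "montage") <- epochs$montage
  erp
}

#' Global field power
#'
#' The spatial standard deviation of the scalp field at each time point:
#' `GFP(t) = sqrt(mean((v_i(t) - vbar(t))^2))` over channels `i`, using the
#' population (divide-by-C) variance. GFP is reference-free: adding any
#' time-varying constant to all channels, permuting channels, or
#' re-referencing to the average leaves it unchanged.
#'
#' @param erp channels x samples matrix (e.g. from [average_epochs()]).
#' @param times_ms optional sample times; taken from the `times_ms`
#'   attribute when present.
#' @return Object of class `gfp_series`: list with `times_ms`, `values`.
#' @export
gfp <- function(erp, times_ms = attr(erp, "times_ms")) {
  if (nrow(erp) < 2L) stop("GFP needs >= 2 channels")
  ctr <- sweep(erp, 2, colMeans(erp))
  vals <- sqrt(colMeans(ctr^2))
  if (is.null(times_ms)) times_ms <- seq_len(ncol(erp))
  structure(list(times_ms = as.numeric(times_ms), values = vals),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples, %g..%g ms, peak %.3g uV at %.0f ms\n",
              length(x$values), min(x$times_ms), max(x$times_ms),
              max(x$values), x$times_ms[which.max(x$values)]))
  invisible(x)
}

#' Locate a component's period of interest on the grand-average GFP
#'
#' Finds the GFP peak (argmax; ties broken to the earliest sample) inside
#' the component search window and returns the period of interest
#' `peak +/- half_width_ms`, clipped to the epoch support (clipping is
#' flagged). The POI is meant to be fixed once, on the grand average over
#' all subjects, then applied unchanged to every individual GFP.
#'
#' @param grand_gfp a [gfp()] result for the grand-average ERP.
#' @param search_window_ms length-2 `(start, end)` inside the series.
#' @param half_width_ms half-width of the POI (default 40 ms).
#' @param component label ("N2", "P3", ...).
#' @return Object of class `poi`: list with `component`, `peak_ms`,
#'   `start_ms`, `end_ms`, `clipped`, `flat`.
#' @export
find_component_poi <- function(grand_gfp, search_window_ms,
                               half_width_ms = 40, component = "component") {
  stopifnot(half_width_ms > 0)
  tms <- grand_gfp$times_ms
  sel <- which(tms >= search_window_ms[1] & tms <= search_window_ms[2])
  if (!length(sel)) stop("search window contains no samples")
  v <- grand_gfp$values[sel]
  flat <- diff(range(v)) == 0
  if (flat)
    warning("GFP is flat in the ", component,
            " search window; peak tie-broken to window start")
  peak_ms <- tms[sel[which.max(v)]]       # which.max takes the earliest tie
  start <- peak_ms - half_width_ms
  end <- peak_ms + half_width_ms
  clipped <- start < min(tms) || end > max(tms)
  structure(list(component = component, peak_ms = peak_ms,
                 start_ms = max(start, min(tms)), end_ms = min(end, max(tms)),
                 clipped = clipped, flat = flat),
            class = "poi")
}

#' @export
print.poi <- function(x, ...) {
  cat(sprintf("<poi> %s: peak %.1f ms, window %.1f..%.1f ms%s\n",
              x$component, x$peak_ms, x$start_ms, x$end_ms,
              if (isTRUE(x$clipped)) " (clipped)" else ""))
  invisible(x)
}

#' Component amplitude: mean individual GFP over a period of interest
#'
#' @param individual_gfp a [gfp()] series for one subject.
#' @param poi a [find_component_poi()] result (fixed on the grand average).
#' @return Mean GFP (uV) over samples with time in `[start_ms, end_ms]`,
#'   endpoints inclusive.
#' @export
component_amplitude <- function(individual_gfp, poi) {
  tms <- individual_gfp$times_ms
  if (poi$start_ms < min(tms) - 1e-9 || poi$end_ms > max(tms) + 1e-9)
    stop("POI lies outside the GFP series support")
  sel <- tms >= poi$start_ms & tms <= poi$end_ms
  mean(individual_gfp$values[sel])
}

#' Write / read epochs in the fixture format
#'
#' A directory with `header.json` (channel labels, positions, sampling
#' rate, window, trial count, condition) and `data.f32`, the voltages as
#' IEEE-754 little-endian float32 in channel-major order within each trial
#' (trial, then channel, then sample fastest).
#'
#' @param epochs an [epoch_set()].
#' @param dir output directory (created).
#' @export
write_epochs_fixture <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- epochs$data
  hdr <- list(format = "epochs-f32", version = 1L,
              n_trials = dim(d)[1], n_channels = dim(d)[2],
              n_samples = dim(d)[3],
              channels = epochs$montage$labels,
              positions_mm = unclass(unname(epochs$montage$positions_mm)),
              srate_hz = epochs$srate_hz, window_ms = epochs$window_ms,
              condition = epochs$condition,
              sample_rounding = "floor(window * srate) + 1 samples")
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA),
             file.path(dir, "header.json"))
  # trial-major blocks, each channel-major: samples vary fastest
  arr <- aperm(d, c(3, 2, 1))
  con <- file(file.path(dir, "data.f32"), "wb")
  on.exit(close(con))
  writeBin(as.vector(arr), con, size = 4L, endian = "little")
  invisible(dir)
}

#' @rdname write_epochs_fixture
#' @export
read_epochs_fixture <- function(dir) {
  hdr <- jsonlite::fromJSON(file.path(dir, "header.json"))
  n <- hdr$n_trials * hdr$n_channels * hdr$n_samples
  con <- file(file.path(dir, "data.f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  arr <- aperm(array(x, c(hdr$n_samples, hdr$n_channels, hdr$n_trials)),
               c(3, 2, 1))
  montage <- channel_montage(hdr$channels, hdr$positions_mm)
  epoch_set(arr, montage, hdr$srate_hz, hdr$window_ms, hdr$condition)
}
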