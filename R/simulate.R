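#' Ground-truth tract-symptom effects for a synthetic study
#'
#' Encodes which connections truly carry symptoms and how strongly: each
#' true edge reduces behavioral performance (slower Go reaction times,
#' more NoGo false alarms) and attenuates the N2/P3 ERP templates, linearly
#' in its disconnection severity. Effects are non-negative by construction
#' (disconnection can only worsen a symptom), matching the one-tailed
#' direction assumed by the CLSM analysis.
#'
#' @param true_edges character vector of connection keys `"a-b"` (possibly
#'   empty for a global-null study).
#' @param rt_ms_per_pct per-edge slowing of mean Go RT, ms per percent
#'   severity (scalar recycled, or named per edge).
#' @param fa_per_pct per-edge increase of the NoGo false-alarm probability
#'   per percent severity.
#' @param erp_per_pct per-edge attenuation of the ERP template scale per
#'   percent severity (scale is truncated at 0).
#' @param noise_sd named numeric: `rt_ms` (patient-level RT shift SD, ms),
#'   `fa` (patient-level FA-rate shift SD), `erp_uv` (per-sample channel
#'   noise SD, uV).
#' @param seed integer recorded with the truth.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(true_edges = character(),
                         rt_ms_per_pct = 1.5, fa_per_pct = 0.002,
                         erp_per_pct = 0.008,
                         noise_sd = c(rt_ms = 20, fa = 0.03, erp_uv = 8),
                         seed = 0L) {
  true_edges <- as.character(true_edges)
  rec <- function(x) {
    x <- if (length(x) == 1L) rep(x, length(true_edges)) else x
    stopifnot(length(x) == length(true_edges), all(x >= 0))
    stats::setNames(as.numeric(x), true_edges)
  }
  stopifnot(all(c("rt_ms", "fa", "erp_uv") %in% names(noise_sd)),
            all(noise_sd >= 0))
  structure(list(true_edges = true_edges,
                 rt_ms_per_pct = rec(rt_ms_per_pct),
                 fa_per_pct = rec(fa_per_pct),
                 erp_per_pct = rec(erp_per_pct),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

# total symptom load Sum(effect * severity) for one patient
.truth_load <- function(truth, severity_row, what) {
  if (!length(truth$true_edges)) return(0)
  miss <- setdiff(truth$true_edges, names(severity_row))
  if (length(miss))
    stop("severity row lacks true edge(s): ", paste(miss, collapse = ", "))
  sum(truth[[what]] * severity_row[truth$true_edges])
}

#' Default Go/NoGo generator parameters
#'
#' Baselines for an undamaged patient: ex-Gaussian Go reaction times
#' (mean `rt_mu + rt_tau` ms), a NoGo false-alarm probability
#' `fa_baseline`, a small Go miss probability, and a per-patient
#' calibration threshold RTt drawn around `rtt_mean_ms`. Baselines are set
#' so that a mildly affected cohort reproduces typical stroke Go/NoGo
#' statistics (mean FA near 15%, mean hit RT near 426 ms).
#'
#' @param fa_baseline baseline NoGo false-alarm probability.
#' @param rt_mu_ms,rt_sd_ms,rt_tau_ms ex-Gaussian RT parameters.
#' @param miss_prob baseline Go miss probability.
#' @param rtt_mean_ms,rtt_sd_ms distribution of the per-patient RT
#'   threshold.
#' @return Named list of parameters.
#' @export
behavior_params <- function(fa_baseline = 0.15, rt_mu_ms = 366,
                            rt_sd_ms = 50, rt_tau_ms = 60,
                            miss_prob = 0.02, rtt_mean_ms = 430,
                            rtt_sd_ms = 40) {
  list(fa_baseline = fa_baseline, rt_mu_ms = rt_mu_ms, rt_sd_ms = rt_sd_ms,
       rt_tau_ms = rt_tau_ms, miss_prob = miss_prob,
       rtt_mean_ms = rtt_mean_ms, rtt_sd_ms = rtt_sd_ms)
}

#' Simulate a Go/NoGo session for one patient
#'
#' Go reaction times are ex-Gaussian with a mean that grows linearly in the
#' patient's disconnection load on the true edges; NoGo false alarms are
#' Bernoulli with a rate that grows likewise (clamped to `[0.01, 0.99]`).
#' Responses slower than the patient's calibration threshold RTt are
#' flagged "too late" but still count as hits. With zero severities and
#' zero patient-level noise, the expected FA rate equals `fa_baseline` and
#' the expected mean hit RT equals `rt_mu_ms + rt_tau_ms`.
#'
#' @param severity_row named per-connection severity vector (percent) for
#'   the patient, aligned with the truth's edge keys.
#' @param truth a [ground_truth()].
#' @param n_go,n_nogo trial counts (default 240 each: 8 blocks of 30 + 30).
#' @param seed integer seed.
#' @param params a [behavior_params()] list.
#' @param patient_id id recorded in the output.
#' @return A `behavioral_record` (see [score_trials()]).
#' @export
simulate_behavior <- function(severity_row, truth, n_go = 240L,
                              n_nogo = 240L, seed = 1,
                              params = behavior_params(),
                              patient_id = "P001") {
  stopifnot(n_go >= 1, n_nogo >= 1)
  l_rt <- .truth_load(truth, severity_row, "rt_ms_per_pct")
  l_fa <- .truth_load(truth, severity_row, "fa_per_pct")
  withr_seed(seed, {
    rtt <- max(150, stats::rnorm(1, params$rtt_mean_ms, params$rtt_sd_ms))
    shift_rt <- stats::rnorm(1, 0, truth$noise_sd[["rt_ms"]])
    shift_fa <- stats::rnorm(1, 0, truth$noise_sd[["fa"]])
    mu <- params$rt_mu_ms + l_rt + shift_rt
    p_fa <- min(0.99, max(0.01, params$fa_baseline + l_fa + shift_fa))

    go_resp <- stats::rbinom(n_go, 1L, 1 - params$miss_prob)
    go_rt <- stats::rnorm(n_go, mu, params$rt_sd_ms) +
      stats::rexp(n_go, 1 / params$rt_tau_ms)
    go_rt <- pmax(go_rt, 120)
    nogo_resp <- stats::rbinom(n_nogo, 1L, p_fa)
    nogo_rt <- stats::rnorm(n_nogo, mu, params$rt_sd_ms) +
      stats::rexp(n_nogo, 1 / params$rt_tau_ms)
    nogo_rt <- pmax(nogo_rt, 120)

    trials <- data.frame(
      type = c(rep("go", n_go), rep("nogo", n_nogo)),
      responded = c(go_resp, nogo_resp),
      rt_ms = c(ifelse(go_resp == 1L, go_rt, NA_real_),
                ifelse(nogo_resp == 1L, nogo_rt, NA_real_)),
      stringsAsFactors = FALSE)
    trials$too_late <- as.integer(!is.na(trials$rt_ms) &
                                    trials$rt_ms > rtt &
                                    trials$type == "go")
    # interleave trial order (randomized presentation)
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
    rownames(trials) <- NULL
    list(patient_id = patient_id, rtt_ms = rtt, trials = trials)
  })
}

#' Simulate stimulus-locked NoGo epochs for one patient
#'
#' Each trial is i.i.d. Gaussian channel noise plus two phenomenological
#' ERP templates: an N2 (frontocentral negativity, Gaussian time course
#' centered 300 ms) and a P3 (centroparietal positivity centered 400 ms).
#' Spatial patterns are fixed zero-mean topographies, so the data already
#' satisfy the average-reference contract. Both template amplitudes are
#' scaled by `max(0, 1 - sum(effect * severity))` — the patient's
#' disconnection load attenuates the evoked response.
#'
#' @inheritParams simulate_behavior
#' @param montage a [channel_montage()] with >= 8 channels.
#' @param n_trials number of epochs (>= 1).
#' @param srate_hz sampling rate (default 1024).
#' @param window_ms epoch window (default -100..700 ms).
#' @param n2_amp_uv,p3_amp_uv template peak amplitudes (uV; the N2 one is
#'   applied with negative sign).
#' @param n2_peak_ms,p3_peak_ms,n2_sd_ms,p3_sd_ms template time courses.
#' @return An [epoch_set()] (condition "CR") with attribute
#'   `attenuation_scale`, the applied template scale.
#' @export
simulate_epochs <- function(severity_row, truth, montage, n_trials = 193L,
                            srate_hz = 1024, seed = 1,
                            window_ms = c(-100, 700),
                            n2_amp_uv = 3, p3_amp_uv = 5,
                            n2_peak_ms = 300, p3_peak_ms = 400,
                            n2_sd_ms = 20, p3_sd_ms = 25) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (length(montage$labels) < 8L) stop("montage needs >= 8 channels")
  n_samp <- n_epoch_samples(window_ms, srate_hz)
  tms <- window_ms[1] + (seq_len(n_samp) - 1L) * 1000 / srate_hz

  topo <- erp_topographies(montage)
  g_n2 <- exp(-(tms - n2_peak_ms)^2 / (2 * n2_sd_ms^2))
  g_p3 <- exp(-(tms - p3_peak_ms)^2 / (2 * p3_sd_ms^2))
  scale <- max(0, 1 - .truth_load(truth, severity_row, "erp_per_pct"))
  signal <- scale * (-n2_amp_uv * outer(topo$n2, g_n2) +
                       p3_amp_uv * outer(topo$p3, g_p3))   # ch x samples

  nc <- length(montage$labels)
  noise_sd <- truth$noise_sd[["erp_uv"]]
  data <- withr_seed(seed, {
    arr <- array(if (noise_sd > 0)
      stats::rnorm(n_trials * nc * n_samp, sd = noise_sd) else 0,
      dim = c(n_trials, nc, n_samp))
    arr + aperm(array(signal, c(nc, n_samp, n_trials)), c(3, 1, 2))
  })
  out <- epoch_set(data, montage, srate_hz, window_ms, condition = "CR")
  attr(out, "attenuation_scale") <- scale
  out
}

#' Fixed zero-mean N2/P3 topographies for a montage
#'
#' Gaussian spatial profiles around a frontocentral site (N2) and a
#' centroparietal site (P3), each demeaned across channels and normalized
#' to unit maximum absolute weight.
#'
#' @param montage a [channel_montage()].
#' @return List with unit-scale zero-mean weight vectors `n2`, `p3`.
#' @export
erp_topographies <- function(montage) {
  P <- montage$positions_mm
  R <- stats::median(sqrt(rowSums(P^2)))
  centers <- list(n2 = R * c(0, 0.45, 0.89), p3 = R * c(0, -0.20, 0.98))
  lapply(centers, function(cc) {
    w <- exp(-colSums((t(P) - cc)^2) / (2 * (0.5 * R)^2))
    w <- w - mean(w)
    w / max(abs(w))
  })
}
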