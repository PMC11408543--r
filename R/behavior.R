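#' Score a Go/NoGo trial record
#'
#' Computes the behavioral summary for one patient: hit / miss / false-alarm
#' / correct-rejection counts, hit and FA rates, mean hit reaction time, the
#' percentage of hits slower than the patient's calibration threshold
#' ("too late" hits — these still count as hits for rates and RT, and are
#' reported separately), the performance index, and log-linear-corrected
#' d-prime and criterion.
#'
#' @param record a `behavioral_record`: list with `patient_id`, `rtt_ms`
#'   (per-patient RT threshold, > 0) and `trials`, a data.frame with
#'   columns `type` ("go"/"nogo"), `responded` (0/1), `rt_ms` (NA when not
#'   responded) and `too_late` (0/1).
#' @return A one-row data.frame of class `behavioral_summary` with fields
#'   `patient_id`, `n_go`, `n_nogo`, `hits`, `misses`, `fas`, `crs`,
#'   `hit_rate`, `fa_rate`, `fa_pct`, `mean_hit_rt_ms`, `pct_too_late`,
#'   `performance_index`, `dprime`, `criterion`.
#' @export
score_trials <- function(record) {
  tr <- record$trials
  if (is.null(tr) || nrow(tr) == 0L) stop("record has no trials")
  stopifnot(all(tr$type %in% c("go", "nogo")))
  go <- tr[tr$type == "go", , drop = FALSE]
  nogo <- tr[tr$type == "nogo", , drop = FALSE]
  if (nrow(go) < 1L || nrow(nogo) < 1L)
    stop("record needs at least one go and one nogo trial")

  hits <- sum(go$responded == 1L)
  misses <- nrow(go) - hits
  fas <- sum(nogo$responded == 1L)
  crs <- nrow(nogo) - fas
  hit_rt <- go$rt_ms[go$responded == 1L]
  mean_hit_rt <- if (hits > 0) mean(hit_rt) else NA_real_
  pct_too_late <- if (hits > 0) 100 * sum(go$too_late[go$responded == 1L]) / hits
  else NA_real_
  fa_pct <- 100 * fas / nrow(nogo)
  pi <- if (hits > 0) performance_index(fa_pct, mean_hit_rt) else NA_real_
  dc <- dprime_loglinear(hits, misses, fas, crs)

  out <- data.frame(patient_id = record$patient_id %||% NA_character_,
                    n_go = nrow(go), n_nogo = nrow(nogo),
                    hits = hits, misses = misses, fas = fas, crs = crs,
                    hit_rate = hits / nrow(go), fa_rate = fas / nrow(nogo),
                    fa_pct = fa_pct, mean_hit_rt_ms = mean_hit_rt,
                    pct_too_late = pct_too_late,
                    performance_index = pi,
                    dprime = dc[["dprime"]], criterion = dc[["criterion"]],
                    stringsAsFactors = FALSE)
  class(out) <- c("behavioral_summary", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Go/NoGo performance index
#'
#' `(100 - fa_pct) / mean_hit_rt_ms`: accuracy credit (100 minus the
#' false-alarm percentage) per millisecond of mean correct-Go reaction time.
#' Higher is better; the index rewards both speed and accuracy and so is
#' insensitive to a speed-accuracy trade-off.
#'
#' @param fa_pct false-alarm percentage in `[0, 100]`.
#' @param mean_hit_rt_ms mean reaction time over correct Go responses, > 0.
#' @return A scalar, strictly decreasing in both arguments.
#' @export
#' @examples
#' performance_index(0, 100)   # 1
#' performance_index(15, 426.2)
performance_index <- function(fa_pct, mean_hit_rt_ms) {
  stopifnot(fa_pct >= 0, fa_pct <= 100)
  if (!all(mean_hit_rt_ms > 0)) stop("mean_hit_rt_ms must be > 0")
  (100 - fa_pct) / mean_hit_rt_ms
}

#' Signal-detection d-prime and criterion with the log-linear correction
#'
#' Adds 0.5 to every cell of the 2 x 2 contingency table before computing
#' hit and false-alarm rates (the log-linear correction), so corrected rates
#' are strictly inside (0, 1) even for perfect or null performance. Then
#' `dprime = z(H) - z(F)` and `criterion = -(z(H) + z(F)) / 2`, with `z` the
#' standard-normal quantile, `H = (hits + 0.5) / (hits + misses + 1)` and
#' `F = (fas + 0.5) / (fas + crs + 1)`.
#'
#' @param hits,misses,fas,crs non-negative trial counts; `hits + misses >= 1`
#'   and `fas + crs >= 1`.
#' @return Named numeric vector `c(dprime = , criterion = )`.
#' @export
#' @examples
#' dprime_loglinear(15, 15, 15, 15)  # d' = 0, c = 0
dprime_loglinear <- function(hits, misses, fas, crs) {
  stopifnot(hits >= 0, misses >= 0, fas >= 0, crs >= 0,
            hits + misses >= 1, fas + crs >= 1)
  H <- (hits + 0.5) / (hits + misses + 1)
  F <- (fas + 0.5) / (fas + crs + 1)
  zh <- stats::qnorm(H)
  zf <- stats::qnorm(F)
  c(dprime = zh - zf, criterion = -(zh + zf) / 2)
}

#' Write / read Go/NoGo trial records as TSV
#'
#' Long format, one trial per row: `patient`, `trial`, `type` (go/nogo),
#' `response` (0/1), `rt_ms` (empty when no response), `too_late` (0/1),
#' `rtt_ms` (the patient's calibration threshold, repeated per row).
#'
#' @param records list of `behavioral_record`s.
#' @param path TSV file.
#' @export
write_behavior_tsv <- function(records, path) {
  rows <- lapply(records, function(r) {
    tr <- r$trials
    data.frame(patient = r$patient_id, trial = seq_len(nrow(tr)),
               type = tr$type, response = tr$responded, rt_ms = tr$rt_ms,
               too_late = tr$too_late, rtt_ms = r$rtt_ms,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(d, d$patient), function(p) {
    list(patient_id = p$patient[1], rtt_ms = p$rtt_ms[1],
         trials = data.frame(type = p$type, responded = p$response,
                             rt_ms = p$rt_ms, too_late = p$too_late,
                             stringsAsFactors = FALSE))
  })
}

#' Score a whole cohort
#'
#' @param records list of `behavioral_record`s.
#' @return A data.frame with one [score_trials()] row per patient.
#' @export
score_cohort <- function(records) {
  out <- do.call(rbind, lapply(records, score_trials))
  rownames(out) <- NULL
  out
}
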