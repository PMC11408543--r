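#' Extract the three symptom vectors from a study
#'
#' Behavioral scoring gives the performance index; the ERP branch follows
#' the fixed recipe: per patient, average-reference and baseline-correct
#' the correct-rejection epochs, average them, take the GFP; fix the N2 and
#' P3 periods of interest on the grand average of all subjects' ERPs, then
#' average each individual GFP over those shared windows. Patients lacking
#' EEG are dropped from the ERP symptoms only (the count is reported).
#'
#' @param study a [make_study()] result (or a compatible list with
#'   `behavior`, `epochs`, `config`).
#' @return List with `performance_index`, `n2_gfp`, `p3_gfp`
#'   ([symptom_vector()]s), `behavior_table`, `poi` (list with `n2`, `p3`),
#'   `grand_gfp`, `n_missing_eeg`.
#' @export
extract_symptoms <- function(study) {
  cfg <- study$config
  beh <- score_cohort(study$behavior)
  pi_sym <- symptom_vector(beh$performance_index, beh$patient_id,
                           name = "performance_index")

  n2 <- p3 <- NULL; poi <- NULL; grand <- NULL; n_missing <- 0L
  if (!is.null(study$epochs)) {
    have <- !vapply(study$epochs, is.null, logical(1))
    n_missing <- sum(!have)
    eps <- study$epochs[have]
    erps <- lapply(eps, function(e)
      average_epochs(baseline_correct(rereference_average(e))))
    grand_erp <- Reduce(`+`, erps) / length(erps)
    attr(grand_erp, "times_ms") <- attr(erps[[1]], "times_ms")
    grand <- gfp(grand_erp)
    poi <- list(n2 = find_component_poi(grand, cfg$n2_window_ms,
                                        cfg$poi_half_width_ms, "N2"),
                p3 = find_component_poi(grand, cfg$p3_window_ms,
                                        cfg$poi_half_width_ms, "P3"))
    ind_gfp <- lapply(erps, gfp)
    n2 <- symptom_vector(vapply(ind_gfp, component_amplitude, numeric(1),
                                poi = poi$n2), names(eps), name = "n2_gfp")
    p3 <- symptom_vector(vapply(ind_gfp, component_amplitude, numeric(1),
                                poi = poi$p3), names(eps), name = "p3_gfp")
  }
  list(performance_index = pi_sym, n2_gfp = n2, p3_gfp = p3,
       behavior_table = beh, poi = poi, grand_gfp = grand,
       n_missing_eeg = n_missing)
}

#' Validate the consistency of a study's inputs
#'
#' Checks grid agreement between lesions, parcellation and streamlines,
#' patient-id alignment of the behavioral and EEG branches, and analysis
#' parameter ranges. Returns a report instead of failing, so callers can
#' decide what is fatal.
#'
#' @param study a [make_study()] result or compatible list.
#' @return data.frame with columns `check`, `ok`, `detail`; zero
#'   failing rows on a clean study.
#' @export
validate_inputs <- function(study) {
  rep <- list()
  add <- function(check, ok, detail = "")
    rep[[length(rep) + 1L]] <<- data.frame(check = check, ok = ok,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  g <- study$atlas$grid
  for (nm in names(study$lesions)) {
    gl <- vol_grid(study$lesions[[nm]])
    if (!same_grid(g, gl))
      add("lesion_grid", FALSE,
          sprintf("%s: lesion grid %s vs atlas grid %s", nm,
                  paste(gl$dims, collapse = "x"),
                  paste(g$dims, collapse = "x")))
  }
  if (!length(rep)) add("lesion_grid", TRUE, "all lesions on the atlas grid")
  add("streamline_grid", same_grid(g, study$streamlines$grid),
      "streamline atlas grid matches parcellation")
  pid <- rownames(study$matrix)
  add("behavior_alignment",
      setequal(pid, names(study$behavior)),
      sprintf("%d behavior records for %d patients",
              length(study$behavior), length(pid)))
  if (!is.null(study$epochs)) {
    have <- names(study$epochs)[!vapply(study$epochs, is.null, logical(1))]
    miss <- setdiff(pid, have)
    add("eeg_alignment", TRUE,
        if (length(miss))
          sprintf("%d patient(s) without EEG dropped from ERP symptoms: %s",
                  length(miss), paste(miss, collapse = ", "))
        else "EEG present for all patients")
  }
  cfg <- study$config
  add("alpha_range", cfg$alpha > 0 && cfg$alpha <= 0.5,
      sprintf("alpha = %g", cfg$alpha))
  add("min_patients_range",
      cfg$min_patients_behavior >= 1 && cfg$min_patients_erp >= 1,
      sprintf("min_patients %d / %d", cfg$min_patients_behavior,
              cfg$min_patients_erp))
  out <- do.call(rbind, rep)
  rownames(out) <- NULL
  out
}

#' Run the full CLSM pipeline on a synthetic study
#'
#' simulate (optional) -> behavioral scoring -> ERP/GFP symptoms ->
#' disconnection matrix -> damage filter -> one CLSM permutation fit per
#' symptom; writes all intermediate tables and a manifest from which the
#' run can be reproduced bit-identically.
#'
#' @param config a [study_config()]; ignored when `study` is given.
#' @param out_dir output directory (created). `NULL` skips all file output.
#' @param study optionally a pre-built [make_study()] result.
#' @return Invisibly, a list of class `clsm_run`: `study`, `symptoms`,
#'   `filtered` (matrices per analysis), `fits` (list of [clsm()] objects),
#'   `coverage`, `manifest`.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         study = NULL) {
  if (is.null(study)) study <- make_study(config)
  config <- study$config
  v <- validate_inputs(study)
  if (any(!v$ok))
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", v$check[!v$ok], v$detail[!v$ok]),
               collapse = "\n"))

  symptoms <- extract_symptoms(study)
  dmat <- study$matrix

  analyses <- list(
    performance_index = list(symptom = symptoms$performance_index,
                             min_patients = config$min_patients_behavior),
    n2_gfp = list(symptom = symptoms$n2_gfp,
                  min_patients = config$min_patients_erp),
    p3_gfp = list(symptom = symptoms$p3_gfp,
                  min_patients = config$min_patients_erp))
  analyses <- Filter(function(a) !is.null(a$symptom), analyses)

  fits <- list(); filtered <- list()
  for (nm in names(analyses)) {
    a <- analyses[[nm]]
    keep <- intersect(rownames(dmat), a$symptom$patient_ids)
    m <- dmat[keep, , drop = FALSE]
    class(m) <- class(dmat)
    fm <- filter_connections(m, a$min_patients, config$damage_threshold)
    filtered[[nm]] <- fm
    if (ncol(fm) == 0L)
      warning("no connections survive the damage filter for ", nm)
    fits[[nm]] <- suppressWarnings(
      clsm(fm, a$symptom, n_permutations = config$n_permutations,
           alpha = config$alpha, seed = substream_seed(config$seed, 7)))
  }

  coverage <- coverage_map(study$lesions, study$streamlines,
                           min_patients = config$min_patients_behavior)

  config_out <- unclass(config)
  config_out$noise_sd <- as.list(config$noise_sd)  # keep names in JSON
  manifest <- list(
    package = "clsmr",
    version = as.character(utils::packageVersion("clsmr")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_out,
    seeds = list(master = config$seed,
                 clsm = substream_seed(config$seed, 7)),
    n_patients_per_analysis = lapply(filtered, nrow),
    n_connections_per_analysis = lapply(filtered, ncol),
    n_missing_eeg = symptoms$n_missing_eeg,
    poi = if (!is.null(symptoms$poi))
      lapply(symptoms$poi, function(p)
        list(component = p$component, peak_ms = p$peak_ms,
             start_ms = p$start_ms, end_ms = p$end_ms)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(symptoms$behavior_table,
                       file.path(out_dir, "behavior_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_matrix_tsv(dmat, file.path(out_dir, "disconnection_matrix.tsv"))
    if (!is.null(symptoms$grand_gfp))
      utils::write.table(
        data.frame(time_ms = symptoms$grand_gfp$times_ms,
                   gfp_uv = symptoms$grand_gfp$values),
        file.path(out_dir, "grand_gfp.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(fits)) {
      s <- summary(fits[[nm]])$table
      utils::write.table(s, file.path(out_dir, paste0("clsm_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_nifti_volume(coverage$counts,
                       file.path(out_dir, "coverage_counts.nii.gz"))
    write_nifti_volume(coverage$mask,
                       file.path(out_dir, "coverage_mask.nii.gz"))
    manifest$files <- as.list(tools::md5sum(list.files(out_dir,
                                                       full.names = TRUE)))
    names(manifest$files) <- basename(names(manifest$files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(structure(list(study = study, symptoms = symptoms,
                           filtered = filtered, fits = fits,
                           coverage = coverage, manifest = manifest),
                      class = "clsm_run"))
}

#' @export
print.clsm_run <- function(x, ...) {
  cat("<clsm_run>\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-18s %3d connections, %d significant at alpha=%g\n",
                nm, length(f$connection), sum(f$significant), f$alpha))
  }
  invisible(x)
}

#' Re-run a pipeline from a saved manifest
#'
#' Rebuilds the [study_config()] recorded in a `manifest.json` and replays
#' the pipeline; deterministic outputs (disconnection matrix, statistics,
#' p-values) reproduce bit-identically.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir optional output directory for the replay.
#' @return The new `clsm_run`.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::fromJSON(manifest_path)
  cfg <- man$config
  cfg$noise_sd <- unlist(cfg$noise_sd)
  cfg <- do.call(study_config, cfg[names(cfg) %in%
                                     names(formals(study_config))])
  run_pipeline(cfg, out_dir = out_dir)
}

#' Write / read a disconnection matrix as TSV
#'
#' Patients in rows (first column `patient`), connections in `"a-b"`
#' columns.
#'
#' @param m a [disconnection_matrix()].
#' @param path TSV file.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(patient = rownames(m), as.data.frame(unclass(m),
                                                       check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$patient
  class(m) <- c("disconnection_matrix", "matrix", "array")
  m
}
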