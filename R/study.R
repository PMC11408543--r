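#' Configuration of a synthetic CLSM study
#'
#' Bundles every generator and analysis parameter with the master seed.
#' Defaults mirror the acquisition they emulate where that is fixed
#' (96 patients with unilateral lesions of 0.001-1.72% brain volume and a
#' 28/96 right-side ratio; 240 Go + 240 NoGo trials; 64-channel EEG at
#' 1024 Hz, epochs -100..700 ms; on average 193 retained correct-rejection
#' epochs) and otherwise use phantom sizes chosen for tractable synthetic
#' studies (48^3 grid, 20 parcels, 150 bundles of 8 streamlines). Analysis
#' defaults: connections damaged in >= 7 patients, alpha 0.05, 5000
#' permutations, POI half-width 40 ms.
#'
#' @param grid_dims,voxel_size_mm phantom grid.
#' @param n_parcels,n_connections,streamlines_per_connection,jitter_sd_mm
#'   connectome generation.
#' @param n_patients,volume_pct_range,side_ratio_right lesion cohort.
#' @param n_go,n_nogo behavioral trials per patient.
#' @param n_channels,srate_hz,window_ms,n_epoch_trials EEG generation.
#' @param simulate_eeg generate epochs at all (disable for purely
#'   behavioral studies).
#' @param n_true_edges,rt_effect,fa_effect,erp_effect,noise_sd planted
#'   ground truth; `n_true_edges = 0` gives a global-null study.
#' @param behavior a [behavior_params()] list.
#' @param min_patients_behavior,min_patients_erp damage filters for the
#'   behavioral and ERP analyses.
#' @param alpha,n_permutations,poi_half_width_ms,damage_threshold analysis
#'   parameters.
#' @param n2_window_ms,p3_window_ms GFP peak search windows.
#' @param seed master seed; all stage seeds are derived substreams.
#' @return Object of class `study_config` (a named list).
#' @export
study_config <- function(grid_dims = c(48, 48, 48), voxel_size_mm = 1,
                         n_parcels = 20L, n_connections = 150L,
                         streamlines_per_connection = 8L, jitter_sd_mm = 2,
                         n_patients = 96L,
                         volume_pct_range = c(0.001, 1.72),
                         side_ratio_right = 28 / 96,
                         n_go = 240L, n_nogo = 240L,
                         n_channels = 64L, srate_hz = 1024,
                         window_ms = c(-100, 700), n_epoch_trials = 193L,
                         simulate_eeg = TRUE,
                         n_true_edges = 0L, rt_effect = 1.5,
                         fa_effect = 0.002, erp_effect = 0.008,
                         noise_sd = c(rt_ms = 20, fa = 0.03, erp_uv = 8),
                         behavior = behavior_params(),
                         min_patients_behavior = 7L, min_patients_erp = 7L,
                         alpha = 0.05, n_permutations = 5000L,
                         poi_half_width_ms = 40,
                         n2_window_ms = c(200, 350),
                         p3_window_ms = c(330, 500),
                         damage_threshold = 0,
                         seed = 42L) {
  cfg <- as.list(environment())
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d patients, %d parcels, %d bundles, %d true edges, seed %d\n",
              x$n_patients, x$n_parcels, x$n_connections, x$n_true_edges,
              x$seed))
  invisible(x)
}

# draw distinct parcel pairs for the connectome
sample_connection_spec <- function(atlas, n_connections,
                                   streamlines_per_connection, seed) {
  ids <- atlas$parcel_table$id
  pairs <- t(utils::combn(ids, 2L))
  if (n_connections > nrow(pairs))
    stop("requested ", n_connections, " connections but only ",
         nrow(pairs), " parcel pairs exist")
  sel <- withr_seed(seed, sample.int(nrow(pairs), n_connections))
  data.frame(parcel_a = pairs[sel, 1], parcel_b = pairs[sel, 2],
             n_streamlines = streamlines_per_connection)
}

#' Generate a complete synthetic study
#'
#' Orchestrates the generators in causal order: phantom brain, streamline
#' atlas, lesion cohort, then the disconnection-severity matrix computed
#' with the same machinery the analysis uses, and finally behavior and EEG
#' simulated *from* those severities — so symptoms are causally downstream
#' of disconnection, exactly the structure the CLSM analysis assumes.
#' Planted true edges are picked among the connections damaged in the most
#' patients (a deterministic pre-symptom choice), so planted effects are
#' identifiable in the cohort.
#'
#' @param config a [study_config()].
#' @return Object of class `synthetic_study`: list with `config`, `atlas`,
#'   `streamlines`, `index`, `lesions`, `matrix` (the
#'   [disconnection_matrix()]), `truth`, `behavior` (records),
#'   `epochs` (list of [epoch_set()]s or `NULL`).
#' @export
make_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  grid <- grid_spec(config$grid_dims, config$voxel_size_mm)
  atlas <- make_phantom_brain(grid, config$n_parcels,
                              seed = substream_seed(seed, 1))
  cs <- sample_connection_spec(atlas, config$n_connections,
                               config$streamlines_per_connection,
                               seed = substream_seed(seed, 2))
  streamlines <- make_streamline_atlas(atlas, cs,
                                       jitter_sd_mm = config$jitter_sd_mm,
                                       seed = substream_seed(seed, 3))
  index <- assign_endpoints(streamlines, atlas$parcellation)
  lesions <- sample_lesions(atlas, config$n_patients,
                            volume_pct_range = config$volume_pct_range,
                            side_ratio_right = config$side_ratio_right,
                            seed = substream_seed(seed, 4))
  dmat <- disconnection_matrix(lesions, streamlines, index)

  true_edges <- character()
  if (config$n_true_edges > 0L) {
    n_damaged <- colSums(dmat > config$damage_threshold)
    ord <- order(n_damaged, decreasing = TRUE)
    true_edges <- colnames(dmat)[ord[seq_len(min(config$n_true_edges,
                                                 ncol(dmat)))]]
  }
  truth <- ground_truth(true_edges, rt_ms_per_pct = config$rt_effect,
                        fa_per_pct = config$fa_effect,
                        erp_per_pct = config$erp_effect,
                        noise_sd = config$noise_sd,
                        seed = substream_seed(seed, 5))

  behavior <- lapply(seq_len(config$n_patients), function(i)
    simulate_behavior(dmat[i, ], truth, n_go = config$n_go,
                      n_nogo = config$n_nogo,
                      seed = substream_seed(seed, 100 + i),
                      params = config$behavior,
                      patient_id = rownames(dmat)[i]))
  names(behavior) <- rownames(dmat)

  epochs <- NULL
  if (isTRUE(config$simulate_eeg)) {
    montage <- make_montage(config$n_channels)
    epochs <- lapply(seq_len(config$n_patients), function(i)
      simulate_epochs(dmat[i, ], truth, montage,
                      n_trials = config$n_epoch_trials,
                      srate_hz = config$srate_hz,
                      window_ms = config$window_ms,
                      seed = substream_seed(seed, 10000 + i)))
    names(epochs) <- rownames(dmat)
  }

  structure(list(config = config, atlas = atlas, streamlines = streamlines,
                 index = index, lesions = lesions, matrix = dmat,
                 truth = truth, behavior = behavior, epochs = epochs),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d patients, %d connections (%d true edges), seed %d\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth$true_edges),
              x$config$seed))
  invisible(x)
}
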