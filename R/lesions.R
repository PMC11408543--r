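#' Sample a cohort of synthetic unilateral lesions
#'
#' Draws one connected lesion mask per patient. Lesion volume, expressed as a
#' percentage of the brain-mask volume, is drawn log-uniformly over
#' `volume_pct_range` — matching the strong right skew of clinical stroke
#' cohorts where the median lesion is far smaller than the mean. Each lesion
#' is confined to a single hemisphere, drawn with probability
#' `side_ratio_right` for the right side, and grown from a random seed voxel
#' by stochastic dilation: at each step a random subset of the blob's
#' 6-neighborhood is annexed, which yields irregular but 6-connected masks of
#' exactly the target voxel count.
#'
#' @param atlas a [make_phantom_brain()] result.
#' @param n_patients number of lesions to draw.
#' @param volume_pct_range length-2 numeric, `(low, high)` percent of brain
#'   volume, `0 < low < high`. Default `c(0.001, 1.72)`, the span reported
#'   for unselected first-stroke cohorts.
#' @param side_ratio_right probability a lesion is right-hemispheric.
#'   Default `28/96`.
#' @param seed integer seed.
#' @param growth_prob per-step probability that an eligible boundary
#'   neighbor is annexed; lower values give more irregular blobs.
#' @return List of binary [label_volume()] lesion masks, named
#'   `P001, P002, ...`; each carries attributes `hemisphere` and
#'   `volume_pct`.
#' @export
sample_lesions <- function(atlas, n_patients,
                           volume_pct_range = c(0.001, 1.72),
                           side_ratio_right = 28 / 96,
                           seed = 1, growth_prob = 0.6) {
  stopifnot(inherits(atlas, "phantom_atlas"), n_patients >= 1)
  lo <- volume_pct_range[1]; hi <- volume_pct_range[2]
  if (!(lo > 0 && hi > lo)) stop("need 0 < low < high volume percentages")
  stopifnot(side_ratio_right >= 0, side_ratio_right <= 1)

  grid <- atlas$grid
  dims <- grid$dims
  brain <- atlas$brain_mask
  hemi <- atlas$hemispheres
  brain_vol <- sum(brain)
  hemi_vox <- lapply(1:2, function(h) which(brain == 1L & hemi == h))
  hemi_sizes <- vapply(hemi_vox, length, integer(1))

  lesions <- vector("list", n_patients)
  withr_seed(seed, {
    sides <- 1L + stats::rbinom(n_patients, 1L, side_ratio_right) # 2 = right
    pcts <- exp(stats::runif(n_patients, log(lo), log(hi)))
    for (i in seq_len(n_patients)) {
      target <- max(1L, as.integer(round(pcts[i] / 100 * brain_vol)))
      h <- sides[i]
      if (target > hemi_sizes[h])
        stop("requested lesion volume (", target,
             " voxels) exceeds hemisphere volume (", hemi_sizes[h], ")")
      region <- logical(prod(dims))
      region[hemi_vox[[h]]] <- TRUE
      les <- .grow_blob(dims, region, target, growth_prob)
      vol <- label_volume(array(les, dims), grid)
      attr(vol, "hemisphere") <- c("L", "R")[h]
      attr(vol, "volume_pct") <- 100 * target / brain_vol
      lesions[[i]] <- vol
    }
  })
  names(lesions) <- sprintf("P%03d", seq_len(n_patients))
  lesions
}

# grow a 6-connected blob of `target` voxels inside `region` (logical vector
# over the linear grid); returns integer vector 0/1 over the grid
.grow_blob <- function(dims, region, target, growth_prob) {
  idx_region <- which(region)
  start <- idx_region[sample.int(length(idx_region), 1L)]
  les <- integer(prod(dims))
  les[start] <- 1L
  n_now <- 1L
  # linear-index offsets of the 6-neighborhood, with wraparound guarded by
  # coordinate checks below
  frontier <- start
  coords <- function(lin) {
    lin0 <- lin - 1L
    i <- lin0 %% dims[1] + 1L
    j <- (lin0 %/% dims[1]) %% dims[2] + 1L
    k <- lin0 %/% (dims[1] * dims[2]) + 1L
    cbind(i, j, k)
  }
  while (n_now < target) {
    fv <- coords(frontier)
    nb <- .neighbors6(fv, dims)
    nb_lin <- voxel_linear_index(nb, dims)
    cand <- unique(nb_lin[region[nb_lin] & les[nb_lin] == 0L])
    if (!length(cand)) {
      # boundary locked in (hemisphere exhausted around the blob): widen the
      # frontier to the whole blob and retry; if still empty, give up
      frontier <- which(les == 1L)
      fv <- coords(frontier)
      nb <- .neighbors6(fv, dims)
      nb_lin <- voxel_linear_index(nb, dims)
      cand <- unique(nb_lin[region[nb_lin] & les[nb_lin] == 0L])
      if (!length(cand))
        stop("lesion growth stalled: target volume not reachable inside ",
             "the hemisphere")
    }
    take <- cand[stats::runif(length(cand)) < growth_prob]
    if (!length(take)) take <- cand[sample.int(length(cand), 1L)]
    need <- target - n_now
    if (length(take) > need)
      take <- take[sample.int(length(take), need)]
    les[take] <- 1L
    n_now <- n_now + length(take)
    frontier <- take
  }
  les
}
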