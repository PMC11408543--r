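#' Generate an ellipsoidal phantom brain with a bihemispheric parcellation
#'
#' Builds a synthetic "brain": an ellipsoidal binary mask bisected into left
#' and right hemispheres along the first axis, parcellated into `n_parcels`
#' compact gray-matter regions. Parcels are split evenly between hemispheres;
#' within each hemisphere most parcels tile a cortex-like outer shell and the
#' remainder sit in a deep "subcortical" core, mimicking the mixed
#' cortical/subcortical parcellations used in lesion-network studies. The
#' mid-depth band between shell and core is left unlabeled and plays the role
#' of white matter through which streamlines run.
#'
#' @param grid a [grid_spec()].
#' @param n_parcels even integer >= 4; total number of parcels.
#' @param seed integer seed; the construction is deterministic given it.
#' @param subcortical_fraction fraction of each hemisphere's parcels placed
#'   in the deep core (default 0.25).
#' @return An object of class `phantom_atlas`: list with `grid`,
#'   `brain_mask` and `parcellation` ([label_volume()]s), `hemispheres`
#'   (label volume, 1 = left, 2 = right) and `parcel_table` (data.frame with
#'   `id`, `name`, `hemisphere`, `tissue`).
#' @export
#' @examples
#' atl <- make_phantom_brain(grid_spec(c(32, 32, 32)), n_parcels = 4, seed = 1)
make_phantom_brain <- function(grid, n_parcels, seed,
                               subcortical_fraction = 0.25) {
  stopifnot(inherits(grid, "grid_spec"))
  n_parcels <- as.integer(n_parcels)
  if (n_parcels < 4L || n_parcels %% 2L != 0L)
    stop("n_parcels must be an even integer >= 4")

  dims <- grid$dims
  cx <- (dims + 1) / 2
  semi <- 0.45 * dims
  ax <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                    k = seq_len(dims[3]))
  # normalized ellipsoidal radius in [0, 1] inside the mask
  r2 <- ((ax$i - cx[1]) / semi[1])^2 + ((ax$j - cx[2]) / semi[2])^2 +
    ((ax$k - cx[3]) / semi[3])^2
  inside <- r2 <= 1
  mask <- array(0L, dims)
  mask[cbind(ax$i, ax$j, ax$k)[inside, , drop = FALSE]] <- 1L

  hemi <- array(0L, dims)
  left <- inside & ax$i < cx[1]
  right <- inside & ax$i > cx[1]
  hemi[as.matrix(ax)[left, , drop = FALSE]] <- 1L
  hemi[as.matrix(ax)[right, , drop = FALSE]] <- 2L
  # voxels on the exact midline (odd first dimension) stay hemisphere 0 but
  # remain part of the brain mask

  rr <- sqrt(pmax(r2, 0))
  shell <- inside & rr >= 0.70
  core <- inside & rr < 0.45

  per_hemi <- n_parcels %/% 2L
  n_sub <- max(if (per_hemi >= 4L) 1L else 0L,
               as.integer(round(subcortical_fraction * per_hemi)))
  n_sub <- min(n_sub, per_hemi - 1L)
  n_ctx <- per_hemi - n_sub

  vox <- as.matrix(ax)
  parc <- array(0L, dims)
  tab <- list()
  next_id <- 1L

  withr_seed(seed, {
    for (h in 1:2) {
      hname <- c("L", "R")[h]
      hmask <- if (h == 1) left else right
      ctx_vox <- vox[shell & hmask, , drop = FALSE]
      sub_vox <- vox[core & hmask, , drop = FALSE]
      if (nrow(ctx_vox) < n_ctx || nrow(sub_vox) < max(n_sub, 1L)) {
        lim <- which.min(dims)
        stop("grid too small to host ", n_parcels, " disjoint parcels; ",
             "limiting dimension is axis ", lim, " (", dims[lim],
             " voxels)")
      }
      seeds_ctx <- ctx_vox[sample.int(nrow(ctx_vox), n_ctx), , drop = FALSE]
      assign_ctx <- .nearest_seed(ctx_vox, seeds_ctx)
      parc[ctx_vox] <- next_id - 1L + assign_ctx
      for (p in seq_len(n_ctx))
        tab[[length(tab) + 1L]] <- data.frame(
          id = next_id - 1L + p,
          name = sprintf("%s_ctx_%02d", hname, p),
          hemisphere = hname, tissue = "cortical",
          stringsAsFactors = FALSE)
      next_id <- next_id + n_ctx
      if (n_sub > 0L) {
        seeds_sub <- sub_vox[sample.int(nrow(sub_vox), n_sub), , drop = FALSE]
        assign_sub <- .nearest_seed(sub_vox, seeds_sub)
        parc[sub_vox] <- next_id - 1L + assign_sub
        for (p in seq_len(n_sub))
          tab[[length(tab) + 1L]] <- data.frame(
            id = next_id - 1L + p,
            name = sprintf("%s_sub_%02d", hname, p),
            hemisphere = hname, tissue = "subcortical",
            stringsAsFactors = FALSE)
        next_id <- next_id + n_sub
      }
    }
  })

  parcel_table <- do.call(rbind, tab)
  structure(list(grid = grid,
                 brain_mask = label_volume(mask, grid),
                 parcellation = label_volume(parc, grid),
                 hemispheres = label_volume(hemi, grid),
                 parcel_table = parcel_table),
            class = "phantom_atlas")
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("<phantom_atlas> %s grid, %d brain voxels, %d parcels (%d L / %d R)\n",
              paste(x$grid$dims, collapse = "x"), sum(x$brain_mask),
              nrow(x$parcel_table),
              sum(x$parcel_table$hemisphere == "L"),
              sum(x$parcel_table$hemisphere == "R")))
  invisible(x)
}

# index of nearest seed (euclidean, voxel units) for each row of vox
.nearest_seed <- function(vox, seeds) {
  d2 <- outer(rowSums(vox^2), rep(1, nrow(seeds))) +
    outer(rep(1, nrow(vox)), rowSums(seeds^2)) -
    2 * vox %*% t(seeds)
  max.col(-d2, ties.method = "first")
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# derive a bounded substream seed from a master seed and a stage offset
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919 * k) %% 2147483647)
}
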