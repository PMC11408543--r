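# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorized implementations.

# severity per connection by testing every (streamline, voxel) pair
oracle_severity <- function(lesion, streamlines, index) {
  les <- which(lesion != 0L)
  dims <- streamlines$grid$dims
  hit_sl <- logical(length(streamlines$paths))
  for (s in seq_along(streamlines$paths)) {
    p <- streamlines$paths[[s]]
    for (v in seq_len(nrow(p))) {
      lin <- (p[v, 1] - 1) + dims[1] * ((p[v, 2] - 1) + dims[2] * (p[v, 3] - 1)) + 1
      if (lin %in% les) { hit_sl[s] <- TRUE; break }
    }
  }
  sev <- numeric(nrow(index$connections))
  for (ci in seq_len(nrow(index$connections))) {
    mem <- index$members[[ci]]
    sev[ci] <- 100 * sum(hit_sl[mem]) / length(mem)
  }
  names(sev) <- index$connections$connection
  sev
}

oracle_voxel_map <- function(lesion, streamlines) {
  dims <- streamlines$grid$dims
  out <- array(0L, dims)
  for (s in seq_along(streamlines$paths)) {
    p <- streamlines$paths[[s]]
    hit <- FALSE
    for (v in seq_len(nrow(p)))
      if (lesion[p[v, 1], p[v, 2], p[v, 3]] != 0L) { hit <- TRUE; break }
    if (hit)
      for (v in seq_len(nrow(p))) out[p[v, 1], p[v, 2], p[v, 3]] <- 1L
  }
  out
}

oracle_coverage <- function(lesions, streamlines) {
  dims <- streamlines$grid$dims
  counts <- array(0L, dims)
  for (l in lesions) counts <- counts + oracle_voxel_map(l, streamlines)
  counts
}

# random jagged-but-connected voxel path by random unit steps, independent
# of the package's curve generator
random_step_path <- function(dims, len, start = NULL) {
  if (is.null(start))
    start <- sapply(dims, function(d) sample.int(d, 1))
  p <- matrix(0L, len, 3)
  p[1, ] <- as.integer(start)
  for (i in 2:len) {
    repeat {
      step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      if (all(step == 0L)) next
      nxt <- p[i - 1, ] + step
      if (all(nxt >= 1L) && all(nxt <= dims)) break
    }
    p[i, ] <- nxt
  }
  p
}

# random disconnectome instance on a small grid: random parcellation
# spheres + random step streamlines + random lesion
random_instance <- function(dim1 = 16L, n_parcels = 4L, n_streamlines = 30L,
                            lesion_frac = 0.02) {
  dims <- rep(as.integer(dim1), 3)
  g <- grid_spec(dims)
  parc <- array(0L, dims)
  centers <- matrix(0L, n_parcels, 3)
  for (p in seq_len(n_parcels)) {
    centers[p, ] <- sapply(dims, function(d) sample.int(d, 1))
    # small cube parcel
    rng <- lapply(1:3, function(a)
      max(1, centers[p, a] - 1):min(dims[a], centers[p, a] + 1))
    parc[rng[[1]], rng[[2]], rng[[3]]] <- p
  }
  paths <- lapply(seq_len(n_streamlines), function(s) {
    st <- centers[sample.int(n_parcels, 1), ]
    random_step_path(dims, len = sample(5:20, 1), start = st)
  })
  sls <- streamline_set(g, paths)
  les <- array(0L, dims)
  n_les <- max(1L, round(lesion_frac * prod(dims)))
  les[sample.int(prod(dims), n_les)] <- 1L
  list(grid = g, parcellation = label_volume(parc, g),
       streamlines = sls, lesion = label_volume(les, g))
}

# number of 6-connected components among the nonzero voxels
n_components6 <- function(vol) {
  vox <- which(vol != 0L, arr.ind = TRUE)
  if (nrow(vox) == 0L) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  remaining <- new.env()
  for (k in key(vox)) assign(k, TRUE, envir = remaining)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comps <- 0L
  while (length(ls(remaining)) > 0L) {
    comps <- comps + 1L
    seedk <- ls(remaining)[1]
    queue <- list(as.integer(strsplit(seedk, " ")[[1]]))
    rm(list = seedk, envir = remaining)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(6)) {
        nb <- cur + offs[o, ]
        k <- paste(nb[1], nb[2], nb[3])
        if (exists(k, envir = remaining, inherits = FALSE)) {
          rm(list = k, envir = remaining)
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  comps
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# exhaustive max-statistic permutation p-value for a severity matrix and
# symptom, using plain lm() per edge as the statistic oracle
oracle_exhaustive_p <- function(X, y) {
  n <- length(y)
  perms <- all_permutations(n)
  stat_one <- function(yy) {
    ts <- apply(X, 2, function(x) {
      f <- stats::lm(yy ~ x)
      -summary(f)$coefficients["x", "t value"]
    })
    max(ts)
  }
  t_obs <- apply(X, 2, function(x) {
    f <- stats::lm(y ~ x)
    -summary(f)$coefficients["x", "t value"]
  })
  maxes <- apply(perms, 1, function(pp) stat_one(y[pp]))
  sapply(t_obs, function(t) mean(maxes >= t))
}

# small scaled study configuration shared across tests; overrides win
tiny_config <- function(...) {
  defaults <- list(grid_dims = c(32, 32, 32), n_parcels = 10L,
                   n_connections = 30L, streamlines_per_connection = 4L,
                   n_patients = 14L, volume_pct_range = c(0.3, 3),
                   n_go = 60L, n_nogo = 60L, n_channels = 16L,
                   srate_hz = 256, n_epoch_trials = 12L,
                   n_permutations = 200L)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}
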