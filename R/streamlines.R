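#' Streamline sets
#'
#' A `streamline_set` holds ordered voxel paths on a shared grid. Each path
#' is an n x 3 integer matrix of 1-based voxel indices whose consecutive rows
#' differ by at most one voxel per axis (26-connectivity), so that a path
#' visits every voxel it crosses.
#'
#' @param grid a [grid_spec()].
#' @param paths list of n x 3 integer matrices.
#' @param ids optional integer ids (default sequential).
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(grid, paths, ids = seq_along(paths)) {
  stopifnot(inherits(grid, "grid_spec"))
  dims <- grid$dims
  for (p in paths) {
    if (nrow(p) < 2L) stop("each streamline path needs >= 2 voxels")
    if (any(p < 1L) || any(p[, 1] > dims[1]) || any(p[, 2] > dims[2]) ||
        any(p[, 3] > dims[3]))
      stop("streamline path leaves the grid")
    step <- abs(diff(p))
    if (any(step > 1L))
      stop("consecutive path voxels must be 26-neighbors")
  }
  structure(list(grid = grid, paths = paths, ids = as.integer(ids)),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  len <- vapply(x$paths, nrow, integer(1))
  cat(sprintf("<streamline_set> %d streamlines on %s grid, path length %d-%d voxels\n",
              length(x$paths), paste(x$grid$dims, collapse = "x"),
              if (length(len)) min(len) else 0L,
              if (length(len)) max(len) else 0L))
  invisible(x)
}

# discretize a dense polyline (m x 3 real, voxel coordinates) into a
# 26-connected voxel path: round, drop repeats, bridge residual gaps
.discretize_path <- function(pts) {
  vox <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(vox)) != 0) > 0)
  vox <- vox[keep, , drop = FALSE]
  # bridge steps larger than one voxel by linear interpolation
  out <- list(vox[1, , drop = FALSE])
  for (i in seq_len(nrow(vox) - 1L)) {
    a <- vox[i, ]; b <- vox[i + 1L, ]
    cheb <- max(abs(b - a))
    if (cheb <= 1L) {
      out[[length(out) + 1L]] <- matrix(b, ncol = 3)
    } else {
      t <- seq_len(cheb) / cheb
      seg <- round(outer(1 - t, a) + outer(t, b))
      keep2 <- c(rowSums(abs(diff(rbind(a, seg))) != 0) > 0)
      out[[length(out) + 1L]] <- seg[keep2, , drop = FALSE]
    }
  }
  path <- do.call(rbind, out)
  storage.mode(path) <- "integer"
  path
}

#' Generate a synthetic streamline tractography atlas
#'
#' Creates bundles of streamlines between pairs of parcels of a phantom
#' atlas, standing in for a deterministic tractography template. Each
#' streamline starts at a voxel inside the first parcel and ends at a voxel
#' inside the second; the path is a smooth jittered curve (spline through
#' randomly perturbed control points) discretized onto the voxel grid.
#' Endpoint membership is verified and the curve regenerated (bounded
#' retries) if jitter pushed an endpoint out of its parcel.
#'
#' @param atlas a [make_phantom_brain()] result.
#' @param connection_spec data.frame with columns `parcel_a`, `parcel_b`,
#'   `n_streamlines` (one row per ROI-ROI bundle), or a list of
#'   `list(pair = c(a, b), n = k)`.
#' @param jitter_sd_mm spatial jitter SD of control points, in mm;
#'   0 gives identical discretized straight lines within a bundle when the
#'   endpoints coincide.
#' @param seed integer seed.
#' @param max_retries retries per streamline before failing.
#' @return A [streamline_set()]; each path carries attributes `conn`
#'   (the generating parcel pair) kept for bookkeeping only — analyses
#'   re-derive connections from endpoints via [assign_endpoints()].
#' @export
make_streamline_atlas <- function(atlas, connection_spec, jitter_sd_mm = 2,
                                  seed = 1, max_retries = 25L) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  spec <- .normalize_connection_spec(connection_spec)
  parc <- atlas$parcellation
  ids_avail <- atlas$parcel_table$id
  bad <- setdiff(unique(c(spec$parcel_a, spec$parcel_b)), ids_avail)
  if (length(bad))
    stop("connection_spec references unknown parcels: ",
         paste(bad, collapse = ", "))
  if (any(spec$parcel_a == spec$parcel_b))
    stop("connection_spec pairs must reference distinct parcels")
  if (any(spec$n_streamlines < 1L))
    stop("n_streamlines must be >= 1")

  dims <- atlas$grid$dims
  vox_by_parcel <- lapply(ids_avail, function(id)
    which(parc == id, arr.ind = TRUE))
  names(vox_by_parcel) <- as.character(ids_avail)
  jitter_vox <- jitter_sd_mm / atlas$grid$voxel_size_mm

  paths <- list()
  conns <- list()
  withr_seed(seed, {
    for (r in seq_len(nrow(spec))) {
      a <- spec$parcel_a[r]; b <- spec$parcel_b[r]
      va <- vox_by_parcel[[as.character(a)]]
      vb <- vox_by_parcel[[as.character(b)]]
      for (s in seq_len(spec$n_streamlines[r])) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          p0 <- va[sample.int(nrow(va), 1L), ]
          p1 <- vb[sample.int(nrow(vb), 1L), ]
          pts <- .jittered_curve(p0, p1, jitter_vox, dims)
          path <- .discretize_path(pts)
          la <- parc[matrix(path[1, ], ncol = 3)]
          lb <- parc[matrix(path[nrow(path), ], ncol = 3)]
          if (nrow(path) >= 2L && la == a && lb == b) { ok <- TRUE; break }
        }
        if (!ok)
          stop("could not generate a streamline for parcel pair (", a,
               ", ", b, ") after ", max_retries, " retries")
        attr(path, "conn") <- c(a, b)
        paths[[length(paths) + 1L]] <- path
      }
    }
  })
  streamline_set(atlas$grid, paths)
}

.normalize_connection_spec <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(all(c("parcel_a", "parcel_b", "n_streamlines") %in% names(spec)))
    return(data.frame(parcel_a = as.integer(spec$parcel_a),
                      parcel_b = as.integer(spec$parcel_b),
                      n_streamlines = as.integer(spec$n_streamlines)))
  }
  do.call(rbind, lapply(spec, function(e)
    data.frame(parcel_a = as.integer(e$pair[1]),
               parcel_b = as.integer(e$pair[2]),
               n_streamlines = as.integer(e$n))))
}

# smooth curve from p0 to p1: spline through jittered interior control
# points, densely sampled; endpoints pinned
.jittered_curve <- function(p0, p1, jitter_vox, dims) {
  n_ctrl <- 3L
  tt <- seq(0, 1, length.out = n_ctrl + 2L)
  ctrl <- outer(1 - tt, p0) + outer(tt, p1)
  if (jitter_vox > 0) {
    jit <- matrix(stats::rnorm(3L * n_ctrl, sd = jitter_vox), ncol = 3)
    ctrl[2:(n_ctrl + 1L), ] <- ctrl[2:(n_ctrl + 1L), ] + jit
  }
  ctrl <- pmin(pmax(ctrl, 1), matrix(dims, nrow(ctrl), 3, byrow = TRUE))
  len <- sqrt(sum((p1 - p0)^2))
  m <- max(16L, 4L * ceiling(len))
  ts <- seq(0, 1, length.out = m)
  dense <- vapply(1:3, function(d)
    stats::spline(tt, ctrl[, d], xout = ts, method = "natural")$y,
    numeric(m))
  dense <- pmin(pmax(dense, 1), matrix(dims, m, 3, byrow = TRUE))
  dense[1, ] <- p0
  dense[m, ] <- p1
  dense
}

#' Write / read streamlines as JSON-lines
#'
#' One streamline per line: a JSON object with the streamline `id`, the
#' generating parcel pair `conn` (if known), and `path`, an array of
#' 1-based voxel index triples. The first line is a header object with the
#' grid definition.
#'
#' @param x a [streamline_set()].
#' @param path output file (`.jsonl`).
#' @export
write_streamlines_jsonl <- function(x, path) {
  stopifnot(inherits(x, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(format = "voxel-path-jsonl", version = 1L,
                               dims = x$grid$dims,
                               voxel_size_mm = x$grid$voxel_size_mm,
                               origin = x$grid$origin),
                          auto_unbox = TRUE)
  writeLines(hdr, con)
  for (i in seq_along(x$paths)) {
    p <- x$paths[[i]]
    rec <- list(id = x$ids[i], path = unclass(unname(p)))
    cn <- attr(p, "conn")
    if (!is.null(cn)) rec$conn <- as.integer(cn)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_streamlines_jsonl
#' @export
read_streamlines_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty streamline file: ", path)
  hdr <- jsonlite::fromJSON(lines[1])
  grid <- grid_spec(hdr$dims, hdr$voxel_size_mm, hdr$origin)
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  paths <- lapply(recs, function(r) {
    p <- matrix(as.integer(r$path), ncol = 3)
    if (!is.null(r$conn)) attr(p, "conn") <- as.integer(r$conn)
    p
  })
  ids <- vapply(recs, function(r) as.integer(r$id), integer(1))
  streamline_set(grid, paths, ids)
}
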