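#' Assign streamlines to ROI-ROI connections by the "End" criterion
#'
#' A streamline belongs to connection (A, B) if and only if its first path
#' voxel carries parcel label A and its last carries label B (in either
#' order), with A != B and both labels nonzero. Streamlines ending in
#' background or looping back into a single parcel are left unassigned.
#' Connections are keyed with `parcel_a < parcel_b`.
#'
#' @param streamlines a [streamline_set()].
#' @param parcellation a [label_volume()] parcellation on the same grid.
#' @return An object of class `connectome_index`: list with
#'   `connections` (data.frame: `connection` key `"a-b"`, `parcel_a`,
#'   `parcel_b`, `count`), `members` (list of streamline-position vectors
#'   per connection) and `unassigned` (streamline positions).
#' @export
assign_endpoints <- function(streamlines, parcellation) {
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(parcellation, "label_volume"))
  if (!same_grid(streamlines$grid, vol_grid(parcellation)))
    stop("streamlines and parcellation are on different grids")
  ends <- t(vapply(streamlines$paths, function(p) {
    c(parcellation[matrix(p[1L, ], ncol = 3)],
      parcellation[matrix(p[nrow(p), ], ncol = 3)])
  }, integer(2)))
  a <- pmin(ends[, 1], ends[, 2])
  b <- pmax(ends[, 1], ends[, 2])
  assigned <- a > 0L & ends[, 1] != ends[, 2]
  key <- ifelse(assigned, paste0(a, "-", b), NA_character_)
  keys <- sort(unique(key[assigned]))
  members <- lapply(keys, function(k) which(!is.na(key) & key == k))
  names(members) <- keys
  ab <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  connections <- data.frame(
    connection = keys,
    parcel_a = if (length(keys)) as.integer(ab[, 1]) else integer(0),
    parcel_b = if (length(keys)) as.integer(ab[, 2]) else integer(0),
    count = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(connections = connections, members = members,
                 unassigned = which(!assigned)),
            class = "connectome_index")
}

#' @export
print.connectome_index <- function(x, ...) {
  cat(sprintf("<connectome_index> %d connections (%d streamlines assigned, %d unassigned)\n",
              nrow(x$connections), sum(x$connections$count),
              length(x$unassigned)))
  invisible(x)
}

# flat lookup tables reused across lesions: voxel linear index of every path
# voxel, the streamline it belongs to, and each streamline's connection slot
.streamline_cache <- function(streamlines, index) {
  dims <- streamlines$grid$dims
  lens <- vapply(streamlines$paths, nrow, integer(1))
  allvox <- do.call(rbind, streamlines$paths)
  lin <- voxel_linear_index(allvox, dims)
  sl_of_vox <- rep.int(seq_along(streamlines$paths), lens)
  conn_of_sl <- rep(NA_integer_, length(streamlines$paths))
  if (!is.null(index))
    for (ci in seq_along(index$members))
      conn_of_sl[index$members[[ci]]] <- ci
  list(lin = lin, sl_of_vox = sl_of_vox, conn_of_sl = conn_of_sl,
       n_vox = prod(dims))
}

.check_lesion <- function(lesion, grid) {
  stopifnot(inherits(lesion, "label_volume"))
  if (!same_grid(vol_grid(lesion), grid))
    stop("lesion and streamline atlas are on different grids")
  if (!is_binary_volume(lesion))
    stop("lesion mask must be binary (0/1)")
}

# streamline positions hit by a binary lesion, given a cache
.hit_streamlines <- function(lesion, cache) {
  les <- as.vector(lesion) != 0L
  unique(cache$sl_of_vox[les[cache$lin]])
}

#' Disconnection severity of one lesion
#'
#' A streamline counts as disconnected when any voxel of its path falls
#' inside the lesion. The severity of connection (A, B) is the percentage of
#' its streamlines disconnected — the modeled percentage reduction of
#' streamlines composing the ROI-ROI connection.
#'
#' @param lesion binary [label_volume()] on the atlas grid.
#' @param streamlines a [streamline_set()].
#' @param index a [assign_endpoints()] result for `streamlines`.
#' @return Named numeric vector of severities in `[0, 100]`, one per
#'   connection, in `index` order.
#' @export
lesion_disconnection <- function(lesion, streamlines, index) {
  .check_lesion(lesion, streamlines$grid)
  cache <- .streamline_cache(streamlines, index)
  .severity_row(lesion, cache, nrow(index$connections),
                index$connections$connection, index$connections$count)
}

.severity_row <- function(lesion, cache, n_conn, conn_names, conn_counts) {
  hit <- .hit_streamlines(lesion, cache)
  ci <- cache$conn_of_sl[hit]
  ci <- ci[!is.na(ci)]
  ndis <- tabulate(ci, nbins = n_conn)
  sev <- 100 * ndis / conn_counts
  names(sev) <- conn_names
  sev
}

#' Patients x connections disconnection matrix
#'
#' @param lesions list of binary [label_volume()]s (named by patient id).
#' @param streamlines a [streamline_set()].
#' @param index a [assign_endpoints()] result.
#' @return A numeric matrix (class `disconnection_matrix`) of severities in
#'   percent, rows = patients, columns = connections keyed `"a-b"`.
#' @export
disconnection_matrix <- function(lesions, streamlines, index) {
  stopifnot(length(lesions) >= 1)
  cache <- .streamline_cache(streamlines, index)
  cn <- index$connections$connection
  cc <- index$connections$count
  rows <- lapply(lesions, function(l) {
    .check_lesion(l, streamlines$grid)
    .severity_row(l, cache, length(cn), cn, cc)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if (!is.null(names(lesions))) names(lesions)
  else sprintf("P%03d", seq_along(lesions))
  class(m) <- c("disconnection_matrix", "matrix", "array")
  m
}

#' @export
print.disconnection_matrix <- function(x, ...) {
  cat(sprintf("<disconnection_matrix> %d patients x %d connections; %.1f%% nonzero entries\n",
              nrow(x), ncol(x), 100 * mean(x > 0)))
  invisible(x)
}

#' Voxel-wise disconnection map of one lesion
#'
#' Marks every voxel lying on the full path of any disconnected streamline
#' (streamlines from the whole atlas, assigned to a connection or not), so
#' the map extends beyond the lesion along each interrupted pathway.
#'
#' @inheritParams lesion_disconnection
#' @return Binary [label_volume()].
#' @export
voxel_disconnection_map <- function(lesion, streamlines) {
  .check_lesion(lesion, streamlines$grid)
  cache <- .streamline_cache(streamlines, NULL)
  hit <- .hit_streamlines(lesion, cache)
  out <- integer(cache$n_vox)
  if (length(hit))
    out[cache$lin[cache$sl_of_vox %in% hit]] <- 1L
  label_volume(array(out, streamlines$grid$dims), streamlines$grid)
}

#' Cohort coverage map of voxel-wise disconnections
#'
#' Counts, per voxel, the number of patients whose lesion disconnects at
#' least one streamline passing through that voxel, and thresholds the count
#' into the binary analysis mask of voxels with adequate cohort coverage.
#'
#' @param lesions list of binary [label_volume()]s.
#' @param streamlines a [streamline_set()].
#' @param min_patients coverage threshold (default 7 patients).
#' @return List with `counts` (integer [label_volume()]) and `mask`
#'   (binary [label_volume()], `counts >= min_patients`).
#' @export
coverage_map <- function(lesions, streamlines, min_patients = 7L) {
  stopifnot(min_patients >= 1)
  grid <- streamlines$grid
  cache <- .streamline_cache(streamlines, NULL)
  counts <- integer(cache$n_vox)
  for (l in lesions) {
    .check_lesion(l, grid)
    hit <- .hit_streamlines(l, cache)
    if (length(hit)) {
      vox <- unique(cache$lin[cache$sl_of_vox %in% hit])
      counts[vox] <- counts[vox] + 1L
    }
  }
  list(counts = label_volume(array(counts, grid$dims), grid),
       mask = label_volume(array(as.integer(counts >= min_patients),
                                 grid$dims), grid))
}

#' Keep connections damaged in enough patients
#'
#' Retains the columns of a disconnection matrix for which at least
#' `min_patients` patients have severity strictly above `damage_threshold`,
#' the minimum-lesion-coverage filter applied before mass-univariate
#' testing. Column order is preserved.
#'
#' @param matrix a [disconnection_matrix()].
#' @param min_patients minimum number of damaged patients (default 7).
#' @param damage_threshold severity (in percent) strictly above which a
#'   patient counts as damaged (default 0: any disconnected streamline).
#' @return The filtered matrix (possibly with zero columns).
#' @export
filter_connections <- function(matrix, min_patients = 7L,
                               damage_threshold = 0) {
  stopifnot(min_patients >= 1)
  n_damaged <- colSums(matrix > damage_threshold)
  keep <- which(n_damaged >= min_patients)
  out <- matrix[, keep, drop = FALSE]
  class(out) <- class(matrix)
  out
}
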