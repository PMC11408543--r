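#' One-tailed edge statistic: does disconnection reduce the symptom?
#'
#' Fits the simple linear model `symptom = a + b * severity + e` and
#' returns the t statistic of the slope, sign-flipped so that positive
#' values mean the symptom *decreases* as disconnection severity grows —
#' the direction in which lesions are assumed to act. Equivalent to
#' `t = -r * sqrt((n - 2) / (1 - r^2))` with `r` the Pearson correlation.
#' Perfect linear fits (residual variance numerically zero) are capped at a
#' large finite value and flagged.
#'
#' @param severity per-patient severity vector (percent), not constant.
#' @param symptom per-patient symptom values, same length (n >= 4).
#' @return Scalar t with attribute `perfect_fit` (logical).
#' @export
edge_statistic <- function(severity, symptom) {
  n <- length(severity)
  stopifnot(length(symptom) == n, n >= 4)
  if (stats::sd(severity) == 0)
    stop("severity is constant; the edge statistic is undefined")
  t <- .edge_t(matrix(severity, ncol = 1), symptom)
  out <- as.vector(t)
  attr(out, "perfect_fit") <- attr(t, "perfect_fit")[1]
  out
}

# vectorized sign-flipped slope t over the columns of X (n x p)
# (constant symptom across patients gives r = 0/0 -> statistic 0: no
# evidence in either direction)
.edge_t <- function(X, y, cap = 1e12) {
  n <- length(y)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(Xc^2)
  syy <- sum(yc^2)
  r <- if (syy == 0) rep(0, ncol(X)) else
    as.vector(crossprod(Xc, yc)) / sqrt(sxx * syy)
  r <- pmin(1, pmax(-1, r))
  one_minus_r2 <- pmax(1 - r^2, 0)
  perfect <- one_minus_r2 < 1e-12 & abs(r) > 0
  t <- -r * sqrt((n - 2) / pmax(one_minus_r2, 1e-300))
  t <- pmin(pmax(t, -cap), cap)
  attr(t, "perfect_fit") <- perfect
  t
}

#' Mass-univariate edge statistics
#'
#' Applies [edge_statistic()] independently to every connection (column) of
#' a disconnection matrix, after aligning patients between matrix and
#' symptom by id.
#'
#' @param matrix a (filtered) [disconnection_matrix()].
#' @param symptom a `symptom_vector` (see [symptom_vector()]) or a named
#'   numeric vector aligned with the matrix rows.
#' @return Named numeric vector of statistics with attribute
#'   `perfect_fit`; constant-severity columns yield `NA` (they are excluded
#'   from permutation inference by [clsm()]).
#' @export
mass_univariate <- function(matrix, symptom) {
  y <- .align_symptom(matrix, symptom)
  t <- .edge_t(unclass(matrix), y)
  const <- apply(matrix, 2, function(col) stats::sd(col) == 0)
  t[const] <- NA_real_
  stats::setNames(as.vector(t), colnames(matrix)) -> out
  attr(out, "perfect_fit") <- attr(t, "perfect_fit")
  out
}

#' Per-patient symptom vector
#'
#' @param values numeric symptom values (no missing entries; drop missing
#'   patients upstream).
#' @param patient_ids ids aligning with a disconnection matrix.
#' @param name symptom name.
#' @return Object of class `symptom_vector`.
#' @export
symptom_vector <- function(values, patient_ids = names(values),
                           name = "symptom") {
  if (anyNA(values)) stop("symptom contains missing values; drop those ",
                          "patients before analysis")
  structure(list(values = as.numeric(values),
                 patient_ids = as.character(patient_ids), name = name),
            class = "symptom_vector")
}

.align_symptom <- function(matrix, symptom) {
  if (inherits(symptom, "symptom_vector")) {
    ids <- rownames(matrix)
    pos <- match(ids, symptom$patient_ids)
    if (anyNA(pos))
      stop("symptom is missing patients present in the matrix: ",
           paste(ids[is.na(pos)], collapse = ", "))
    symptom$values[pos]
  } else {
    if (!is.null(names(symptom)) && !is.null(rownames(matrix))) {
      if (!all(rownames(matrix) %in% names(symptom)))
        stop("symptom names do not cover the matrix patients")
      as.numeric(symptom[rownames(matrix)])
    } else {
      stopifnot(length(symptom) == nrow(matrix))
      as.numeric(symptom)
    }
  }
}

#' Connectome-based lesion-symptom mapping with max-statistic permutation
#'
#' The central fitting function: regresses one symptom on each connection's
#' disconnection severity (one-tailed, worse symptom with more
#' disconnection), and controls the family-wise error rate over all
#' connections with the maximal-statistic permutation procedure. For each
#' of `n_permutations` random reassignments of the symptom values across
#' patients (severities fixed — the exchangeability null), all edge
#' statistics are recomputed and their maximum recorded; the corrected
#' p-value of an edge is `(1 + #permutation maxima >= t_edge) /
#' (n_permutations + 1)` (add-one convention, so p >= 1/(B+1) and the
#' estimator is valid), and the critical value is the empirical `1 - alpha`
#' quantile of the permutation maxima.
#'
#' Constant-severity columns are excluded before permutation (the maximum
#' runs over testable edges only) and reported in `excluded`.
#'
#' @param matrix a [disconnection_matrix()], already filtered with
#'   [filter_connections()].
#' @param symptom a [symptom_vector()] or named numeric vector.
#' @param n_permutations number of permutations (>= 100; default 5000).
#' @param alpha corrected significance level in (0, 0.5] (default 0.05).
#' @param seed integer seed for the permutation stream (recorded).
#' @return Object of class `clsm`: list with `connection` ids,
#'   `statistic`, `p_fwer`, `significant` (`p_fwer <= alpha`),
#'   `critical_value`, `alpha`, `n_permutations`, `n_patients`,
#'   `max_null` (the permutation maxima), `excluded`, `symptom_name`,
#'   `seed`.
#' @export
#' @examples
#' sev <- matrix(runif(80, 0, 60), 20, 4,
#'               dimnames = list(sprintf("P%02d", 1:20), paste0("e", 1:4)))
#' y <- rnorm(20)
#' fit <- clsm(sev, y, n_permutations = 200, seed = 1)
#' summary(fit)
clsm <- function(matrix, symptom, n_permutations = 5000L, alpha = 0.05,
                 seed = 1L) {
  stopifnot(n_permutations >= 100, alpha > 0, alpha <= 0.5)
  sname <- if (inherits(symptom, "symptom_vector")) symptom$name else
    deparse(substitute(symptom))[1]
  y <- .align_symptom(matrix, symptom)
  n <- length(y)
  X <- unclass(matrix)
  const <- if (ncol(X)) apply(X, 2, function(col) stats::sd(col) == 0)
  else logical(0)
  excluded <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0L) {
    warning("no testable connections (all constant or none survive the ",
            "damage filter); returning an empty result")
    return(structure(list(connection = character(0),
                          statistic = numeric(0), p_fwer = numeric(0),
                          significant = logical(0),
                          critical_value = NA_real_, alpha = alpha,
                          n_permutations = as.integer(n_permutations),
                          n_patients = n, max_null = numeric(0),
                          excluded = excluded, symptom_name = sname,
                          seed = as.integer(seed)), class = "clsm"))
  }

  t_obs <- .edge_t(X, y)
  perfect <- attr(t_obs, "perfect_fit")
  B <- as.integer(n_permutations)

  # precompute centered design once; each permutation is one mat-vec
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  max_null <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      yp <- y[sample.int(n)]
      yc <- yp - mean(yp)
      syy <- sum(yc^2)
      if (syy == 0) return(0)
      r <- as.vector(crossprod(Xc, yc)) / sqrt(sxx * syy)
      r <- pmin(1, pmax(-1, r))
      max(-r * sqrt((n - 2) / pmax(1 - r^2, 1e-300)))
    }, numeric(1))
  })
  p_fwer <- (1 + vapply(as.vector(t_obs), function(t)
    sum(max_null >= t), numeric(1))) / (B + 1)
  crit <- sort(max_null)[ceiling((1 - alpha) * B)]

  structure(list(connection = colnames(X),
                 statistic = stats::setNames(as.vector(t_obs), colnames(X)),
                 p_fwer = stats::setNames(p_fwer, colnames(X)),
                 significant = stats::setNames(p_fwer <= alpha, colnames(X)),
                 perfect_fit = stats::setNames(perfect, colnames(X)),
                 critical_value = crit, alpha = alpha,
                 n_permutations = B, n_patients = n,
                 max_null = max_null, excluded = excluded,
                 symptom_name = sname, seed = as.integer(seed)),
            class = "clsm")
}

#' @export
print.clsm <- function(x, ...) {
  cat(sprintf("Connectome-based lesion-symptom mapping: %s\n",
              x$symptom_name))
  cat(sprintf("  %d connections tested on %d patients; %d permutations\n",
              length(x$connection), x$n_patients, x$n_permutations))
  cat(sprintf("  FWER-corrected alpha = %g (critical t = %.3f): %d significant edge(s)\n",
              x$alpha, x$critical_value, sum(x$significant)))
  if (length(x$excluded))
    cat(sprintf("  %d constant-severity connection(s) excluded\n",
                length(x$excluded)))
  invisible(x)
}

#' @export
summary.clsm <- function(object, alpha = object$alpha, ...) {
  d <- data.frame(connection = object$connection,
                  statistic = unname(object$statistic),
                  p_fwer = unname(object$p_fwer),
                  significant = unname(object$p_fwer <= alpha),
                  stringsAsFactors = FALSE)
  d <- d[order(d$statistic, decreasing = TRUE), ]
  rownames(d) <- NULL
  structure(list(table = d, alpha = alpha,
                 critical_value = object$critical_value,
                 n_permutations = object$n_permutations,
                 symptom_name = object$symptom_name), class = "summary.clsm")
}

#' @export
print.summary.clsm <- function(x, n = 10L, ...) {
  cat(sprintf("CLSM summary for %s (alpha = %g, B = %d)\n",
              x$symptom_name, x$alpha, x$n_permutations))
  print(utils::head(x$table, n))
  if (nrow(x$table) > n) cat("...", nrow(x$table) - n, "more edges\n")
  invisible(x)
}

#' @export
coef.clsm <- function(object, ...) object$statistic

#' @export
plot.clsm <- function(x, ...) {
  if (!length(x$max_null)) {
    warning("empty result; nothing to plot")
    return(invisible(x))
  }
  graphics::hist(x$max_null, breaks = 40, col = "grey85", border = "white",
                 main = paste("Permutation null of the maximal statistic:",
                              x$symptom_name),
                 xlab = "max t over connections",
                 xlim = range(c(x$max_null, x$statistic)))
  graphics::abline(v = x$critical_value, col = "red3", lwd = 2)
  graphics::rug(x$statistic, col = "blue3")
  sig <- x$statistic[x$significant]
  if (length(sig))
    graphics::points(sig, rep(0, length(sig)), pch = 17, col = "blue3")
  invisible(x)
}

#' Report significant edges with anatomical labels
#'
#' Thresholds a [clsm()] result at a chosen level (e.g. the 0.05 inference
#' level or a stricter 0.01 display level) and joins parcel names and
#' hemispheres, sorted by statistic descending.
#'
#' @param result a [clsm()] object.
#' @param index the [assign_endpoints()] index the matrix came from.
#' @param parcel_table data.frame with `id`, `name`, `hemisphere`.
#' @param alpha reporting threshold (default the result's alpha).
#' @return data.frame: `connection`, `parcel_a`, `parcel_b`, `name_a`,
#'   `name_b`, `hemisphere_a`, `hemisphere_b`, `statistic`, `p_fwer`.
#'   Zero rows when nothing is significant.
#' @export
significant_edges <- function(result, index, parcel_table,
                              alpha = result$alpha) {
  keep <- which(result$p_fwer <= alpha)
  conn <- result$connection[keep]
  ab <- if (length(conn))
    do.call(rbind, strsplit(conn, "-", fixed = TRUE)) else
      matrix(integer(0), 0, 2)
  a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
  look <- function(id, col) parcel_table[[col]][match(id, parcel_table$id)]
  out <- data.frame(connection = conn, parcel_a = a, parcel_b = b,
                    name_a = look(a, "name"), name_b = look(b, "name"),
                    hemisphere_a = look(a, "hemisphere"),
                    hemisphere_b = look(b, "hemisphere"),
                    statistic = unname(result$statistic[keep]),
                    p_fwer = unname(result$p_fwer[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$statistic, decreasing = TRUE), ]
  rownames(out) <- NULL
  out
}
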