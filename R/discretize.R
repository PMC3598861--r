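#' Binarize continuous activity series into a two-state raster
#'
#' Each unit's series is thresholded at one half of its maximum value
#' (`mode = "half-max"`, the default) or at its mean (`mode = "mean"`); an
#' entry is 1 iff the value strictly exceeds the threshold, so ties at the
#' threshold map to 0. Units whose binarized row is constant are flagged
#' (`constant-0`, `constant-1`) but kept: downstream model fitting decides
#' whether to exclude such degenerate units.
#'
#' @param x A numeric matrix (units x time, non-negative), a numeric vector
#'   (a single unit), a `dmn_trajectory` (its amplitude series is used) or a
#'   `dmn_activity`.
#' @param mode Threshold rule, `"half-max"` or `"mean"`.
#' @return An object of class `binary_raster`: list with `values` (0/1 matrix
#'   units x time) and `flags` (per-unit `"ok"`, `"constant-0"` or
#'   `"constant-1"`).
#' @export
#' @examples
#' binarize(rbind(a = c(4, 1, 3), b = c(0, 0, 0)))
binarize <- function(x, mode = c("half-max", "mean")) {
  mode <- match.arg(mode)
  if (inherits(x, "dmn_trajectory")) x <- amplitude_series(x)
  if (inherits(x, "dmn_activity")) x <- x$values
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x), ncol(x) >= 1)
  if (any(x < 0)) stop("activity values must be non-negative")
  thr <- if (mode == "half-max") apply(x, 1, max) / 2 else rowMeans(x)
  values <- (x > thr) + 0L
  storage.mode(values) <- "integer"
  rs <- rowSums(values)
  flags <- ifelse(rs == 0L, "constant-0",
                  ifelse(rs == ncol(values), "constant-1", "ok"))
  structure(list(values = values, flags = stats::setNames(flags, rownames(x))),
            class = "binary_raster")
}

as_raster <- function(x) {
  if (inherits(x, "binary_raster")) return(x)
  if (is.matrix(x) && all(x %in% c(0, 1))) {
    v <- x; storage.mode(v) <- "integer"
    rs <- rowSums(v)
    return(structure(list(values = v,
                          flags = ifelse(rs == 0L, "constant-0",
                                         ifelse(rs == ncol(v), "constant-1", "ok"))),
                     class = "binary_raster"))
  }
  stop("expected a binary_raster or a 0/1 matrix")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat("Binary raster: ", nrow(x$values), " units x ", ncol(x$values),
      " time steps\n", sep = "")
  ndeg <- sum(x$flags != "ok")
  if (ndeg) cat("  degenerate units: ", ndeg, " (",
                paste(which(x$flags != "ok"), collapse = ", "), ")\n", sep = "")
  cat("  mean activity: ", round(mean(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Clamped first and second moments of a binary raster
#'
#' Sample means `m_i`, second moments `<s_i s_j>` and covariances
#' `C_ij = <s_i s_j> - m_i m_j` over the post-burn-in columns. The 1/T
#' normalization is used, so the second-moment diagonal equals the means and
#' the covariance diagonal equals `m_i (1 - m_i)` exactly.
#'
#' @param raster A `binary_raster` or 0/1 matrix.
#' @param burn_in Number of initial columns to discard.
#' @return An object of class `moment_stats`: list with `means`,
#'   `second_moments`, `covariance`, `n_samples` and the raster's `flags`.
#' @export
compute_moments <- function(raster, burn_in = 0L) {
  raster <- as_raster(raster)
  X <- raster$values
  if (burn_in > 0) {
    if (ncol(X) - burn_in < 2) stop("too few post-burn-in samples to estimate moments")
    X <- X[, (burn_in + 1L):ncol(X), drop = FALSE]
  }
  if (ncol(X) < 2) stop("too few samples to estimate moments")
  Tn <- ncol(X)
  m <- rowMeans(X)
  S2 <- tcrossprod(X) / Tn
  C <- S2 - tcrossprod(m)
  # re-flag on the analyzed window
  rs <- rowSums(X)
  flags <- ifelse(rs == 0L, "constant-0", ifelse(rs == Tn, "constant-1", "ok"))
  structure(list(means = m, second_moments = S2, covariance = C,
                 n_samples = Tn, flags = stats::setNames(flags, rownames(X))),
            class = "moment_stats")
}

#' @export
print.moment_stats <- function(x, ...) {
  cat("Moment statistics over ", x$n_samples, " samples, ",
      length(x$means), " units\n", sep = "")
  cat("  mean activity range: [", round(min(x$means), 3), ", ",
      round(max(x$means), 3), "]\n", sep = "")
  offd <- x$covariance[upper.tri(x$covariance)]
  cat("  |covariance| (off-diagonal) max: ", round(max(abs(offd)), 4), "\n",
      sep = "")
  invisible(x)
}
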