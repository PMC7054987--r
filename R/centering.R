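#' Centering velocity from an exponential fit of distance versus time
#'
#' Fits the distance of an object centroid to the cell center as a function
#' of time with `d(t) = a * exp(b * t)` (nonlinear least squares; log-linear
#' fallback when all distances are positive and the nonlinear fit fails).
#' The centering velocity is `v = |a * b|`, the initial radial speed of the
#' exponential approach; the sign of `b` says whether the object approaches
#' (`b < 0`) or recedes.
#'
#' @param distance_series Data frame with columns `time_min` and
#'   `distance_um` (>= 5 points, distances >= 0), or a `track_set` whose
#'   object track is used together with its `oocyte_radius`.
#' @param oocyte_radius Cell radius (um) used for the off-centering series
#'   and the centered flag; optional for plain data frames.
#' @param threshold Off-centering threshold for the `centered` flag.
#' @return A `centering_result` list: `a` (um), `b` (1/min), `v` (um/min,
#'   `|a b|`), `b_sign`, `residual_norm`, `converged`, `time_to_center`
#'   (NA when never centered or no radius given), `centered`,
#'   `offcentering_series`.
#' @export
#' @examples
#' t <- seq(0, 500, by = 5)
#' fit <- centering_velocity(data.frame(time_min = t,
#'                                      distance_um = 10 * exp(-0.01 * t)))
#' c(fit$a, fit$b, fit$v)  # 10, -0.01, 0.1
centering_velocity <- function(distance_series, oocyte_radius = NULL,
                               threshold = 0.2) {
  if (inherits(distance_series, "track_set")) {
    ts <- distance_series
    obj <- split_tracks(ts, kind = "object")
    if (length(obj) == 0) stop("track_set has no object track", call. = FALSE)
    tr <- obj[[1]]
    oocyte_radius <- oocyte_radius %||% ts$oocyte_radius
    distance_series <- data.frame(time_min = tr$time_min,
                                  distance_um = track_distances(tr))
  }
  d <- distance_series
  stopifnot(all(c("time_min", "distance_um") %in% names(d)))
  if (nrow(d) < 5) stop("need at least 5 points to fit", call. = FALSE)
  if (any(d$distance_um < 0)) stop("distances must be >= 0", call. = FALSE)

  a0 <- max(d$distance_um[1], 1e-6)
  b0 <- if (all(d$distance_um > 0)) {
    unname(coef(lm(log(distance_um) ~ time_min, data = d))[2])
  } else {
    -1 / max(d$time_min)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(distance_um ~ a * exp(b * time_min), data = d,
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  converged <- !is.null(fit)
  if (converged) {
    a <- unname(coef(fit)[["a"]])
    b <- unname(coef(fit)[["b"]])
    resid_norm <- sqrt(sum(stats::residuals(fit)^2))
  } else if (all(d$distance_um > 0)) {
    # log-linear fallback
    lf <- lm(log(distance_um) ~ time_min, data = d)
    a <- exp(unname(coef(lf)[1]))
    b <- unname(coef(lf)[2])
    resid_norm <- sqrt(sum((d$distance_um - a * exp(b * d$time_min))^2))
    converged <- TRUE
  } else {
    a <- b <- resid_norm <- NA_real_
  }

  off <- ttc <- centered <- NULL
  if (!is.null(oocyte_radius) && is.finite(oocyte_radius)) {
    off <- d$distance_um / oocyte_radius
    centered <- off[length(off)] < threshold
    hit <- which(off < threshold)
    ttc <- if (length(hit) > 0) d$time_min[hit[1]] else NA_real_
  }
  structure(list(a = a, b = b,
                 v = if (is.na(a)) NA_real_ else abs(a * b),
                 b_sign = sign(b), residual_norm = resid_norm,
                 converged = converged, time_to_center = ttc,
                 centered = centered, offcentering_series = off,
                 n_points = nrow(d)),
            class = "centering_result")
}

#' @export
print.centering_result <- function(x, ...) {
  cat("<centering_result>\n")
  if (x$converged) {
    cat(sprintf("  d(t) = %.4g * exp(%.4g t); v = |a b| = %.4g um/min (%s)\n",
                x$a, x$b, x$v,
                if (x$b_sign < 0) "approaching" else "receding"))
  } else {
    cat("  fit did not converge\n")
  }
  if (!is.null(x$centered)) {
    cat(sprintf("  centered at end: %s; first centered at t = %s min\n",
                x$centered, format(x$time_to_center)))
  }
  invisible(x)
}

#' Size-sweep summary: centering velocity versus object size
#'
#' Fits the surface law `v = k * d^2` (least squares through the origin)
#' relating centering velocity to object diameter, as expected from the
#' Archimedes-like character of the active pressure gradient, and reports
#' the Spearman rank correlation of `v` with diameter.
#'
#' @param sweep Data frame with columns `diameter_um` and `v_um_min`
#'   (one row per run; >= 5 rows spanning >= 3 distinct diameters).
#' @return List: `k` (um^-1 min^-1), `rho`, `p_value`, `n`, `fitted`.
#' @export
size_sweep_summary <- function(sweep) {
  stopifnot(all(c("diameter_um", "v_um_min") %in% names(sweep)))
  sweep <- sweep[is.finite(sweep$diameter_um) & is.finite(sweep$v_um_min), ]
  if (nrow(sweep) < 5 || length(unique(sweep$diameter_um)) < 3) {
    stop("need >= 5 runs spanning >= 3 distinct diameters", call. = FALSE)
  }
  k <- unname(coef(lm(v_um_min ~ 0 + I(diameter_um^2), data = sweep))[1])
  ct <- suppressWarnings(cor.test(sweep$v_um_min, sweep$diameter_um,
                                  method = "spearman"))
  list(k = k, rho = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(sweep), fitted = k * sweep$diameter_um^2)
}
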