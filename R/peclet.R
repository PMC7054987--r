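#' Peclet number of an advected, diffusing object
#'
#' `P = L v / D`, the ratio of the diffusion time `tau_D = L^2 / D` across a
#' system of size `L` to the advection time `tau_A = L / v`. `P > 1` means
#' directed transport dominates diffusion. For centering objects, `v` is the
#' centering velocity from the exponential fit and `D` the diffusion
#' coefficient of a matched object in a gradient-free run.
#'
#' @param L System size (um), > 0 (here, the oocyte radius).
#' @param v Advection velocity (um/min), >= 0.
#' @param D Diffusion coefficient (um^2/min), > 0.
#' @return A `peclet_result` list: `L`, `v`, `D`, `P`, `tau_D` (min) and
#'   `tau_A` (min, `NA` when `v = 0`).
#' @export
#' @examples
#' peclet(10, 0.1, 1)$P  # 1
peclet <- function(L, v, D) {
  if (!(L > 0)) stop("L must be positive", call. = FALSE)
  if (!(D > 0)) stop("D must be positive", call. = FALSE)
  if (v < 0) stop("v must be >= 0", call. = FALSE)
  structure(list(L = L, v = v, D = D,
                 P = L * v / D,
                 tau_D = L^2 / D,
                 tau_A = if (v > 0) L / v else NA_real_),
            class = "peclet_result")
}

#' @export
print.peclet_result <- function(x, ...) {
  cat(sprintf("<peclet> P = %.3g  (L = %g um, v = %g um/min, D = %g um2/min)\n",
              x$P, x$L, x$v, x$D))
  cat(sprintf("  tau_D = %.3g min, tau_A = %s min\n", x$tau_D, format(x$tau_A)))
  invisible(x)
}
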