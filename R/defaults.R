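#' Model constants and default parameter values
#'
#' All tunable defaults of the simulator live here, in one place. Units are
#' micrometres, minutes and piconewtons throughout, so that force divided by
#' a Stokes friction coefficient is a velocity in um/min.
#'
#' * `gamma`: cytoplasmic viscosity. 1 Pa.s (the value measured for the
#'   prophase oocyte cytoplasm by tweezers microrheology) equals
#'   1 pN.s/um^2 = 1/60 pN.min/um^2.
#' * `v0`: intrinsic vesicle speed. Not printed in the source material for
#'   the simulations; fixed by calibrating the simulated squared-velocity
#'   profile and emergent centering kinetics against the published summary
#'   dynamics (see the methods vignette).
#' * `c_r`, `c_c`: contact and confinement stiffnesses, set large enough
#'   that steady-state sphere overlaps stay below ~10% of a radius at the
#'   default propulsion forces.
#' * `tau0`, `tau_r`: minimal persistence time (0.001 min) and slope of the
#'   persistence gradient (0.25 per um): `tau(r) = tau0 (1 + tau_r r)`
#'   by default, giving tau from 0.001 min at the center to ~0.0098 min at
#'   the cortex and sub-micron persistence lengths at the calibrated speed.
#'
#' @format A named list.
#' @export
oocenter_defaults <- list(
  oocyte_radius  = 35,      # um ("sphere of 70-um diameter")
  n_vesicles     = 500L,
  vesicle_radius_mean  = 0.5,   # um (1-um diameter on average)
  vesicle_radius_sd    = 0.1,
  vesicle_radius_floor = 0.1,
  object_radius  = 12.5,    # um (25-um nucleus)
  v0     = 30,              # um/min, calibrated (see vignette)
  tau0   = 0.001,           # min
  tau_r  = 0.25,            # per um
  gradient_form = "multiplicative",
  gamma  = 1 / 60,          # pN.min/um^2  == 1 Pa.s
  c_r    = 100,             # pN
  c_c    = 200,             # pN
  confinement_exponent = 2,
  dt     = 0.001,           # min
  record_interval = 5,      # min
  redraw_model = "exponential"
)
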