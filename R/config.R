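#' Build a simulation configuration
#'
#' Collects every geometric, motility, force and integration parameter of the
#' agent-based model into a validated `simulation_config` object. Defaults
#' describe the prophase-I oocyte: a 70-um cell containing 500 actin-positive
#' vesicles of 1-um mean diameter and a 25-um passive object starting tangent
#' to the cortex.
#'
#' @param oocyte_radius Cell radius (um).
#' @param n_vesicles Number of self-propelled vesicles.
#' @param vesicle_radius_mean,vesicle_radius_sd Mean and sd of the truncated
#'   normal from which vesicle radii are drawn (um).
#' @param vesicle_radius_floor Lower truncation bound for vesicle radii (um).
#' @param object_radius Radius of the passive object (um); 0 simulates a
#'   vesicle-only cell with no object.
#' @param object_initial_distance Initial distance of the object center from
#'   the cell center (um). Default places the object tangent to the cortex.
#' @param v0 Intrinsic vesicle speed (um/min).
#' @param tau0 Minimal persistence time (min), the value of tau at the center.
#' @param tau_r Slope of the persistence gradient (per um in the default
#'   multiplicative form; min/um in the additive form).
#' @param gradient_form `"multiplicative"` (`tau0 * (1 + tau_r * r)`,
#'   default, the form that keeps persistence lengths small and the vesicle
#'   density uniform) or `"additive"` (`tau0 + tau_r * r`).
#' @param gradient_on If `FALSE`, every vesicle uses the constant persistence
#'   `tau_const` instead of the gradient.
#' @param tau_const Constant persistence time used when `gradient_on = FALSE`.
#'   Default: the volume-weighted spatial mean of the gradient-on tau, so the
#'   homogeneous control has the same average motility.
#' @param c_r Agent-agent repulsion coefficient (pN).
#' @param c_c Cortex confinement coefficient (pN).
#' @param confinement_exponent Exponent of the confinement force law.
#' @param gamma Cytoplasmic viscosity (pN.min/um^2; `1/60` is 1 Pa.s).
#' @param dt Integration step (min).
#' @param duration Simulated time (min).
#' @param record_interval Interval between recorded frames (min).
#' @param seed Integer seed; a configuration plus its seed fully determines
#'   the output trajectory set.
#' @param object_motile If `TRUE` the object also self-propels (off by
#'   default: the object is passive and only moves through collisions).
#' @param redraw_model `"exponential"` (redraw probability `1 - exp(-dt/tau)`
#'   per step, default: exact exponential heading decorrelation at any `dt`)
#'   or `"linear"` (`min(1, dt/tau)`).
#' @param auto_dt If `TRUE`, [run_simulation()] halves `dt` and reruns when
#'   any per-step displacement exceeds 10% of the smallest agent radius.
#'   Off by default: at the calibrated vesicle speed the free-flight step
#'   `v0 * dt` itself is of that order, which is harmless (headings persist
#'   across steps), so the check is useful mainly for slow-motility
#'   configurations with stiff contacts.
#'
#' @return A `simulation_config` list.
#' @seealso [prophase_config()], [meiosis_config()], [run_simulation()]
#' @export
#' @examples
#' cfg <- simulation_config(n_vesicles = 50, duration = 10, seed = 1)
#' cfg$object_initial_distance  # tangent to the cortex: 35 - 12.5
simulation_config <- function(oocyte_radius = oocenter_defaults$oocyte_radius,
                              n_vesicles = oocenter_defaults$n_vesicles,
                              vesicle_radius_mean = oocenter_defaults$vesicle_radius_mean,
                              vesicle_radius_sd = oocenter_defaults$vesicle_radius_sd,
                              vesicle_radius_floor = oocenter_defaults$vesicle_radius_floor,
                              object_radius = oocenter_defaults$object_radius,
                              object_initial_distance = NULL,
                              v0 = oocenter_defaults$v0,
                              tau0 = oocenter_defaults$tau0,
                              tau_r = oocenter_defaults$tau_r,
                              gradient_form = oocenter_defaults$gradient_form,
                              gradient_on = TRUE,
                              tau_const = NULL,
                              c_r = oocenter_defaults$c_r,
                              c_c = oocenter_defaults$c_c,
                              confinement_exponent = oocenter_defaults$confinement_exponent,
                              gamma = oocenter_defaults$gamma,
                              dt = oocenter_defaults$dt,
                              duration = 1000,
                              record_interval = oocenter_defaults$record_interval,
                              seed = 1L,
                              object_motile = FALSE,
                              redraw_model = oocenter_defaults$redraw_model,
                              auto_dt = FALSE) {
  gradient_form <- match.arg(gradient_form, c("additive", "multiplicative"))
  redraw_model <- match.arg(redraw_model, c("linear", "exponential"))
  if (is.null(object_initial_distance)) {
    object_initial_distance <- oocyte_radius - object_radius
  }
  cfg <- structure(list(
    oocyte_radius = oocyte_radius, n_vesicles = as.integer(n_vesicles),
    vesicle_radius_mean = vesicle_radius_mean,
    vesicle_radius_sd = vesicle_radius_sd,
    vesicle_radius_floor = vesicle_radius_floor,
    object_radius = object_radius,
    object_initial_distance = object_initial_distance,
    v0 = v0, tau0 = tau0, tau_r = tau_r,
    gradient_form = gradient_form, gradient_on = isTRUE(gradient_on),
    tau_const = tau_const,
    c_r = c_r, c_c = c_c, confinement_exponent = confinement_exponent,
    gamma = gamma, dt = dt, duration = duration,
    record_interval = record_interval, seed = as.integer(seed),
    object_motile = isTRUE(object_motile), redraw_model = redraw_model,
    auto_dt = isTRUE(auto_dt)
  ), class = "simulation_config")
  if (is.null(cfg$tau_const)) cfg$tau_const <- mean_persistence_time(cfg)
  validate_config(cfg)
  cfg
}

#' Spatial mean of the persistence time over the cell volume
#'
#' Volume-weighted average of `tau(r)` over a ball of the oocyte radius:
#' for the additive gradient `tau0 + tau_r * 3R/4`, for the multiplicative
#' one `tau0 * (1 + tau_r * 3R/4)`. Used as the homogeneous persistence of
#' the no-gradient control so that both conditions share the same mean
#' motility.
#'
#' @param config A `simulation_config`.
#' @return Mean persistence time (min).
#' @export
mean_persistence_time <- function(config) {
  r_mean <- 0.75 * config$oocyte_radius
  persistence_time(r_mean, config$tau0, config$tau_r, config$gradient_form)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  oocyte R = %g um | %d vesicles (r ~ %g +/- %g um) | object r = %g um\n",
              x$oocyte_radius, x$n_vesicles, x$vesicle_radius_mean,
              x$vesicle_radius_sd, x$object_radius))
  cat(sprintf("  v0 = %g um/min | tau = %s (tau0 %g, tau_r %g)%s\n",
              x$v0, x$gradient_form, x$tau0, x$tau_r,
              if (x$gradient_on) "" else sprintf(" [OFF, tau_const %.3g]", x$tau_const)))
  cat(sprintf("  dt = %g min | duration = %g min | record every %g min | seed %d\n",
              x$dt, x$duration, x$record_interval, x$seed))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  pos_fields <- c("oocyte_radius", "vesicle_radius_mean", "vesicle_radius_sd",
                  "vesicle_radius_floor", "tau0", "tau_r",
                  "gamma", "dt", "duration", "record_interval", "c_r", "c_c",
                  "confinement_exponent", "tau_const")
  for (f in pos_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop(sprintf("config field '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  if (cfg$n_vesicles < 0) stop("n_vesicles must be >= 0", call. = FALSE)
  if (cfg$v0 < 0) stop("v0 must be >= 0", call. = FALSE)
  if (cfg$object_radius < 0) {
    stop("object_radius must be >= 0 (0 = no object)", call. = FALSE)
  }
  if (cfg$object_radius >= cfg$oocyte_radius) {
    stop("object_radius must be smaller than oocyte_radius", call. = FALSE)
  }
  if (cfg$dt > cfg$record_interval) {
    stop("dt must not exceed record_interval", call. = FALSE)
  }
  if (cfg$object_radius > 0 &&
      (cfg$object_initial_distance < 0 ||
       cfg$object_initial_distance + cfg$object_radius >
         cfg$oocyte_radius + 1e-9)) {
    stop("object_initial_distance places the object outside the oocyte",
         call. = FALSE)
  }
  # infeasible packing: total agent volume above 60% of the cell volume
  ves_vol <- cfg$n_vesicles * (4 / 3) * pi * cfg$vesicle_radius_mean^3
  obj_vol <- (4 / 3) * pi * cfg$object_radius^3
  cell_vol <- (4 / 3) * pi * cfg$oocyte_radius^3
  if ((ves_vol + obj_vol) / cell_vol > 0.6) {
    stop("infeasible packing: agents occupy more than 60% of the cell volume",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Preset configurations for prophase I and meiosis I oocytes
#'
#' `prophase_config()` is the stage before nuclear envelope breakdown:
#' 500 vesicles of 1-um mean diameter. `meiosis_config()` reflects the
#' vesicle population after meiosis resumption: 200 vesicles of 1.4-um mean
#' diameter (fewer vesicles of roughly triple the volume). Both use the
#' 25-um passive object and the same motility parameters; additional
#' arguments override any field.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
prophase_config <- function(...) {
  simulation_config(...)
}

#' @rdname prophase_config
#' @export
meiosis_config <- function(...) {
  args <- list(...)
  base <- list(n_vesicles = 200L, vesicle_radius_mean = 0.7,
               vesicle_radius_sd = 0.14)
  base[names(args)] <- args
  do.call(simulation_config, base)
}

#' Read a simulation configuration from a file
#'
#' Accepts either a JSON document or a flat TOML-style `key = value` file.
#' Keys must be [simulation_config()] field names; unknown keys are an error.
#' A preset supplies defaults that explicit keys override.
#'
#' @param path Path to the configuration file, or `NULL` for preset-only.
#' @param preset `"prophase"`, `"meiosis"`, or `NULL`.
#' @return A `simulation_config`.
#' @export
load_config <- function(path = NULL, preset = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    txt <- readLines(path, warn = FALSE)
    joined <- paste(txt, collapse = "\n")
    if (grepl("^\\s*\\{", joined)) {
      vals <- jsonlite::fromJSON(joined, simplifyVector = TRUE)
    } else {
      vals <- parse_flat_toml(txt)
    }
  }
  allowed <- setdiff(names(formals(simulation_config)), "...")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  builder <- switch(preset %||% "none",
                    prophase = prophase_config,
                    meiosis = meiosis_config,
                    none = simulation_config,
                    stop("unknown preset: ", preset, call. = FALSE))
  do.call(builder, vals)
}

# minimal flat TOML: 'key = value' lines, '#' comments, strings or scalars
parse_flat_toml <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- m[2]
    raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num)) stop("cannot parse value for key ", key, call. = FALSE)
      num
    }
    vals[[key]] <- val
  }
  vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
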