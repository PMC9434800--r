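#' Solve the sensor--DNA--metal coupled equilibria at fixed free metal
#'
#' Five species -- apo sensor P, metalated sensor PM, free operator D,
#' apo-sensor-bound operator PD, metalated-sensor-bound operator PMD -- are
#' linked by three equilibria: `P + M <-> PM` (K_metal), `P + D <-> PD`
#' (K_DNA,apo) and `PM + D <-> PMD` (K_DNA,holo). The buffered metal pool is
#' treated as an infinite reservoir, so the free metal concentration is fixed
#' rather than depleted. Metal binding to DNA-bound sensor is implied by
#' thermodynamic cycle closure of the three constants. Eliminating PM, PD and
#' PMD with the mass balances for sensor and operator leaves a quadratic in P
#' whose positive root is evaluated in the numerically stable form.
#'
#' @param params a [sensor_params()] object.
#' @param free_metal buffered free metal concentration (M), `>= 0`.
#' @param abundance_mode how sensor abundance is blended between
#'   `abundance_low` and `abundance_high`: `"saturation"` (linear in the
#'   sensor's fractional metal saturation `[M]/([M] + K_metal)`), `"low"`,
#'   `"high"`, or `"mean"`. The default `"auto"` uses `"saturation"` for
#'   co-repressors and activators and `"mean"` for de-repressors: a
#'   metal-tracking abundance makes the derepression readout slightly
#'   non-monotone, which would defeat occupancy-to-concentration inversion.
#' @return An object of class `"species_state"`: list with molar
#'   concentrations `P`, `PM`, `D`, `PD`, `PMD`, the fixed `free_metal`, and
#'   the totals `P_total`, `D_total`.
#' @examples
#' s <- sensor_params("demo", "Ni2+", "co-repressor",
#'                    k_metal = 1e-12, k_dna_apo = 1e-6, k_dna_holo = 1e-9,
#'                    abundance_low = 100, abundance_high = 100, n_targets = 1)
#' solve_sensor_equilibrium(s, 1e-12)
#' @export
solve_sensor_equilibrium <- function(params, free_metal,
                                     abundance_mode = c("auto", "saturation",
                                                        "low", "high",
                                                        "mean")) {
  stopifnot(inherits(params, "sensor_params"))
  abundance_mode <- match.arg(abundance_mode)
  if (abundance_mode == "auto") {
    abundance_mode <- if (params$class == "de-repressor") "mean"
                      else "saturation"
  }
  if (!is.numeric(free_metal) || length(free_metal) != 1L ||
      !is.finite(free_metal) || free_metal < 0) {
    stop("free_metal must be a single finite concentration >= 0",
         call. = FALSE)
  }
  M <- free_metal
  sat <- M / (M + params$k_metal)
  n_sensor <- switch(abundance_mode,
    saturation = params$abundance_low +
      (params$abundance_high - params$abundance_low) * sat,
    low  = params$abundance_low,
    high = params$abundance_high,
    mean = (params$abundance_low + params$abundance_high) / 2
  )
  Ptot <- molecules_to_molar(n_sensor, params$cell_volume)
  Dtot <- molecules_to_molar(params$n_targets, params$cell_volume)

  # free-sensor partition: a = (P + PM)/P; operator-binding factor per unit P
  a <- 1 + M / params$k_metal
  b <- 1 / params$k_dna_apo + M / (params$k_metal * params$k_dna_holo)

  # sensor balance P*a + P*b*Dtot/(1 + b*P) = Ptot  =>
  # (a*b) P^2 + (a + b*(Dtot - Ptot)) P - Ptot = 0, positive root
  A <- a * b
  B <- a + b * (Dtot - Ptot)
  if (A == 0) {
    P <- Ptot / a
  } else {
    disc <- B^2 + 4 * A * Ptot
    if (!is.finite(disc) || disc < 0) {
      stop("equilibrium solver failed for sensor ", params$name,
           " at [M] = ", M, " M (degenerate discriminant)", call. = FALSE)
    }
    P <- 2 * Ptot / (B + sqrt(disc))
  }
  if (!is.finite(P) || P < 0) {
    stop("equilibrium solver returned an invalid root for sensor ",
         params$name, " at [M] = ", M, " M", call. = FALSE)
  }
  D <- Dtot / (1 + b * P)
  state <- list(
    P = P,
    PM = P * M / params$k_metal,
    D = D,
    PD = P * D / params$k_dna_apo,
    PMD = P * M * D / (params$k_metal * params$k_dna_holo),
    free_metal = M,
    P_total = Ptot,
    D_total = Dtot
  )
  class(state) <- "species_state"
  state
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state> at [M] =", format(x$free_metal, digits = 4), "M\n")
  for (sp in c("P", "PM", "D", "PD", "PMD")) {
    cat(sprintf("  %-4s = %.4g M\n", sp, x[[sp]]))
  }
  invisible(x)
}

#' Normalized sensor response from a solved equilibrium state
#'
#' Maps a [solve_sensor_equilibrium()] state to the transcriptional readout:
#' for co-repressors the fraction of operator bound by metalated sensor
#' (theta_D = PMD / D_total; repression rises with metal), for de-repressors
#' the fraction bound by apo sensor (theta_D = PD / D_total; repression falls
#' with metal), and for activators the metalated-sensor occupancy reported as
#' theta_DM (= PMD / D_total).
#'
#' @param state a `"species_state"` object.
#' @param class sensor class (see [sensor_params()]).
#' @return Occupancy in `[0, 1]`.
#' @export
response_occupancy <- function(state, class) {
  stopifnot(inherits(state, "species_state"))
  class <- match.arg(class, sensor_classes())
  theta <- switch(class,
    "co-repressor" = state$PMD / state$D_total,
    "de-repressor" = state$PD / state$D_total,
    "activator"    = state$PMD / state$D_total
  )
  min(max(theta, 0), 1)
}

#' Forward response map: buffered metal concentration to occupancy
#'
#' @param params a [sensor_params()] object.
#' @param free_metal buffered free metal concentration(s), M.
#' @param ... passed to [solve_sensor_equilibrium()].
#' @return Numeric vector of occupancies in `[0, 1]`.
#' @export
sensor_occupancy <- function(params, free_metal, ...) {
  vapply(free_metal, function(m) {
    response_occupancy(solve_sensor_equilibrium(params, m, ...), params$class)
  }, numeric(1))
}

#' Invert a sensor response: occupancy to buffered metal concentration
#'
#' Bisection on log10 concentration of the monotone forward map
#' [sensor_occupancy()], the step that converts a calibrated fractional
#' sensor response into an available metal concentration.
#'
#' @param params a [sensor_params()] object.
#' @param theta target occupancy, strictly inside (0, 1) and within the
#'   sensor's attainable range over the search bracket.
#' @param bracket concentration search interval (M); default `[1e-25, 1e-1]`.
#' @param tol relative tolerance on the returned concentration.
#' @param ... passed to [solve_sensor_equilibrium()].
#' @return Buffered metal concentration (M).
#' @export
invert_sensor_response <- function(params, theta, bracket = c(1e-25, 1e-1),
                                   tol = 1e-6, ...) {
  stopifnot(inherits(params, "sensor_params"))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0 || theta >= 1) {
    stop("theta must lie strictly inside (0, 1)", call. = FALSE)
  }
  lo <- sensor_occupancy(params, bracket[1], ...)
  hi <- sensor_occupancy(params, bracket[2], ...)
  attain <- sort(c(lo, hi))
  if (theta < attain[1] || theta > attain[2]) {
    stop(sprintf(
      "theta = %.4g outside attainable range [%.4g, %.4g] for sensor %s",
      theta, attain[1], attain[2], params$name), call. = FALSE)
  }
  f <- function(lg) sensor_occupancy(params, 10^lg, ...) - theta
  root <- stats::uniroot(f, lower = log10(bracket[1]),
                         upper = log10(bracket[2]),
                         tol = tol / log(10) / 4, maxiter = 200L)
  10^root$root
}

#' Build a calibrated sensor response curve
#'
#' Evaluates the forward response on a log-spaced concentration grid and
#' locates the dynamic-range boundaries (occupancies 0.01 and 0.99) and the
#' log-scale midpoint between them -- the concentration at which the sensor
#' is conventionally said to sit at the centre of its range.
#'
#' @param params a [sensor_params()] object.
#' @param n number of grid points.
#' @param range concentration range (M) of the grid; default `[1e-25, 1e-1]`.
#' @param boundaries occupancy anchors delimiting the dynamic range.
#' @param ... passed to [solve_sensor_equilibrium()].
#' @return A `"sensor_response_curve"`: data.frame with columns
#'   `concentration` and `theta`, attributes `sensor`, `readout` (`"theta_D"`
#'   or `"theta_DM"`), `boundaries` (named concentrations at the anchors),
#'   `midpoint`, and `warnings` (character; non-empty when the grid does not
#'   span the full dynamic range).
#' @export
sensor_response_curve <- function(params, n = 200L, range = c(1e-25, 1e-1),
                                  boundaries = c(0.01, 0.99), ...) {
  stopifnot(inherits(params, "sensor_params"), n >= 2, range[1] > 0,
            range[2] > range[1])
  grid <- 10^seq(log10(range[1]), log10(range[2]), length.out = n)
  theta <- sensor_occupancy(params, grid, ...)
  warnings <- character()
  bounds <- vapply(boundaries, function(th) {
    tryCatch(invert_sensor_response(params, th, bracket = range, ...),
             error = function(e) NA_real_)
  }, numeric(1))
  names(bounds) <- sprintf("theta_%.2f", boundaries)
  if (anyNA(bounds)) {
    warnings <- c(warnings, paste0(
      "grid [", range[1], ", ", range[2], "] M does not span the full ",
      "dynamic range of ", params$name))
  }
  midpoint <- if (anyNA(bounds)) NA_real_ else
    10^mean(log10(range(bounds)))
  curve <- data.frame(concentration = grid, theta = theta)
  structure(curve,
            class = c("sensor_response_curve", "data.frame"),
            sensor = params$name,
            readout = if (params$class == "activator") "theta_DM" else "theta_D",
            sensor_class = params$class,
            boundaries = bounds,
            midpoint = midpoint,
            warnings = warnings)
}

#' @export
print.sensor_response_curve <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat(sprintf("<sensor_response_curve> %s (%s, %d points)\n",
              attr(x, "sensor"), attr(x, "readout"), nrow(x)))
  if (!anyNA(b)) {
    cat(sprintf("  dynamic range: %.3g .. %.3g M (midpoint %.3g M)\n",
                min(b), max(b), attr(x, "midpoint")))
  }
  for (w in attr(x, "warnings")) cat("  warning:", w, "\n")
  invisible(x)
}

#' Plot a sensor response curve
#'
#' Occupancy against buffered metal concentration on a log axis, with the
#' dynamic-range boundaries and their log-scale midpoint marked.
#'
#' @param x a [sensor_response_curve()] object.
#' @param ... passed to [plot()].
#' @export
plot.sensor_response_curve <- function(x, ...) {
  plot(x$concentration, x$theta, type = "l", log = "x",
       xlab = "buffered metal (M)", ylab = attr(x, "readout"),
       main = attr(x, "sensor"), ...)
  b <- attr(x, "boundaries")
  if (!anyNA(b)) {
    graphics::points(b, as.numeric(sub("theta_", "", names(b))),
                     col = "red", pch = 19)
    graphics::abline(v = attr(x, "midpoint"), lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Write a response curve as TSV
#'
#' @param curve a [sensor_response_curve()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sensor_response_curve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
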