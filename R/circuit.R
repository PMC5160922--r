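#' Default rate constants for the transition-counter circuit
#'
#' Chosen to satisfy the qualitative design constraints of the counter:
#' sensor and activator dynamics equilibrate well within a 50-time-unit
#' nutrient pulse (time constants of a few units), counter "memory" molecules
#' degrade orders of magnitude more slowly than everything else (ratio
#' 5e-4, far below the 0.01 design ceiling), and the two branches are
#' symmetric so that spike increments are commensurate. Concentrations and
#' times are in arbitrary units.
#'
#' @return A named numeric vector of rate constants.
#' @export
counter_default_rates <- function() {
  c(
    k_sense = 0.5,      # catalytic sensor production per unit input sugar
    k_bind = 1,         # sensor + sugar -> activator (second order)
    k_unbind = 0.1,     # activator -> sensor (first order)
    k_count = 0.05,     # catalytic counter production per unit activator
    k_deg_sensor = 0.2, # sensor degradation
    k_deg_act = 0.2,    # activator degradation
    k_deg_counter = 1e-4 # counter degradation ("very slow": stable memory)
  )
}

counter_species <- function() {
  c("Glu", "Gal", "Glu_Sensor", "Gal_Sensor", "Glu_Activator",
    "Gal_Activator", "GluToGal_Counter", "GalToGlu_Counter")
}

#' Build the eight-component nutrient transition counter
#'
#' Constructs the mass-action reaction network that counts directed nutrient
#' switches. In the left branch, glucose catalytically produces a galactose
#' sensor; when galactose appears, the sensor reversibly binds it to form a
#' galactose activator (Gal_Sensor + Gal = Gal_Activator), and the activator
#' catalytically produces the glucose-to-galactose counter molecule. The
#' right branch mirrors this (galactose produces a glucose sensor; the
#' glucose activator produces the galactose-to-glucose counter). Sensors and
#' activators degrade quickly; counters degrade very slowly and therefore act
#' as stable memory whose plateau encodes how many transitions of each
#' direction have occurred. The crosstalk wiring - each sugar producing the
#' sensor for the *other* sugar - is what makes a completed spike require an
#' actual transition.
#'
#' Catalytic steps are linear in the catalyst (rate `k * [modifier]`, or
#' `k * [modifier] * [substrate]` for the binding step); the input sugars
#' Glu and Gal are clamped to the schedule during simulation.
#'
#' @param rates Named rate-constant overrides of [counter_default_rates()].
#' @param initial Named initial-concentration overrides (all species default
#'   to 0).
#' @return A `circuit_model` object.
#' @examples
#' build_transition_counter()
#' @export
build_transition_counter <- function(rates = NULL, initial = NULL) {
  k <- counter_default_rates()
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(k))
    if (length(bad) > 0) {
      abort(paste0("Unknown rate constant(s): ", paste(bad, collapse = ", ")))
    }
    if (any(rates <= 0)) abort("Rate constants must be strictly positive.")
    k[names(rates)] <- rates
  }
  species <- counter_species()
  y0 <- setNames(rep(0, length(species)), species)
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), species)
    if (length(bad) > 0) {
      abort(paste0("Unknown species: ", paste(bad, collapse = ", ")))
    }
    if (any(initial < 0)) abort("Initial concentrations must be nonnegative.")
    y0[names(initial)] <- initial
  }
  reactions <- list(
    list(kind = "catalytic_production", modifier = "Glu",
         product = "Gal_Sensor", rate = k[["k_sense"]]),
    list(kind = "reversible_binding", reactants = c("Gal_Sensor", "Gal"),
         product = "Gal_Activator", forward = k[["k_bind"]],
         reverse = k[["k_unbind"]]),
    list(kind = "catalytic_production", modifier = "Gal_Activator",
         product = "GluToGal_Counter", rate = k[["k_count"]]),
    list(kind = "catalytic_production", modifier = "Gal",
         product = "Glu_Sensor", rate = k[["k_sense"]]),
    list(kind = "reversible_binding", reactants = c("Glu_Sensor", "Glu"),
         product = "Glu_Activator", forward = k[["k_bind"]],
         reverse = k[["k_unbind"]]),
    list(kind = "catalytic_production", modifier = "Glu_Activator",
         product = "GalToGlu_Counter", rate = k[["k_count"]]),
    list(kind = "degradation", species = "Gal_Sensor",
         rate = k[["k_deg_sensor"]]),
    list(kind = "degradation", species = "Glu_Sensor",
         rate = k[["k_deg_sensor"]]),
    list(kind = "degradation", species = "Gal_Activator",
         rate = k[["k_deg_act"]]),
    list(kind = "degradation", species = "Glu_Activator",
         rate = k[["k_deg_act"]]),
    list(kind = "degradation", species = "GluToGal_Counter",
         rate = k[["k_deg_counter"]]),
    list(kind = "degradation", species = "GalToGlu_Counter",
         rate = k[["k_deg_counter"]])
  )
  structure(list(species = species, reactions = reactions, rates = k,
                 initial = y0),
            class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("<circuit_model> %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  invisible(x)
}

#' Piecewise-constant sugar input schedule
#'
#' @param t_start,t_end Segment boundaries (contiguous, non-overlapping).
#' @param glu,gal Clamped input levels per segment (nonnegative).
#' @return An `input_schedule` tibble.
#' @seealso [alternating_schedule()] for the canonical pulse train.
#' @export
input_schedule <- function(t_start, t_end, glu, gal) {
  n <- length(t_start)
  if (length(t_end) != n || length(glu) != n || length(gal) != n) {
    abort("All schedule columns must have the same length.")
  }
  if (any(t_end <= t_start)) abort("Each segment must have t_end > t_start.")
  if (n > 1 && any(abs(t_start[-1] - t_end[-n]) > 1e-9)) {
    abort("Schedule segments must be contiguous and non-overlapping.")
  }
  if (any(glu < 0 | gal < 0)) abort("Input levels must be nonnegative.")
  out <- tibble(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                glu = as.numeric(glu), gal = as.numeric(gal))
  class(out) <- c("input_schedule", class(out))
  out
}

#' Alternating glucose/galactose pulse schedule
#'
#' Pulses of a single sugar at a time, switching every `period` time units.
#' The default (`period = 50`, `t_end = 200`, glucose first) is the
#' worked-example schedule: glucose on \[0, 50), galactose on \[50, 100),
#' glucose on \[100, 150), galactose on \[150, 200\], giving two
#' glucose-to-galactose switches and one galactose-to-glucose switch.
#'
#' @param period Pulse length.
#' @param t_end End of the simulation window.
#' @param level Input concentration during a pulse.
#' @param first Which sugar comes first (`"Glu"` or `"Gal"`).
#' @return An `input_schedule`.
#' @export
alternating_schedule <- function(period = 50, t_end = 200, level = 1,
                                 first = c("Glu", "Gal")) {
  first <- match.arg(first)
  n_seg <- max(1L, ceiling(t_end / period - 1e-9))
  starts <- (seq_len(n_seg) - 1) * period
  ends <- pmin(starts + period, t_end)
  glu_on <- (seq_along(starts) %% 2) == (if (first == "Glu") 1 else 0)
  input_schedule(starts, ends, glu = level * glu_on, gal = level * !glu_on)
}

#' Simulate the transition-counter circuit
#'
#' Integrates the mass-action ODEs with the input sugars clamped to the
#' schedule, segment by segment (so input discontinuities never cross an
#' integrator step). Uses `deSolve::lsoda` with tight tolerances
#' (atol 1e-10, rtol 1e-8).
#'
#' @param model A `circuit_model`.
#' @param schedule An `input_schedule` covering the simulation window.
#' @param dt Output sampling interval (default 0.1).
#' @return A `circuit_sim` tibble: `t` plus one concentration column per
#'   species.
#' @examples
#' \donttest{
#' sim <- simulate_circuit(build_transition_counter(), alternating_schedule())
#' }
#' @export
simulate_circuit <- function(model, schedule, dt = 0.1) {
  stopifnot(inherits(model, "circuit_model"),
            inherits(schedule, "input_schedule"))
  k <- model$rates
  deriv <- function(t, y, parms) {
    glu <- parms[["glu"]]; gal <- parms[["gal"]]
    gs <- y[["Gal_Sensor"]]; ga <- y[["Gal_Activator"]]
    us <- y[["Glu_Sensor"]]; ua <- y[["Glu_Activator"]]
    bind_gal <- k[["k_bind"]] * gs * gal - k[["k_unbind"]] * ga
    bind_glu <- k[["k_bind"]] * us * glu - k[["k_unbind"]] * ua
    list(c(
      Glu = 0, Gal = 0,  # clamped inputs
      Glu_Sensor = k[["k_sense"]] * gal - bind_glu -
        k[["k_deg_sensor"]] * us,
      Gal_Sensor = k[["k_sense"]] * glu - bind_gal -
        k[["k_deg_sensor"]] * gs,
      Glu_Activator = bind_glu - k[["k_deg_act"]] * ua,
      Gal_Activator = bind_gal - k[["k_deg_act"]] * ga,
      GluToGal_Counter = k[["k_count"]] * ga -
        k[["k_deg_counter"]] * y[["GluToGal_Counter"]],
      GalToGlu_Counter = k[["k_count"]] * ua -
        k[["k_deg_counter"]] * y[["GalToGlu_Counter"]]
    ))
  }
  y <- model$initial
  pieces <- vector("list", nrow(schedule))
  for (seg in seq_len(nrow(schedule))) {
    y[["Glu"]] <- schedule$glu[seg]
    y[["Gal"]] <- schedule$gal[seg]
    times <- seq(schedule$t_start[seg], schedule$t_end[seg], by = dt)
    if (times[length(times)] < schedule$t_end[seg]) {
      times <- c(times, schedule$t_end[seg])
    }
    sol <- deSolve::lsoda(y, times, deriv,
                          parms = c(glu = schedule$glu[seg],
                                    gal = schedule$gal[seg]),
                          atol = 1e-10, rtol = 1e-8)
    if (attr(sol, "istate")[1] != 2) {
      abort(sprintf("Integrator failed in segment %d (istate %d).",
                    seg, attr(sol, "istate")[1]))
    }
    sol <- as.data.frame(sol)
    names(sol)[1] <- "t"
    y <- setNames(as.numeric(sol[nrow(sol), model$species]), model$species)
    if (seg > 1) sol <- sol[-1, , drop = FALSE]  # drop duplicated boundary
    pieces[[seg]] <- sol
  }
  out <- as_tibble(do.call(rbind, pieces))
  class(out) <- c("circuit_sim", class(out))
  attr(out, "model") <- model
  attr(out, "schedule") <- schedule
  out
}

#' Read integer transition counts off a counter trajectory
#'
#' Divides the final plateau level of a counter trajectory by the calibrated
#' increment a single switch produces and rounds to the nearest integer.
#' Spike times (rising edges where the derivative crosses 20% of its
#' maximum) are attached for diagnostics.
#'
#' @param trajectory Numeric counter concentrations over time.
#' @param increment The single-switch increment (from
#'   [calibrate_increment()]).
#' @param times Optional time points (defaults to the sample index).
#' @return Integer count with attribute `"spike_times"`.
#' @export
count_transitions <- function(trajectory, increment, times = NULL) {
  if (increment <= 0) abort("`increment` must be positive.")
  trajectory <- as.numeric(trajectory)
  n <- length(trajectory)
  if (is.null(times)) times <- seq_len(n)
  count <- as.integer(round(trajectory[n] / increment))
  d <- diff(trajectory) / diff(times)
  spikes <- numeric(0)
  if (any(d > 0)) {
    thr <- 0.2 * max(d)
    above <- d > thr & thr > 0
    rising <- which(above & !c(FALSE, above[-length(above)]))
    spikes <- times[rising]
  }
  structure(count, spike_times = spikes)
}

#' Calibrate the single-switch counter increment
#'
#' Simulates the circuit through exactly one nutrient switch (one full pulse
#' of the first sugar followed by the second) and returns the final level of
#' the corresponding counter - the concentration increment one directed
#' transition contributes.
#'
#' @param model A `circuit_model`.
#' @param period Pulse length (default 50).
#' @param level Input level (default 1).
#' @param direction `"GluToGal"` or `"GalToGlu"`.
#' @param dt Output step.
#' @return The single-switch increment (a positive number).
#' @export
calibrate_increment <- function(model, period = 50, level = 1,
                                direction = c("GluToGal", "GalToGlu"),
                                dt = 0.1) {
  direction <- match.arg(direction)
  first <- if (direction == "GluToGal") "Glu" else "Gal"
  sched <- alternating_schedule(period = period, t_end = 2 * period,
                                level = level, first = first)
  sim <- simulate_circuit(model, sched, dt = dt)
  col <- paste0(direction, "_Counter")
  tail(sim[[col]], 1)
}

#' Count both directed transitions under an input schedule
#'
#' Convenience wrapper: simulates the circuit under `schedule`, calibrates
#' the single-switch increment for each direction from a one-switch run, and
#' reads out both counters.
#'
#' @param model A `circuit_model` (default build).
#' @param schedule An `input_schedule` (default the canonical four-pulse
#'   train).
#' @param dt Output step.
#' @return A tibble with `direction`, `final_level`, `increment`, `count`,
#'   and a list-column `spike_times`.
#' @examples
#' \donttest{
#' count_switches()  # 2 Glu->Gal and 1 Gal->Glu under the default schedule
#' }
#' @export
count_switches <- function(model = build_transition_counter(),
                           schedule = alternating_schedule(), dt = 0.1) {
  sim <- simulate_circuit(model, schedule, dt = dt)
  period <- schedule$t_end[1] - schedule$t_start[1]
  level <- max(schedule$glu, schedule$gal)
  purrr::map_dfr(c("GluToGal", "GalToGlu"), function(dir) {
    inc <- calibrate_increment(model, period = period, level = level,
                               direction = dir, dt = dt)
    col <- paste0(dir, "_Counter")
    cnt <- count_transitions(sim[[col]], increment = inc, times = sim$t)
    tibble(direction = dir,
           final_level = tail(sim[[col]], 1),
           increment = inc,
           count = as.integer(cnt),
           spike_times = list(attr(cnt, "spike_times")))
  })
}
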