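#' Simulation settings
#'
#' Time window, output grid and integrator controls. The default window of
#' 1500 s at 1500 evenly spaced output points resolves the peak times of the
#' follicle models (tens to hundreds of seconds) to about one second;
#' receptor-level readouts are typically re-run on a 0-70 s window. The
#' default method is `lsoda` (switches to a stiff BDF scheme automatically);
#' `vode` and `radau` are accepted for solver cross-checks.
#'
#' @param t_start,t_end Simulation window in seconds.
#' @param n_output_points Number of output times (>= 2), evenly spaced.
#' @param rel_tol,abs_tol Integrator tolerances (> 0).
#' @param method Integrator identifier understood by [deSolve::ode()].
#' @return List of class `sbn_settings`.
#' @export
simulation_settings <- function(t_start = 0, t_end = 1500,
                                n_output_points = 1500,
                                rel_tol = 1e-8, abs_tol = 1e-10,
                                method = "lsoda") {
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (n_output_points < 2) stop("need at least 2 output points", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be positive", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end,
                 n_output_points = as.integer(n_output_points),
                 rel_tol = rel_tol, abs_tol = abs_tol, method = method),
            class = "sbn_settings")
}

#' Integrate a model to a time course
#'
#' Deterministic stiff integration of the mass-action ODE system
#' `dx/dt = N v(x)` built by [build_ode_rhs()]. The model is deterministic,
#' so `nsim`/`seed` of the [stats::simulate()] generic are accepted for
#' interface compatibility but a single trajectory is always returned.
#'
#' @param object A validated `sbn_model`.
#' @param nsim,seed Ignored (deterministic model); present for the generic.
#' @param settings A [simulation_settings()] object.
#' @param ... Unused.
#' @return Object of class `sbn_timecourse`: `times` (seconds), `values`
#'   (species x time matrix, first column equal to the initial amounts),
#'   `species_ids`, `settings`.
#' @export
#' @examples
#' m <- network_model(
#'   species = list(species_def("A", initial = 1), species_def("B")),
#'   reactions = list(reaction_def("decay", c(A = 1), c(B = 1), kf = 0.1)))
#' tc <- simulate(m, settings = simulation_settings(t_end = 10, n_output_points = 11))
#' tc$values["B", 11]   # 1 - exp(-1)
simulate.sbn_model <- function(object, nsim = 1, seed = NULL,
                               settings = simulation_settings(), ...) {
  stopifnot(inherits(settings, "sbn_settings"))
  rhs <- build_ode_rhs(object)
  y0 <- initial_state(object)
  y0 <- apply_rules(object, y0)
  times <- seq(settings$t_start, settings$t_end,
               length.out = settings$n_output_points)
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) list(rhs(t, y)),
    parms = NULL, method = settings$method,
    rtol = settings$rel_tol, atol = settings$abs_tol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("integrator failed near t = %.6g s (diagnostic state %d)",
                 max(sol[, "time"]), attr(sol, "istate")[1L]), call. = FALSE)
  vals <- t(unname(sol[, -1L, drop = FALSE]))
  rownames(vals) <- names(y0)
  # re-apply assignment rules on the dense output so rule targets are exact
  if (length(object$rules)) {
    for (k in seq_len(ncol(vals)))
      vals[, k] <- apply_rules(object, vals[, k])
  }
  if (!all(is.finite(vals)))
    stop("integration produced non-finite values", call. = FALSE)
  structure(list(times = times, values = vals,
                 species_ids = names(y0), settings = settings),
            class = "sbn_timecourse")
}

#' @export
print.sbn_timecourse <- function(x, ...) {
  cat(sprintf("<sbn_timecourse> %d species over [%g, %g] s (%d points)\n",
              nrow(x$values), min(x$times), max(x$times), length(x$times)))
  invisible(x)
}

#' Convert a time course to a data frame
#'
#' @param x An `sbn_timecourse`.
#' @param row.names,optional Ignored.
#' @param long If `TRUE` (default) a tidy three-column frame
#'   (time, species, value); otherwise wide with one column per species.
#' @param ... Unused.
#' @export
as.data.frame.sbn_timecourse <- function(x, row.names = NULL, optional = FALSE,
                                         long = TRUE, ...) {
  if (long) {
    data.frame(
      time = rep(x$times, each = nrow(x$values)),
      species = rep(x$species_ids, times = length(x$times)),
      value = as.vector(x$values),
      stringsAsFactors = FALSE)
  } else {
    cbind(data.frame(time = x$times),
          as.data.frame(t(x$values)))
  }
}

#' Plot selected species of a time course
#'
#' @param x An `sbn_timecourse`.
#' @param species Character vector of species ids (default: six largest
#'   amplitudes).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sbn_timecourse <- function(x, species = NULL, ...) {
  if (is.null(species)) {
    amp <- apply(x$values, 1L, max)
    species <- names(sort(amp, decreasing = TRUE))[seq_len(min(6L, nrow(x$values)))]
  }
  graphics::matplot(x$times, t(x$values[species, , drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "concentration (a.u.)", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n", cex = 0.8)
  invisible(x)
}

#' Integrate with automatic tolerance refinement
#'
#' Halves (squares down) the integrator tolerances until the peak-time
#' estimate of a probe species changes by less than one output-grid step
#' between successive refinements, guarding peak-time statistics against
#' tolerance artefacts.
#'
#' @param model A validated `sbn_model`.
#' @param settings Starting [simulation_settings()].
#' @param probe Species id to monitor; default: the species with the largest
#'   dynamic range in the first pass.
#' @param max_refinements Give up (with an error) after this many halvings.
#' @return The converged `sbn_timecourse`, with attribute `"convergence"`
#'   (data frame of refinement steps and peak-time estimates).
#' @export
refine_until_converged <- function(model, settings = simulation_settings(),
                                   probe = NULL, max_refinements = 5L) {
  tc <- simulate(model, settings = settings)
  if (is.null(probe)) {
    rng <- apply(tc$values, 1L, function(v) diff(range(v)))
    probe <- names(which.max(rng))
  }
  grid_step <- diff(tc$times[1:2])
  pt <- function(tc) {
    v <- tc$values[probe, ]
    tc$times[which.max(v)]
  }
  history <- data.frame(refinement = 0L, rel_tol = settings$rel_tol,
                        peak_time = pt(tc))
  for (i in seq_len(max_refinements)) {
    s2 <- settings
    s2$rel_tol <- settings$rel_tol / 2^i
    s2$abs_tol <- settings$abs_tol / 2^i
    tc2 <- simulate(model, settings = s2)
    history <- rbind(history, data.frame(refinement = i, rel_tol = s2$rel_tol,
                                         peak_time = pt(tc2)))
    if (abs(pt(tc2) - pt(tc)) < grid_step) {
      attr(tc2, "convergence") <- history
      return(tc2)
    }
    tc <- tc2
  }
  stop("peak-time estimate did not converge after ", max_refinements,
       " tolerance refinements", call. = FALSE)
}

#' Export a time course as CSV
#'
#' Writes the trajectory in tidy (long) or wide form, with the simulation
#' settings echoed to a JSON sidecar for provenance.
#'
#' @param tc An `sbn_timecourse`.
#' @param path CSV output path; the sidecar is `<path>.settings.json`.
#' @param long Tidy long format (default) or wide.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, long = TRUE) {
  utils::write.csv(as.data.frame(tc, long = long), path, row.names = FALSE)
  jsonlite::write_json(unclass(tc$settings), paste0(path, ".settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
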