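#' Trajectory container
#'
#' Time-indexed states (probability vectors or concentration vectors, one row
#' per time point) with an optional free-energy annotation in nats.
#'
#' @param times strictly increasing numeric vector (arbitrary time units).
#' @param states numeric matrix, one row per time point.
#' @param free_energy optional numeric vector of per-time free energies.
#' @param labels optional column (state/species) names.
#' @return an object of class `catflow_trajectory`.
#' @export
trajectory <- function(times, states, free_energy = NULL, labels = NULL) {
  times <- as.numeric(times)
  states <- as.matrix(states)
  if (length(times) != nrow(states))
    stop("trajectory: times and states lengths disagree")
  if (any(diff(times) <= 0))
    stop("trajectory: times must be strictly increasing")
  if (!is.null(free_energy) && length(free_energy) != length(times))
    stop("trajectory: free_energy length disagrees with times")
  if (!is.null(labels)) colnames(states) <- labels
  structure(list(times = times, states = states, free_energy = free_energy),
            class = "catflow_trajectory")
}

#' @export
print.catflow_trajectory <- function(x, ...) {
  cat("<trajectory:", length(x$times), "time points x", ncol(x$states),
      "states", if (!is.null(x$free_energy)) "(+free energy)", ">\n")
  cat("  t in [", min(x$times), ",", max(x$times), "]\n")
  cat("  final state:", signif(x$states[nrow(x$states), ], 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.catflow_trajectory <- function(x, ...) {
  df <- data.frame(time = x$times, x$states, check.names = FALSE)
  if (!is.null(x$free_energy)) df$free_energy <- x$free_energy
  df
}

#' Write a trajectory to CSV
#'
#' Column 1 is `time`, then one column per state/species, and an optional
#' `free_energy` column. Values are written at full double precision (17
#' significant digits) so repeated deterministic runs are byte-identical.
#'
#' @param traj a `catflow_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Final state of a trajectory
#'
#' @param traj a `catflow_trajectory`.
#' @return the last row of the state matrix, as a named vector when the
#'   trajectory carries labels.
#' @export
final_state <- function(traj) {
  out <- traj$states[nrow(traj$states), ]
  if (!is.null(colnames(traj$states))) names(out) <- colnames(traj$states)
  out
}

# shared integrator contract: adaptive stiff-capable lsoda, tight tolerances,
# so master equations and the (stiff) enzymatic systems go through one path
ode_integrate <- function(y0, times, rhs, rtol = 1e-8, atol = 1e-10, ...) {
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms) list(rhs(t, y)),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol, ...)
  if (attr(sol, "istate")[1] < 0)
    stop("ode_integrate: integration failed (istate = ",
         attr(sol, "istate")[1], ")")
  list(times = sol[, 1], states = unname(sol[, -1, drop = FALSE]))
}
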