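#' Integrate a categorical master equation
#'
#' Solves `dp/dt = L p` from `p0` at the requested times with an adaptive
#' stiff-capable integrator (lsoda, relative tolerance `1e-8`, absolute
#' `1e-10`). For a valid rate matrix the solution equals `expm(L t) p0`,
#' stays on the probability simplex, and the variational free energy
#' relative to the stationary distribution is non-increasing.
#'
#' @param L a `rate_matrix`.
#' @param p0 initial distribution (`catdist` or numeric vector on the
#'   simplex).
#' @param times strictly increasing output times.
#' @param free_energy logical; annotate the trajectory with
#'   `free_energy(p(t), p_inf)` when the steady state is computable.
#' @return a `catflow_trajectory`.
#' @examples
#' L <- rate_matrix(matrix(c(-2, 2, 1, -1), 2))
#' simulate_master(L, c(1, 0), seq(0, 5, 0.5))
#' @export
simulate_master <- function(L, p0, times, free_energy = TRUE) {
  M <- rm_entries(L)
  if (any(!is.finite(M))) stop("simulate_master: non-finite entries in L")
  p0 <- if (inherits(p0, "catdist")) p0$probs else as.numeric(p0)
  stopifnot(length(p0) == nrow(M))
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < -1e-12))
    stop("simulate_master: p0 must lie on the probability simplex")
  sol <- ode_integrate(p0, times, function(t, y) M %*% y)
  fe <- NULL
  if (free_energy) {
    pinf <- tryCatch(steady_state(L), error = function(e) NULL)
    if (!is.null(pinf))
      fe <- apply(sol$states, 1, function(r)
        free_energy(pmax(r, 0) / sum(pmax(r, 0)), pinf))
  }
  trajectory(sol$times, sol$states, free_energy = fe,
             labels = if (inherits(L, "rate_matrix")) L$labels else NULL)
}

#' Integrate selected components of the decomposed flow
#'
#' Using the decomposition `L = (Q - Gamma) Lambda`, integrates
#' `dp/dt = (Q - Gamma) Lambda p` (`mode = "full"`), the solenoidal part
#' `dp/dt = Q Lambda p` alone, or the dissipative part
#' `dp/dt = -Gamma Lambda p` alone. The solenoidal flow conserves the
#' linearized free energy `G(p) = p . Lambda p / 2` exactly (skew symmetry
#' of `Q`) and its trajectories are deliberately not clamped to the simplex:
#' they may develop negative entries. The dissipative flow descends the free
#' energy and converges to `p_inf`; the full flow reaches the same minimum
#' along a different path.
#'
#' @param L a `rate_matrix`.
#' @param p_inf stationary distribution (strictly positive); computed from
#'   `L` if missing.
#' @param p0 initial distribution.
#' @param times output times.
#' @param mode one of `"full"`, `"solenoidal"`, `"dissipative"`.
#' @return a `catflow_trajectory`; its free-energy annotation is the exact
#'   functional for full/dissipative modes and the conserved quadratic
#'   `p . Lambda p / 2` for the solenoidal mode (the exact functional is not
#'   defined off the simplex).
#' @export
simulate_mode <- function(L, p0, times,
                          mode = c("full", "solenoidal", "dissipative"),
                          p_inf = NULL) {
  mode <- match.arg(mode)
  if (is.null(p_inf)) p_inf <- steady_state(L)
  dec <- decompose(L, p_inf)
  G <- switch(mode,
    full        = (dec$Q - dec$Gamma) %*% dec$Lambda,
    solenoidal  = dec$Q %*% dec$Lambda,
    dissipative = -dec$Gamma %*% dec$Lambda)
  p0 <- if (inherits(p0, "catdist")) p0$probs else as.numeric(p0)
  sol <- ode_integrate(p0, times, function(t, y) G %*% y)
  if (mode == "solenoidal") {
    lam <- diag(dec$Lambda)
    fe <- apply(sol$states, 1, function(r) sum(r * lam * r) / 2)
  } else {
    fe <- apply(sol$states, 1, function(r) {
      r <- pmax(r, 0); free_energy(r / sum(r), dec$p_inf)
    })
  }
  trajectory(sol$times, sol$states, free_energy = fe,
             labels = if (inherits(L, "rate_matrix")) L$labels else NULL)
}

#' Integrate a master equation until the steady-state criterion is met
#'
#' Advances the system in windows of one time unit until
#' `||dp/dt||_inf < tol` holds over a whole window (sustained, not just at a
#' point), or the horizon is reached.
#'
#' @param L a `rate_matrix`.
#' @param p0 initial distribution.
#' @param tol derivative threshold declaring steady state.
#' @param horizon maximum integration time.
#' @return list with `p` (final `catdist`), `converged`, `time`.
#' @export
integrate_to_steady_state <- function(L, p0, tol = 1e-8, horizon = 1e4) {
  M <- rm_entries(L)
  p <- if (inherits(p0, "catdist")) p0$probs else as.numeric(p0)
  t <- 0
  while (t < horizon) {
    sol <- ode_integrate(p, seq(t, t + 1, length.out = 11),
                         function(tt, y) M %*% y)
    derivs <- apply(sol$states, 1, function(r) max(abs(M %*% r)))
    p <- sol$states[nrow(sol$states), ]
    t <- t + 1
    if (max(derivs) < tol)
      return(list(p = catdist(pmax(p, 0) / sum(pmax(p, 0))),
                  converged = TRUE, time = t))
  }
  list(p = catdist(pmax(p, 0) / sum(pmax(p, 0))), converged = FALSE,
       time = t)
}
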