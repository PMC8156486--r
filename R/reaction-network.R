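#' Multi-reaction network
#'
#' Assembles species, reactions (mass-action and/or Michaelis--Menten) and
#' constant source terms into a network with an explicit stoichiometry
#' matrix. Reversible mass-action reactions contribute two directed columns
#' (forward and backward are separate reactions); a Michaelis--Menten
#' reaction contributes one. A Michaelis--Menten reaction whose `product`
#' is `NA` is an efflux (sink) reaction. Conserved moieties -- left null
#' vectors of the stoichiometry matrix supported on source-free species --
#' are computed at assembly and stored.
#'
#' @param species character vector of species names.
#' @param reactions named list of [mass_action_reaction()] /
#'   [michaelis_menten()] objects; names are used as reaction ids when the
#'   objects carry none.
#' @param sources named numeric vector of constant influx (+) per unit
#'   time; default none.
#' @return an object of class `reaction_network` with elements `species`,
#'   `reactions`, `stoichiometry` (species x directed reactions), `sources`,
#'   `moieties`.
#' @export
reaction_network <- function(species, reactions, sources = NULL) {
  species <- as.character(species)
  if (is.null(names(reactions)) || any(names(reactions) == ""))
    names(reactions) <- vapply(seq_along(reactions), function(i)
      reactions[[i]]$id %||% paste0("r", i), character(1))
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    refs <- if (inherits(r, "mass_action_reaction"))
      c(names(r$substrates), names(r$products))
    else c(r$substrate, if (!is.na(r$product)) r$product)
    if (!all(refs %in% species))
      stop("reaction_network: reaction '", nm, "' references unknown ",
           "species ", paste(setdiff(refs, species), collapse = ", "))
  }
  src <- stats::setNames(numeric(length(species)), species)
  if (!is.null(sources)) {
    if (!all(names(sources) %in% species))
      stop("reaction_network: source attached to undeclared species")
    src[names(sources)] <- sources
  }
  # record reversibility structurally: a later lesion zeroes constants but
  # must not change the stoichiometry's column set
  for (nm in names(reactions))
    if (inherits(reactions[[nm]], "mass_action_reaction"))
      reactions[[nm]]$reversible <- reactions[[nm]]$kr > 0
  net <- structure(list(species = species, reactions = reactions,
                        sources = src), class = "reaction_network")
  net$stoichiometry <- network_stoichiometry(net)
  net$moieties <- network_moieties(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network:", length(x$species), "species,",
      ncol(x$stoichiometry), "directed reactions,",
      sum(x$sources != 0), "sources/sinks>\n")
  invisible(x)
}

# species x directed-reaction integer stoichiometry (net coefficients)
network_stoichiometry <- function(net) {
  cols <- list()
  for (nm in names(net$reactions)) {
    r <- net$reactions[[nm]]
    if (inherits(r, "mass_action_reaction")) {
      w <- stats::setNames(numeric(length(net$species)), net$species)
      w[names(r$substrates)] <- w[names(r$substrates)] - r$substrates
      w[names(r$products)] <- w[names(r$products)] + r$products
      cols[[paste0(nm, ".f")]] <- w
      if (isTRUE(r$reversible)) cols[[paste0(nm, ".r")]] <- -w
    } else {
      w <- stats::setNames(numeric(length(net$species)), net$species)
      w[r$substrate] <- -1
      if (!is.na(r$product)) w[r$product] <- 1
      cols[[nm]] <- w
    }
  }
  do.call(cbind, cols)
}

# directed reaction rates r(u) (the "messages")
network_rates <- function(net, u) {
  rates <- numeric(0)
  for (nm in names(net$reactions)) {
    r <- net$reactions[[nm]]
    if (inherits(r, "mass_action_reaction")) {
      rates[paste0(nm, ".f")] <- r$kf * rate_product(u, r$substrates)
      if (isTRUE(r$reversible))
        rates[paste0(nm, ".r")] <- r$kr * rate_product(u, r$products)
    } else {
      rates[nm] <- mm_rate(r, max(u[[r$substrate]], 0))
    }
  }
  rates
}

network_rhs <- function(net, u) {
  names(u) <- net$species
  du <- as.numeric(net$stoichiometry %*% network_rates(net, u)) +
    net$sources
  # ramp sources that would drain an exhausted species
  drained <- net$sources < 0 & u < 1e-9
  if (any(drained))
    du[drained] <- du[drained] -
      net$sources[drained] * (1 - pmax(u[drained], 0) / 1e-9)
  stats::setNames(du, net$species)
}

# left null vectors of the stoichiometry over source-free species
network_moieties <- function(net) {
  free <- net$species[net$sources == 0]
  if (length(free) == 0) return(matrix(0, 0, length(net$species)))
  Om <- net$stoichiometry[free, , drop = FALSE]
  sv <- svd(t(Om), nu = 0, nv = length(free))
  null_idx <- which(c(sv$d, rep(0, length(free) - length(sv$d))) <
                      1e-10 * max(sv$d, 1))
  if (length(null_idx) == 0) return(matrix(0, 0, length(net$species)))
  M <- matrix(0, length(null_idx), length(net$species),
              dimnames = list(NULL, net$species))
  M[, free] <- t(sv$v[, null_idx, drop = FALSE])
  M
}

#' Simulate a reaction network
#'
#' Integrates `du/dt = Omega r(u) + s`. Conserved moieties of the closed
#' part stay constant and concentrations remain non-negative (up to
#' integrator tolerance) for well-posed networks.
#'
#' @param network a [reaction_network()].
#' @param u0 named (or ordered) initial concentrations.
#' @param times output times.
#' @return a `catflow_trajectory` with one column per species.
#' @export
simulate_network <- function(network, u0, times) {
  u0 <- if (!is.null(names(u0))) u0[network$species] else
    stats::setNames(as.numeric(u0), network$species)
  if (any(u0 < 0)) stop("simulate_network: u0 must be non-negative")
  sol <- ode_integrate(as.numeric(u0), times, function(t, y)
    as.numeric(network_rhs(network, y)))
  trajectory(sol$times, sol$states, labels = network$species)
}

#' Integrate a network to steady state
#'
#' Advances the system in growing windows until `||du/dt||_inf` stays below
#' `tol` across a whole window of one time unit, then polishes the state
#' with damped Newton iterations on `Omega r(u) + s = 0` (finite-difference
#' Jacobian) to drive the residual to solver precision. Non-convergence
#' within the horizon is a reported state, not an error.
#'
#' @param network a [reaction_network()].
#' @param u0 initial concentrations.
#' @param tol steady-state derivative threshold.
#' @param horizon maximum integration time (default `1e4` time units, so
#'   oscillatory networks terminate with `converged = FALSE`).
#' @return an object of class `steady_state_report`: `u` (named
#'   concentrations), `residual` (`||Omega r + s||_inf`), `converged`,
#'   `time` (integration time used).
#' @export
find_steady_state <- function(network, u0, tol = 1e-8, horizon = 1e4) {
  u <- if (!is.null(names(u0))) as.numeric(u0[network$species]) else
    as.numeric(u0)
  t_used <- 0; window <- 1; settled <- FALSE
  repeat {
    if (max(abs(network_rhs(network, u))) < tol) { settled <- TRUE; break }
    if (t_used >= horizon) break
    # sample densely enough that the last time unit of the window is covered
    sol <- ode_integrate(u, seq(0, window, length.out = max(11, window + 1)),
                         function(t, y) as.numeric(network_rhs(network, y)))
    derivs <- apply(sol$states, 1, function(r)
      max(abs(network_rhs(network, r))))
    u <- sol$states[nrow(sol$states), ]
    t_used <- t_used + window
    if (all(derivs[sol$times >= window - 1] < tol)) { settled <- TRUE; break }
    window <- min(window * 2, max(1, horizon - t_used))
  }
  # polish only a settled state: polishing an oscillator would jump to an
  # unstable fixed point and misreport convergence
  if (settled) u <- newton_polish(network, u)
  resid <- max(abs(network_rhs(network, u)))
  structure(list(u = stats::setNames(u, network$species),
                 residual = resid, converged = settled && resid < tol,
                 time = t_used),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat("<steady_state_report: converged =", x$converged,
      "| residual =", signif(x$residual, 3),
      "| t =", x$time, ">\n")
  print(signif(x$u, 6))
  invisible(x)
}

newton_polish <- function(network, u, iters = 20) {
  f <- function(x) as.numeric(network_rhs(network, x))
  best <- u; bestres <- max(abs(f(u)))
  for (i in seq_len(iters)) {
    r <- f(u)
    if (max(abs(r)) < 1e-13) break
    n <- length(u)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-8, 1e-8 * abs(u[j]))
      up <- u; up[j] <- up[j] + h
      J[, j] <- (f(up) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    cand <- u + step
    if (any(cand < -1e-10) || max(abs(f(cand))) >= max(abs(r))) {
      cand <- u + step / 4          # damped fallback
      if (any(cand < -1e-10) || max(abs(f(cand))) >= max(abs(r))) break
    }
    u <- pmax(cand, 0)
    if (max(abs(f(u))) < bestres) { best <- u; bestres <- max(abs(f(u))) }
  }
  best
}

#' Lesion a reaction
#'
#' Returns a copy of the network in which the given reaction is silenced:
#' its `v_max` (Michaelis--Menten) or both rate constants (mass action) are
#' set to zero. The stoichiometry matrix is untouched -- a lesion is a
#' parameter change, not a structural one -- yet its consequences propagate
#' through the whole network (diaschisis).
#'
#' @param network a [reaction_network()].
#' @param reaction_id name of the reaction to silence.
#' @return the lesioned `reaction_network`.
#' @export
lesion <- function(network, reaction_id) {
  if (!reaction_id %in% names(network$reactions))
    stop("lesion: unknown reaction '", reaction_id, "'")
  r <- network$reactions[[reaction_id]]
  if (inherits(r, "michaelis_menten")) r$v_max <- 0
  else { r$kf <- 0; r$kr <- 0 }
  network$reactions[[reaction_id]] <- r
  network
}

#' Compare two steady states after a perturbation
#'
#' Classifies each species' change between a pre- and post-perturbation
#' steady state: `lost` (present before, essentially zero after),
#' `decreased`, `unchanged` (absolute change below `threshold`), or
#' `increased`. Distant species can change even though only one reaction's
#' parameters did -- the network analogue of diaschisis.
#'
#' @param pre,post `steady_state_report`s over the same species (both
#'   converged).
#' @param threshold absolute-change threshold for `unchanged`, and the
#'   "essentially zero" level for `lost`.
#' @return a data frame (class `diaschisis_report`) with columns `species`,
#'   `pre`, `post`, `change`, `class`.
#' @export
diaschisis <- function(pre, post, threshold = 1e-6) {
  if (!identical(names(pre$u), names(post$u)))
    stop("diaschisis: the two reports cover different species")
  if (!pre$converged || !post$converged)
    stop("diaschisis: both steady states must have converged")
  ch <- post$u - pre$u
  cls <- ifelse(abs(ch) <= threshold, "unchanged",
         ifelse(post$u <= threshold & pre$u > threshold, "lost",
         ifelse(ch < 0, "decreased", "increased")))
  structure(data.frame(species = names(pre$u), pre = unname(pre$u),
                       post = unname(post$u), change = unname(ch),
                       class = unname(cls), row.names = NULL),
            class = c("diaschisis_report", "data.frame"))
}

#' Example metabolic network
#'
#' A seven-species Michaelis--Menten network with one sensory species
#' (`S3`, constant external influx) and two active species (`S5`, `S7`,
#' saturating efflux): influx -> S3 -> S2 -> S1, which branches to
#' S4 -> S5 -> out and S6 -> S7 -> out. Every interior conversion has a
#' weaker reverse reaction, so back-pressure propagates upstream and a
#' lesion produces compensatory increases behind it as well as losses
#' downstream of it.
#'
#' @param influx constant source rate into `S3`.
#' @param v_max,v_max_rev,kappa_m forward/reverse maximal rates and shared
#'   half-saturation constant of the interior conversions.
#' @return a [reaction_network()].
#' @export
metabolic_network <- function(influx = 0.1, v_max = 1, v_max_rev = 0.5,
                              kappa_m = 1) {
  mk <- function(s, p, v = v_max)
    michaelis_menten(v, kappa_m, substrate = s, product = p)
  fwd <- list(S3_to_S2 = mk("S3", "S2"), S2_to_S1 = mk("S2", "S1"),
              S1_to_S4 = mk("S1", "S4"), S4_to_S5 = mk("S4", "S5"),
              S1_to_S6 = mk("S1", "S6"), S6_to_S7 = mk("S6", "S7"))
  rev <- list(S2_to_S3 = mk("S2", "S3", v_max_rev),
              S1_to_S2 = mk("S1", "S2", v_max_rev),
              S4_to_S1 = mk("S4", "S1", v_max_rev),
              S5_to_S4 = mk("S5", "S4", v_max_rev),
              S6_to_S1 = mk("S6", "S1", v_max_rev),
              S7_to_S6 = mk("S7", "S6", v_max_rev))
  out <- list(S5_out = michaelis_menten(v_max, kappa_m, substrate = "S5",
                                        product = NA),
              S7_out = michaelis_menten(v_max, kappa_m, substrate = "S7",
                                        product = NA))
  reaction_network(paste0("S", 1:7), c(fwd, rev, out),
                   sources = c(S3 = influx))
}
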