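#' Mean-field-corrected beta coefficient
#'
#' The equilibrium constant `beta = alpha / (1 - alpha)` obtained from
#' orthogonality to the joint steady state leaves the mean-field marginals
#' inconsistent with the model's marginals (a product of marginals is not
#' the joint). The correction raises the numerator to the power of the
#' number of substrate species and the denominator to the power of the
#' number of product species, which is what solving the fixed-point
#' condition at the steady-state marginals yields.
#'
#' @param alpha prior presence probability of the substrate block, in (0,1).
#' @param n_substrates,n_products species counts on each side.
#' @return `alpha^n_substrates / (1 - alpha)^n_products`.
#' @examples
#' corrected_beta(1/4, 2, 2)  # 1/9
#' corrected_beta(1/4, 1, 1)  # the uncorrected 1/3
#' @export
corrected_beta <- function(alpha, n_substrates, n_products) {
  if (alpha <= 0 || alpha >= 1)
    stop("corrected_beta: alpha must lie strictly inside (0, 1)")
  alpha^n_substrates / (1 - alpha)^n_products
}

# minimum-norm least-squares solve via SVD
pinv_solve <- function(A, b, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 1e-300)
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

# steady-state net forward flux through each annotated reaction, from the
# source/sink vector: solve  Omega phi = -sources  (minimum norm)
reaction_fluxes <- function(model) {
  rx <- model$reactions
  if (length(rx) == 0) return(numeric(0))
  if (all(model$sources == 0)) return(numeric(length(rx)))
  Om <- sapply(rx, function(r) {
    w <- stats::setNames(numeric(length(model$species)), model$species)
    w[r$substrates] <- w[r$substrates] - 1
    w[r$products] <- w[r$products] + 1
    w
  })
  phi <- as.numeric(pinv_solve(Om, -model$sources))
  resid <- max(abs(Om %*% phi + model$sources))
  if (resid > 1e-8)
    stop("reaction_fluxes: sources are inconsistent with the reaction ",
         "stoichiometry (residual ", signif(resid, 3), "); no steady ",
         "throughput exists")
  phi
}

# forward/reverse rate constants (probability units) for every annotated
# reaction; corrected = TRUE balances against products of marginals (the
# mean-field fixed point), FALSE against joint-support probabilities
# (orthogonality to the joint steady state)
reaction_constants <- function(model, corrected = TRUE) {
  rx <- model$reactions
  if (length(rx) == 0)
    stop("reaction_constants: model carries no reaction annotation")
  pj <- joint_steady_state(model)$probs
  m <- model_marginals(model)
  phi <- reaction_fluxes(model)
  side_mass <- function(set) {
    if (corrected) prod(m[set]) else joint_presence_prob(model, set, pj)
  }
  out <- lapply(seq_along(rx), function(j) {
    r <- rx[[j]]
    ms <- side_mass(r$substrates); mp <- side_mass(r$products)
    if (ms <= 0 || mp <= 0)
      stop("reaction_constants: zero steady-state mass on a reaction side; ",
           "rate constants undefined")
    if (r$pinned == "substrate") {
      kf <- r$rate
      kr <- (kf * ms - phi[j]) / mp
    } else {
      kr <- r$rate
      kf <- (kr * mp + phi[j]) / ms
    }
    if (kf < -1e-12 || kr < -1e-12)
      stop("reaction_constants: negative rate constant (kf = ",
           signif(kf, 4), ", kr = ", signif(kr, 4), "); the source rate ",
           "exceeds what the steady state can sustain")
    list(kf = max(kf, 0), kr = max(kr, 0),
         substrates = r$substrates, products = r$products)
  })
  names(out) <- paste0("r", seq_along(out))
  out
}

#' Mean-field transition operator for one species
#'
#' Builds the marginal dynamics `dq1_i/dt = lambda_i * v . q`, where `v` is
#' a weighted sum of Kronecker indicator rows: each term is a coefficient
#' `beta` times the product of presence probabilities over a subset of
#' species. All subsets involve only the species itself and its Markov
#' blanket. With `corrected = FALSE` the coefficients are balanced against
#' the joint steady state, so `v . p_inf = 0` (exactly, up to arithmetic);
#' with `corrected = TRUE` they are solved at the steady-state marginals
#' instead, making the product of marginals the mean-field fixed point. A
#' constant term (`beta_1`) carries any non-equilibrium source/sink
#' throughput.
#'
#' @param model a `generative_model` with reaction annotations.
#' @param species the species whose operator to build.
#' @param lambda_i base rate; defaults to the model's per-species lambda.
#' @param nonequilibrium_const constant beta_1 term; defaults to the
#'   model's declared source/sink for this species.
#' @param corrected logical, see Details.
#' @return an object of class `meanfield_operator`: list with `species`,
#'   `lambda`, `beta0` (constant term) and `terms` (list of
#'   `list(beta, subset)`).
#' @export
build_operator <- function(model, species, lambda_i = NULL,
                           nonequilibrium_const = NULL, corrected = FALSE) {
  if (!species %in% model$species)
    stop("build_operator: unknown species '", species, "'")
  if (is.null(lambda_i)) lambda_i <- unname(model$lambda[species])
  if (is.null(nonequilibrium_const))
    nonequilibrium_const <- unname(model$sources[species])
  if (is.null(model$reactions))
    model$reactions <- infer_reactions(model)
  kc <- reaction_constants(model, corrected = corrected)
  terms <- list()
  for (r in kc) {
    s <- if (species %in% r$substrates) -1 else if (species %in% r$products)
      1 else 0
    if (s == 0) next
    terms <- c(terms,
               list(list(beta = s * r$kf, subset = r$substrates),
                    list(beta = -s * r$kr, subset = r$products)))
  }
  if (length(terms) == 0 && nonequilibrium_const == 0)
    stop("build_operator: species '", species, "' participates in no ",
         "reaction and has no source; its operator is empty")
  # coupling set: the Markov blanket plus reaction co-members. Deterministic
  # factors can make the information-theoretic blanket strictly smaller than
  # the set of species a reaction couples (a fully determined co-substrate
  # d-separates the rest), so the reaction partners are the operative bound.
  partners <- unlist(lapply(model$reactions, function(r)
    if (species %in% c(r$substrates, r$products))
      c(r$substrates, r$products)))
  bl <- unique(c(species, markov_blanket(model, species), partners))
  offenders <- unlist(lapply(terms, function(tm) setdiff(tm$subset, bl)))
  if (length(offenders))
    stop("build_operator: reaction annotation reaches outside the Markov ",
         "blanket/coupling set of '", species, "' (", paste(unique(offenders),
         collapse = ", "), "); the generative model and reactions disagree")
  structure(list(species = species, lambda = lambda_i,
                 beta0 = nonequilibrium_const, terms = terms),
            class = "meanfield_operator")
}

#' @export
print.meanfield_operator <- function(x, ...) {
  cat("<meanfield_operator for", x$species, "| lambda =", x$lambda, ">\n")
  cat("  dq1/dt = lambda * (", x$beta0,
      paste(vapply(x$terms, function(tm)
        sprintf("%+g*%s", tm$beta,
                paste0("q(", paste(tm$subset, collapse = ")q("), ")")),
        character(1)), collapse = " "), ")\n")
  invisible(x)
}

#' Orthogonality defect of an operator against the joint steady state
#'
#' Evaluates `v . p_inf` (the row vector of the operator applied to the
#' joint stationary distribution). Zero -- up to the declared
#' non-equilibrium constant -- is the construction constraint for
#' uncorrected operators.
#'
#' @param op a `meanfield_operator`.
#' @param model the generative model it was built from.
#' @return scalar `v . p_inf` (including the constant term).
#' @export
operator_orthogonality <- function(op, model) {
  pj <- joint_steady_state(model)$probs
  op$beta0 + sum(vapply(op$terms, function(tm)
    tm$beta * joint_presence_prob(model, tm$subset, pj), numeric(1)))
}

# detect the two-block reaction structure (prior with mass only on
# all-present / all-absent + deterministic complement conditional) in a
# model lacking an explicit annotation
infer_reactions <- function(model) {
  prior <- NULL; cond <- NULL
  for (f in model$factors) {
    tb <- f$table
    if (length(f$parents) == 0 && nrow(tb) >= 2 &&
        sum(tb > 1e-12) == 2 && tb[1, 1] > 0 && tb[nrow(tb), 1] > 0)
      prior <- f
    if (length(f$parents) > 0 && all(tb %in% c(0, 1)))
      cond <- f
  }
  if (is.null(prior) || is.null(cond))
    stop("build_operator: the model has no reaction annotation and no ",
         "recognizable two-block reaction structure; annotate reactions ",
         "with model_reaction()")
  list(model_reaction(prior$children, cond$children,
                      rate = unname(model$lambda[prior$children[1]]),
                      pinned = "substrate"))
}

#' Simulate coupled mean-field marginal dynamics
#'
#' Integrates `dq1_i/dt = lambda_i (beta0_i + sum_k beta_k prod_{j in S_k}
#' q1_j)` for all species jointly. Marginals are not clamped; the
#' integrator keeps them on the unit interval for well-posed models, and a
#' warning is raised if the conserved summed presence probability of the
#' initial condition is inconsistent with the target steady state (closed
#' models only reach the prescribed marginals from initial conditions with
#' the right total mass).
#'
#' @param operators list of `meanfield_operator` objects covering all
#'   species, or a `generative_model` (operators are then built with
#'   `corrected = TRUE`).
#' @param q0 named numeric vector of initial presence probabilities.
#' @param times output times.
#' @param model optional `generative_model` used to annotate the trajectory
#'   with the mean-field free energy `sum_i KL(q_i || m_i)` against the
#'   model marginals.
#' @return a `catflow_trajectory` whose columns are the presence
#'   probabilities `q1` of each species.
#' @export
meanfield_simulate <- function(operators, q0, times, model = NULL) {
  if (inherits(operators, "generative_model")) {
    model <- operators
    operators <- lapply(model$species, function(s)
      build_operator(model, s, corrected = TRUE))
  }
  sp <- vapply(operators, `[[`, character(1), "species")
  if (anyDuplicated(sp)) stop("meanfield_simulate: duplicate operators")
  if (!all(names(q0) %in% sp) || length(q0) != length(sp))
    stop("meanfield_simulate: q0 must name exactly the operated species")
  q0 <- q0[sp]
  if (any(q0 < -1e-12 | q0 > 1 + 1e-12))
    stop("meanfield_simulate: q0 entries must be probabilities in [0, 1]")
  if (!is.null(model) && length(model$reactions)) {
    # conserved combinations: left null vectors of the reaction
    # stoichiometry, restricted to source-free species
    m <- model_marginals(model)[sp]
    Om <- sapply(model$reactions, function(r) {
      w <- stats::setNames(numeric(length(sp)), sp)
      w[r$substrates] <- w[r$substrates] - 1
      w[r$products] <- w[r$products] + 1
      w
    })
    sv <- svd(t(Om), nu = 0, nv = length(sp))
    null_idx <- which(c(sv$d, rep(0, length(sp) - length(sv$d))) <
                        1e-10 * max(sv$d, 1))
    for (k in null_idx) {
      v <- sv$v[, k]
      if (any(abs(v[model$sources[sp] != 0]) > 1e-10)) next
      if (abs(sum(v * q0) - sum(v * m)) > 1e-6) {
        warning("meanfield_simulate: the initial condition's conserved ",
                "presence mass differs from the steady state's; a closed ",
                "system cannot reach the prescribed marginals from this ",
                "mass")
        break
      }
    }
  }
  rhs <- function(t, y) {
    names(y) <- sp
    vapply(operators, function(op) {
      op$lambda * (op$beta0 + sum(vapply(op$terms, function(tm)
        tm$beta * prod(y[tm$subset]), numeric(1))))
    }, numeric(1))
  }
  sol <- ode_integrate(as.numeric(q0), times, rhs)
  bad <- which(!is.finite(sol$states), arr.ind = TRUE)
  if (nrow(bad))
    stop("meanfield_simulate: non-finite dynamics for species ",
         paste(unique(sp[bad[, 2]]), collapse = ", "))
  fe <- NULL
  if (!is.null(model)) {
    m <- model_marginals(model)[sp]
    fe <- apply(sol$states, 1, function(q) {
      q <- pmin(pmax(q, 0), 1)
      sum(mapply(function(qi, mi)
        free_energy(c(qi, 1 - qi), c(mi, 1 - mi)), q, m))
    })
  }
  trajectory(sol$times, sol$states, free_energy = fe, labels = sp)
}
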