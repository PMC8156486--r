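#' Scale parameters linking probabilities to concentrations
#'
#' @param N maximum molecule count per species (molecules).
#' @param V reaction volume (arbitrary volume units).
#' @param lambda base rate (per unit time).
#' @return an object of class `scale_params`.
#' @export
scale_params <- function(N = 1, V = 1, lambda = 1) {
  stopifnot(N > 0, V > 0, lambda > 0)
  structure(list(N = N, V = V, lambda = lambda), class = "scale_params")
}

#' Map presence probabilities to concentrations and back
#'
#' Concentrations are `u_i = N q1_i / V`: the presence probability read as
#' the occupied fraction of `N` molecules, per unit volume. The mapping is
#' a bijection; `to_probability` inverts it exactly.
#'
#' @param q named vector of presence probabilities (each in `[0, 1]`).
#' @param scale a [scale_params()].
#' @return concentration vector (dimensionless multiples of `N/V`).
#' @examples
#' to_concentration(c(S = 0.25), scale_params(N = 2, V = 0.5))  # 1.0
#' @export
to_concentration <- function(q, scale = scale_params()) {
  if (any(q < -1e-12 | q > 1 + 1e-12))
    stop("to_concentration: probabilities must lie in [0, 1]")
  scale$N * q / scale$V
}

#' @rdname to_concentration
#' @param u concentration vector.
#' @export
to_probability <- function(u, scale = scale_params()) {
  scale$V * u / scale$N
}

#' Mass-action reaction
#'
#' A reversible reaction `sum_i sigma_i S_i <-> sum_i rho_i S_i` with
#' forward constant `kf` and reverse constant `kr`. Species with equal
#' stoichiometry on both sides (catalysts) are permitted: their net
#' coefficient is zero but they still enter the rate product.
#'
#' @param substrates named integer vector of substrate stoichiometries
#'   `sigma`.
#' @param products named integer vector of product stoichiometries `rho`.
#' @param kf,kr non-negative rate constants (units depend on molecularity).
#' @param id optional reaction identifier.
#' @return an object of class `mass_action_reaction`.
#' @examples
#' mass_action_reaction(c(S1 = 2), c(S3 = 1, S4 = 1), kf = 1, kr = 1)
#' @export
mass_action_reaction <- function(substrates, products, kf, kr = 0,
                                 id = NULL) {
  stopifnot(kf >= 0, kr >= 0, length(substrates) + length(products) >= 1)
  if ((length(substrates) && is.null(names(substrates))) ||
      (length(products) && is.null(names(products))))
    stop("mass_action_reaction: stoichiometries must be named by species")
  structure(list(substrates = substrates, products = products,
                 kf = kf, kr = kr, id = id), class = "mass_action_reaction")
}

rate_product <- function(u, stoich) {
  if (length(stoich) == 0) return(1)
  prod(u[names(stoich)]^stoich)
}

#' Mass-action right-hand side
#'
#' Evaluates `du_i/dt = sum_j (rho_ij - sigma_ij) (kf_j prod u^sigma_j -
#' kr_j prod u^rho_j)` for a list of reactions; equivalently `Omega r(u)`
#' with each directed rate `r_j = kappa_j prod_i u_i^sigma_ij`.
#'
#' @param u named non-negative concentration vector covering all species
#'   referenced by the reactions.
#' @param reactions list of [mass_action_reaction()] objects.
#' @return named vector of concentration time-derivatives.
#' @export
mass_action_rhs <- function(u, reactions) {
  if (any(u < -1e-6))
    stop("mass_action_rhs: negative concentrations")
  u <- pmax(u, 0)
  du <- stats::setNames(numeric(length(u)), names(u))
  for (r in reactions) {
    flux <- r$kf * rate_product(u, r$substrates) -
            r$kr * rate_product(u, r$products)
    for (s in names(r$substrates)) du[s] <- du[s] - r$substrates[s] * flux
    for (s in names(r$products))   du[s] <- du[s] + r$products[s] * flux
  }
  du
}

#' Closed-form rate constants for the coupled two-reaction network
#'
#' Rate constants, as functions of the generative-model parameters, for the
#' chain `S1 + S2 <-> S3 <-> S4 + S5` (see [coupled_reaction_model()]):
#' `kappa1 = lambda V/N * z * (alpha2 - alpha1) / (alpha1^2 alpha2)`,
#' `kappa2 = lambda z`, `kappa3 = lambda (1 - z)`,
#' `kappa4 = lambda V/N * (1 - z) * alpha2 (alpha2 - alpha1) /
#' (alpha1^2 (1 - alpha2)^2)`. The bimolecular constants carry the
#' mean-field correction (squared marginals in the denominators) and the
#' `V/N` factor that converts them to concentration units.
#'
#' @param alpha1,alpha2 model parameters with `0 < alpha1 < alpha2 < 1`.
#' @param z rate split in (0, 1).
#' @param scale a [scale_params()].
#' @return named vector `c(kappa1, kappa2, kappa3, kappa4)`, all
#'   non-negative.
#' @examples
#' table1_constants(0.2, 0.5, 0.5)  # 7.5, 0.5, 0.5, 7.5
#' @export
table1_constants <- function(alpha1, alpha2, z, scale = scale_params()) {
  stopifnot(alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1, z > 0, z < 1)
  if (alpha2 < alpha1)
    stop("table1_constants: alpha2 >= alpha1 required for non-negative ",
         "constants (the alpha2 - alpha1 factor)")
  lam <- scale$lambda; f <- scale$V / scale$N
  c(kappa1 = lam * f * z * (alpha2 - alpha1) / (alpha1^2 * alpha2),
    kappa2 = lam * z,
    kappa3 = lam * (1 - z),
    kappa4 = lam * f * (1 - z) * alpha2 * (alpha2 - alpha1) /
      (alpha1^2 * (1 - alpha2)^2))
}

#' Enzymatic reaction system
#'
#' Bundles the generative-model parameters of an enzymatic reaction
#' `S + E <-> C <-> P + E` with its scale, throughput `c` and the derived
#' rate constants (see [table2_constants()]).
#'
#' @param alpha1,alpha2 model parameters in (0, 1).
#' @param z rate split in (0, 1).
#' @param c throughput (concentration per unit time); must satisfy
#'   `c <= (1 - z)(1 - alpha1)` (in probability units) for non-negative
#'   constants.
#' @param scale a [scale_params()].
#' @return an object of class `enzymatic_system` with elements `alpha1`,
#'   `alpha2`, `z`, `c`, `scale`, `kappa` (the four constants) and `model`
#'   (the underlying [enzymatic_model()]).
#' @export
enzymatic_system <- function(alpha1, alpha2, z, c = 0,
                             scale = scale_params()) {
  model <- enzymatic_model(alpha1, alpha2, z = z, c = c,
                           lambda = scale$lambda)
  sys <- structure(list(alpha1 = alpha1, alpha2 = alpha2, z = z, c = c,
                        scale = scale, model = model),
                   class = "enzymatic_system")
  sys$kappa <- table2_constants(sys)
  sys
}

#' Closed-form rate constants for an enzymatic reaction
#'
#' `kappa1 = lambda V/N (z - alpha1 z + c) / (alpha1^2 alpha2)` (binding),
#' `kappa2 = lambda z` (unbinding), `kappa3 = lambda (1 - z)` (catalysis),
#' `kappa4 = lambda V/N ((1 - z)(1 - alpha1) - c) / (alpha1^2 (1 -
#' alpha2))` (reverse catalysis). Non-negativity of `kappa4` is exactly the
#' throughput bound `c <= (1 - z)(1 - alpha1)`.
#'
#' @param system an [enzymatic_system()].
#' @return named vector `c(kappa1, kappa2, kappa3, kappa4)`.
#' @examples
#' table2_constants(enzymatic_system(0.5, 0.5, z = 0.5))  # 2, .5, .5, 2
#' @export
table2_constants <- function(system) {
  a1 <- system$alpha1; a2 <- system$alpha2; z <- system$z; cc <- system$c
  if (cc > (1 - z) * (1 - a1) + 1e-12)
    stop("table2_constants: c exceeds (1 - z)(1 - alpha1); kappa4 would ",
         "be negative")
  lam <- system$scale$lambda; f <- system$scale$V / system$scale$N
  c(kappa1 = lam * f * (z - a1 * z + cc) / (a1^2 * a2),
    kappa2 = lam * z,
    kappa3 = lam * (1 - z),
    kappa4 = lam * f * ((1 - z) * (1 - a1) - cc) / (a1^2 * (1 - a2)))
}

#' Right-hand side of the open enzymatic system
#'
#' Mass-action dynamics of the four reactions (bind, unbind, catalyze,
#' reverse catalyze) plus a constant source `+c` on the substrate and sink
#' `-c` on the product. The sink is clipped when the product concentration
#' has been exhausted so concentrations cannot be driven negative. The
#' reaction terms leave the enzyme moiety `u_E + u_C` exactly invariant.
#'
#' @param u named vector `c(S, E, C, P)` of concentrations.
#' @param kappa the four rate constants (named as from
#'   [table2_constants()]).
#' @param c throughput.
#' @return named derivative vector.
#' @export
enzymatic_rhs <- function(u, kappa, c = 0) {
  # tolerate integrator-scale undershoot; reject genuinely negative input
  if (any(u < -1e-6)) stop("enzymatic_rhs: negative concentrations")
  u <- pmax(u, 0)
  bind <- kappa[["kappa1"]] * u[["S"]] * u[["E"]] -
          kappa[["kappa2"]] * u[["C"]]
  cat_ <- kappa[["kappa3"]] * u[["C"]] -
          kappa[["kappa4"]] * u[["P"]] * u[["E"]]
  # sink ramps linearly below a small threshold so an empty product pool is
  # not driven negative (and cannot absorb all production in a spurious
  # pinned state); above the threshold the efflux is exactly c
  sink <- c * min(1, max(u[["P"]], 0) / 1e-9)
  c(S = -bind + c, E = -bind + cat_, C = bind - cat_, P = cat_ - sink)
}

#' Simulate an enzymatic system
#'
#' @param system an [enzymatic_system()].
#' @param u0 named initial concentrations `c(S, E, C, P)`.
#' @param times output times.
#' @return a `catflow_trajectory` with columns `S, E, C, P`.
#' @export
simulate_enzymatic <- function(system, u0, times) {
  u0 <- u0[c("S", "E", "C", "P")]
  sol <- ode_integrate(as.numeric(u0), times, function(t, y) {
    names(y) <- c("S", "E", "C", "P")
    enzymatic_rhs(y, system$kappa, system$c)
  })
  trajectory(sol$times, sol$states, labels = c("S", "E", "C", "P"))
}

#' Michaelis--Menten reduction of an enzymatic system
#'
#' Under a separation of timescales -- binding and unbinding much faster
#' than catalysis, i.e. `z` close to 1, with the reverse catalytic flux
#' negligible (throughput `c` close to its bound) -- the complex
#' equilibrates at `u_C = e_T u_S / (kappa_m + u_S)` with
#' `kappa_m = kappa2 / kappa1` and total enzyme `e_T = u_E + u_C`. The
#' product formation rate then follows the saturating law
#' `r(u_S) = v_max u_S / (kappa_m + u_S)` with `v_max = kappa3 e_T`, the
#' constant that reproduces the full system's quasi-equilibrium catalytic
#' flux `kappa3 u_C`. (Some treatments scale `v_max` by the binding
#' constant as well; that convention is not self-consistent with the
#' quasi-equilibrium complex and is not used here.)
#'
#' @param system an [enzymatic_system()].
#' @param enzyme_total total enzyme concentration `e_T = u_E + u_C`.
#' @return an object of class `michaelis_menten` with `v_max` and
#'   `kappa_m`. A warning is raised when the separation conditions are
#'   grossly violated (`kappa3 >= kappa2`); the approximation degrades
#'   continuously rather than failing.
#' @export
mm_reduce <- function(system, enzyme_total) {
  k <- system$kappa
  if (k[["kappa3"]] >= k[["kappa2"]])
    warning("mm_reduce: catalysis is not slower than unbinding ",
            "(kappa3 >= kappa2); the quasi-equilibrium reduction is ",
            "unreliable here")
  michaelis_menten(v_max = unname(k[["kappa3"]] * enzyme_total),
                   kappa_m = unname(k[["kappa2"]] / k[["kappa1"]]))
}

#' Michaelis--Menten reaction
#'
#' @param v_max maximal rate (concentration per unit time), `>= 0`.
#' @param kappa_m half-saturation concentration, `> 0`.
#' @param substrate,product optional species names (used in networks).
#' @param id optional reaction identifier.
#' @return an object of class `michaelis_menten`.
#' @export
michaelis_menten <- function(v_max, kappa_m, substrate = "S",
                             product = "P", id = NULL) {
  stopifnot(v_max >= 0, kappa_m > 0)
  structure(list(v_max = v_max, kappa_m = kappa_m, substrate = substrate,
                 product = product, id = id), class = "michaelis_menten")
}

#' @export
print.michaelis_menten <- function(x, ...) {
  cat("<michaelis_menten ", x$substrate, " -> ", x$product,
      ": v_max = ", signif(x$v_max, 6), ", kappa_m = ",
      signif(x$kappa_m, 6), ">\n", sep = "")
  invisible(x)
}

#' Saturating reaction rate
#'
#' `r(u_S) = v_max u_S / (kappa_m + u_S)`: half of `v_max` at
#' `u_S = kappa_m`, zero at zero, saturating at `v_max`.
#'
#' @param reaction a [michaelis_menten()] reaction.
#' @param u_S substrate concentration(s).
#' @return rate(s).
#' @export
mm_rate <- function(reaction, u_S) {
  reaction$v_max * u_S / (reaction$kappa_m + u_S)
}

#' Simulate the reduced (Michaelis--Menten) enzymatic system
#'
#' Two-species dynamics `du_S = c - r(u_S)`, `du_P = r(u_S) - c` with the
#' saturating rate from [mm_rate()]; the enzyme species are absorbed into
#' `v_max`.
#'
#' @param reaction a [michaelis_menten()] reaction.
#' @param u0 named initial concentrations `c(S, P)`.
#' @param times output times.
#' @param c throughput.
#' @return a `catflow_trajectory` with columns `S, P`.
#' @export
simulate_mm <- function(reaction, u0, times, c = 0) {
  sol <- ode_integrate(as.numeric(u0[c("S", "P")]), times, function(t, y) {
    r <- mm_rate(reaction, y[1])
    sink <- c * min(1, max(y[2], 0) / 1e-9)
    c(c - r, r - sink)
  })
  trajectory(sol$times, sol$states, labels = c("S", "P"))
}
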