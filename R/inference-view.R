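#' Implicit beliefs encoded by substrate and product concentrations
#'
#' In an enzymatic system the substrate and product are conditionally
#' independent given the enzyme/complex state, and their presence
#' probabilities sum to a model constant at steady state. Each side's
#' concentration can therefore be read as an implicit belief about the
#' other side: `q~_S = offset - q_P` and `q~_P = offset - q_S`, where
#' `offset` is the steady-state total presence probability of substrate
#' plus product (for [enzymatic_model()] this equals the free-enzyme
#' parameter `alpha1`). As the system attains steady state both beliefs
#' converge onto the corresponding marginals. Values are clipped to
#' `[0, 1]` with a warning: the linear relations can transiently exit the
#' unit interval under mean-field error.
#'
#' @param q_S,q_P current presence probabilities of substrate and product.
#' @param alpha2 the belief offset (see Details).
#' @return an object of class `implicit_belief`: list with `q_S_belief`
#'   (the substrate presence believed by the product side... the belief
#'   *about* the substrate), `q_P_belief`, `alpha2`, `clipped`.
#' @examples
#' implicit_beliefs(q_S = 0.1, q_P = 0.05, alpha2 = 0.2)
#' @export
implicit_beliefs <- function(q_S, q_P, alpha2) {
  stopifnot(q_S >= 0, q_S <= 1, q_P >= 0, q_P <= 1,
            alpha2 > 0, alpha2 < 1)
  bS <- alpha2 - q_P
  bP <- alpha2 - q_S
  clipped <- bS < 0 | bS > 1 | bP < 0 | bP > 1
  if (any(clipped))
    warning("implicit_beliefs: belief outside [0, 1] clipped ",
            "(transient mean-field excursion)")
  structure(list(q_S_belief = pmin(pmax(bS, 0), 1),
                 q_P_belief = pmin(pmax(bP, 0), 1),
                 alpha2 = alpha2, clipped = clipped),
            class = "implicit_belief")
}

#' Belief free energies along an enzymatic trajectory
#'
#' Each side of the reaction encodes a belief about the other: the product
#' concentration carries the belief `q~_S = offset - q_P` about the
#' substrate, and vice versa. For each time point this function
#' renormalizes the belief by the free-enzyme probability (conditioned on
#' the complex both species are absent with certainty, so that state is
#' excluded by the renormalization) and scores it against the model's
#' conditional distribution of the species given the free enzyme:
#' `product_side(t) = KL(b_S(t) || P(S | enzyme free))` with
#' `b_S = clip(q~_S) / q_E`, and symmetrically for `substrate_side`. Both
#' series vanish at the model steady state. The enzyme here plays the role
#' of the data: when binding is much faster than catalysis the free-enzyme
#' probability collapses before the belief-carrying concentrations can
#' adjust, which transiently *raises* the product-side series (a prediction
#' error) before it is suppressed. The averaging convention is one of
#' several consistent readings; only its qualitative behaviour should be
#' relied upon.
#'
#' @param traj a `catflow_trajectory` with columns `S, E, C, P` in
#'   probability units.
#' @param model the [enzymatic_model()] (or `enzymatic_system`) that
#'   generated it.
#' @return data frame with columns `time`, `substrate_side` (free energy of
#'   the belief held by the substrate, about the product) and
#'   `product_side` (belief held by the product, about the substrate), in
#'   nats.
#' @export
belief_free_energy <- function(traj, model) {
  if (inherits(model, "enzymatic_system")) model <- model$model
  st <- traj$states
  need <- c("S", "E", "C", "P")
  if (is.null(colnames(st)) || !all(need %in% colnames(st)))
    stop("belief_free_energy: trajectory must cover species S, E, C, P")
  m <- model_marginals(model)
  offset <- unname(m[["S"]] + m[["P"]])
  # conditional steady states given the free enzyme
  pS_E <- unname(m[["S"]] / m[["E"]])
  pP_E <- unname(m[["P"]] / m[["E"]])
  kl2 <- function(b, p) {
    b <- min(max(b, 1e-12), 1 - 1e-12)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    b * log(b / p) + (1 - b) * log((1 - b) / (1 - p))
  }
  one_side <- function(belief, qE, target) {
    b <- min(max(belief, 0), 1) / max(qE, 1e-12)
    kl2(min(max(b, 0), 1), target)
  }
  n <- nrow(st)
  fS <- fP <- numeric(n)
  for (i in seq_len(n)) {
    qS <- min(max(st[i, "S"], 0), 1); qP <- min(max(st[i, "P"], 0), 1)
    qE <- min(max(st[i, "E"], 0), 1)
    fS[i] <- one_side(offset - qS, qE, pP_E)  # substrate's belief about P
    fP[i] <- one_side(offset - qP, qE, pS_E)  # product's belief about S
  }
  data.frame(time = traj$times, substrate_side = fS, product_side = fP)
}
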