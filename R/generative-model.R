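#' Conditional probability factor over binary species
#'
#' One factor of a factorized steady-state (generative) model. The children
#' form a joint block of binary species (state order: present before absent,
#' leftmost child varying slowest); the table holds one normalized column of
#' categorical parameters per parent configuration (same ordering convention
#' for the parents).
#'
#' @param children character vector of child species names (the block).
#' @param parents character vector of parent species names (may be empty).
#' @param table numeric matrix `2^length(children)` x `2^length(parents)`
#'   with columns summing to 1; a vector is accepted when there are no
#'   parents.
#' @return an object of class `cond_factor`.
#' @export
cond_factor <- function(children, parents = character(0), table) {
  table <- as.matrix(table)
  nr <- 2^length(children); nc <- 2^length(parents)
  if (nrow(table) != nr || ncol(table) != nc)
    stop("cond_factor: table must be ", nr, " x ", nc, " for ",
         length(children), " children and ", length(parents), " parents")
  if (any(table < -1e-12) || any(table > 1 + 1e-12))
    stop("cond_factor: entries must lie in [0, 1]")
  if (any(abs(colSums(table) - 1) > 1e-9))
    stop("cond_factor: every column must sum to 1")
  structure(list(children = children, parents = parents, table = table),
            class = "cond_factor")
}

#' Generative model over binary chemical species
#'
#' A set of binary species (index 1 = present, index 2 = absent) and
#' conditional factors whose product defines the joint steady-state
#' distribution. Every species must appear as a child in exactly one factor
#' and the parent-to-child graph must be acyclic. Optionally the model
#' carries a reaction annotation (see [model_reaction()]) describing which
#' species blocks interconvert; this is what the kinetic compilation uses.
#'
#' @param species character vector of unique species names. Kronecker
#'   ordering convention: species as declared, leftmost varying slowest in
#'   the joint index.
#' @param factors list of [cond_factor()] objects.
#' @param reactions optional list of [model_reaction()] annotations.
#' @param lambda base rate per species (per unit time); scalar or named
#'   vector. Sets only the time scale.
#' @param sources named numeric vector of constant source (+) / sink (-)
#'   probability throughput per unit time, for non-equilibrium steady
#'   states; default none.
#' @return an object of class `generative_model`.
#' @export
generative_model <- function(species, factors, reactions = NULL,
                             lambda = 1, sources = NULL) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("generative_model: duplicate species names")
  child_of <- unlist(lapply(factors, `[[`, "children"))
  if (anyDuplicated(child_of) ||
      !setequal(child_of, species))
    stop("generative_model: every species must appear as a child in ",
         "exactly one factor")
  for (f in factors)
    if (!all(f$parents %in% species))
      stop("generative_model: unknown parent species ",
           paste(setdiff(f$parents, species), collapse = ", "))
  # acyclicity of the parent -> child graph (topological elimination)
  owner <- function(sp) which(vapply(factors, function(f) sp %in% f$children,
                                     logical(1)))
  deps <- lapply(factors, function(f) unique(vapply(f$parents, owner, 1L)))
  done <- rep(FALSE, length(factors))
  repeat {
    ready <- which(!done & vapply(seq_along(factors), function(i)
      all(done[deps[[i]]] | deps[[i]] == i), logical(1)))
    ready <- ready[vapply(ready, function(i) !any(deps[[i]] == i), logical(1))]
    if (length(ready) == 0) break
    done[ready] <- TRUE
  }
  if (!all(done))
    stop("generative_model: the factor graph is cyclic in the ",
         "parent-to-child direction")
  if (length(lambda) == 1) lambda <- stats::setNames(rep(lambda,
    length(species)), species)
  src <- stats::setNames(numeric(length(species)), species)
  if (!is.null(sources)) {
    if (!all(names(sources) %in% species))
      stop("generative_model: source/sink attached to unknown species")
    src[names(sources)] <- sources
  }
  structure(list(species = species, factors = factors,
                 reactions = reactions, lambda = lambda, sources = src),
            class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model:", length(x$species), "binary species,",
      length(x$factors), "factors,",
      length(x$reactions %||% list()), "reactions>\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reaction annotation on a generative model
#'
#' Declares that one block of species interconverts with another
#' (substrates to the left, products to the right), together with the base
#' rate of the reaction and which side's rate constant is pinned to it (the
#' opposite side's constant is then solved from the model's steady state --
#' this is how rate constants become functions of the model parameters).
#'
#' @param substrates,products character vectors of species names.
#' @param rate pinned rate constant (per unit time), e.g. `lambda * z`.
#' @param pinned `"substrate"` or `"product"`: the side whose constant
#'   equals `rate`.
#' @return an object of class `model_reaction`.
#' @export
model_reaction <- function(substrates, products, rate = 1,
                           pinned = c("substrate", "product")) {
  pinned <- match.arg(pinned)
  stopifnot(length(substrates) >= 1, length(products) >= 1, rate >= 0)
  structure(list(substrates = substrates, products = products,
                 rate = rate, pinned = pinned), class = "model_reaction")
}

# enumerate joint states: row k gives each species' state (1 present,
# 2 absent), species 1 varying slowest
joint_states <- function(n) {
  idx <- as.matrix(expand.grid(rep(list(1:2), n))[, n:1, drop = FALSE])
  colnames(idx) <- NULL
  idx[order(apply(idx, 1, function(r) sum((r - 1) * 2^((n - 1):0)))), ,
      drop = FALSE]
}

block_index <- function(states_row) {
  # joint index of a block configuration, leftmost slowest
  n <- length(states_row)
  sum((states_row - 1) * 2^((n - 1):0)) + 1
}

#' Joint steady state implied by a generative model
#'
#' Multiplies the conditional factors over all `2^n` joint configurations
#' (Kronecker ordering: declared species order, leftmost slowest) to obtain
#' the prescribed stationary distribution.
#'
#' @param model a `generative_model`.
#' @return a `catdist` over the joint states, labelled like
#'   `"S1+S2-"` (present `+`, absent `-`).
#' @export
joint_steady_state <- function(model) {
  n <- length(model$species)
  grid <- joint_states(n)
  p <- apply(grid, 1, function(cfg) {
    names(cfg) <- model$species
    prod(vapply(model$factors, function(f) {
      ci <- block_index(cfg[f$children])
      pi <- if (length(f$parents)) block_index(cfg[f$parents]) else 1L
      f$table[ci, pi]
    }, numeric(1)))
  })
  labs <- apply(grid, 1, function(cfg)
    paste0(model$species, c("+", "-")[cfg], collapse = ""))
  catdist(p, labels = labs)
}

#' Steady-state marginal presence probabilities
#'
#' @param model a `generative_model`.
#' @return named vector of `P(species present)` under the joint steady
#'   state.
#' @export
model_marginals <- function(model) {
  p <- joint_steady_state(model)$probs
  grid <- joint_states(length(model$species))
  stats::setNames(
    vapply(seq_along(model$species),
           function(i) sum(p[grid[, i] == 1]), numeric(1)),
    model$species)
}

# P(all species in `set` simultaneously present) under the joint
joint_presence_prob <- function(model, set, p = NULL) {
  if (length(set) == 0) return(1)
  if (is.null(p)) p <- joint_steady_state(model)$probs
  grid <- joint_states(length(model$species))
  cols <- match(set, model$species)
  sum(p[rowSums(grid[, cols, drop = FALSE] == 1) == length(cols)])
}

#' Markov blanket of a species
#'
#' The minimal set rendering all other variables conditionally independent
#' of the given species under the factorized steady state: the union of its
#' factor co-children, its parents, its children (species whose factor it
#' parents), and those children's co-parents, minus the species itself.
#'
#' @param model a `generative_model`.
#' @param species a species name.
#' @return character vector of blanket species.
#' @export
markov_blanket <- function(model, species) {
  if (!species %in% model$species)
    stop("markov_blanket: unknown species '", species, "'")
  out <- character(0)
  for (f in model$factors) {
    if (species %in% f$children)
      out <- c(out, f$children, f$parents)
    if (species %in% f$parents)
      out <- c(out, f$children, f$parents)
  }
  setdiff(unique(out), species)
}
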