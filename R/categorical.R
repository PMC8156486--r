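#' Categorical distribution over a finite state space
#'
#' A light container for a probability vector with named states. Entries must
#' be non-negative and sum to one (within `1e-9`) unless `normalized = FALSE`,
#' which permits vectors that have left the probability simplex -- needed for
#' purely solenoidal trajectories, which conserve a quadratic free-energy
#' functional but not simplex membership.
#'
#' @param probs numeric vector of probabilities (dimensionless).
#' @param labels optional character vector of state names; defaults to
#'   `s1, s2, ...`.
#' @param normalized logical; if `TRUE` (default) the simplex invariants are
#'   enforced.
#' @return an object of class `catdist`.
#' @examples
#' catdist(c(0.25, 0.75), c("present", "absent"))
#' @export
catdist <- function(probs, labels = NULL, normalized = TRUE) {
  probs <- as.numeric(probs)
  if (is.null(labels)) labels <- paste0("s", seq_along(probs))
  stopifnot(length(labels) == length(probs))
  if (normalized) {
    if (any(probs < -1e-9))
      stop("catdist: negative probability entries")
    if (abs(sum(probs) - 1) > 1e-9)
      stop("catdist: probabilities must sum to 1 (got ", sum(probs), ")")
    probs <- pmax(probs, 0)
    probs <- probs / sum(probs)
  }
  structure(list(probs = probs, labels = as.character(labels),
                 normalized = normalized),
            class = "catdist")
}

#' @export
print.catdist <- function(x, ...) {
  cat("<catdist over", length(x$probs), "states",
      if (!x$normalized) "(unnormalized)", ">\n")
  print(stats::setNames(x$probs, x$labels))
  invisible(x)
}

#' @export
length.catdist <- function(x) length(x$probs)

as_catdist <- function(x, labels = NULL, normalized = TRUE) {
  if (inherits(x, "catdist")) return(x)
  catdist(x, labels = labels, normalized = normalized)
}

#' Variational free energy of a categorical distribution
#'
#' Evaluates `F(p) = sum_i p_i (log p_i - log pinf_i) + z_inf` in nats, with
#' the convention `0 * log 0 = 0`. With `z_inf = 0` (the default, appropriate
#' for closed systems) this is the Kullback--Leibler divergence from `p` to
#' the steady state `pinf`: non-negative, and zero exactly when `p = pinf`.
#' Callers modelling open systems may supply a constant log-evidence offset
#' `z_inf`.
#'
#' @param p current distribution (`catdist` or numeric vector).
#' @param p_inf steady-state distribution.
#' @param z_inf scalar log-evidence constant (nats), default 0.
#' @return scalar free energy in nats.
#' @examples
#' free_energy(c(1, 0), c(0.5, 0.5))  # log 2
#' @export
free_energy <- function(p, p_inf, z_inf = 0) {
  p <- if (inherits(p, "catdist")) p$probs else as.numeric(p)
  q <- if (inherits(p_inf, "catdist")) p_inf$probs else as.numeric(p_inf)
  stopifnot(length(p) == length(q))
  bad <- p > 1e-12 & q <= 0
  if (any(bad))
    stop("free_energy: p has mass on states where p_inf is zero; ",
         "the divergence is infinite (states: ",
         paste(which(bad), collapse = ", "), ")")
  on <- p > 0 & q > 0
  sum(p[on] * (log(p[on]) - log(q[on]))) + z_inf
}
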