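#' Two-block reversible reaction model
#'
#' The canonical generative model for a reversible reaction in which a
#' block of substrate species interconverts with a block of product
#' species: the substrate block is jointly present with probability
#' `alpha` and jointly absent otherwise, and the products are the
#' deterministic complement of the substrates. With two substrates and two
#' products this is the textbook bimolecular case whose corrected
#' equilibrium constant is `alpha^2 / (1 - alpha)^2`.
#'
#' @param alpha steady-state presence probability of the substrate block,
#'   in (0, 1).
#' @param n_substrates,n_products block sizes.
#' @param lambda base reaction rate (per unit time).
#' @param species optional names; defaults to `S1, S2, ...`.
#' @return a `generative_model` with one reaction annotation.
#' @examples
#' m <- reaction_model(alpha = 1/4)
#' model_marginals(m)
#' @export
reaction_model <- function(alpha, n_substrates = 2, n_products = 2,
                           lambda = 1, species = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_substrates >= 1, n_products >= 1)
  n <- n_substrates + n_products
  if (is.null(species)) species <- paste0("S", seq_len(n))
  subs <- species[seq_len(n_substrates)]
  prods <- species[n_substrates + seq_len(n_products)]
  prior <- numeric(2^n_substrates)
  prior[1] <- alpha                      # all substrates present
  prior[length(prior)] <- 1 - alpha      # all substrates absent
  # products are the complement of the conditioning substrate
  tb <- matrix(0, 2^n_products, 2)
  tb[2^n_products, 1] <- 1               # substrate present -> products absent
  tb[1, 2] <- 1                          # substrate absent  -> products present
  generative_model(
    species,
    factors = list(
      cond_factor(subs, table = matrix(prior, ncol = 1)),
      cond_factor(prods, parents = subs[n_substrates], table = tb)),
    reactions = list(model_reaction(subs, prods, rate = lambda,
                                    pinned = "substrate")),
    lambda = lambda)
}

#' Two coupled reversible reactions sharing an intermediate
#'
#' A five-species model for the chain `S1 + S2 <-> S3 <-> S4 + S5`. The
#' steady state places mass `alpha1` on the substrate pair, and splits the
#' remainder between the intermediate and the product pair so that the
#' intermediate's marginal is `(alpha2 - alpha1)/alpha2`. Mass is conserved
#' in the sense that the marginal of S1 (or S2), plus the marginal of S3,
#' plus the marginal of S4 (or S5) equals one. The free parameter `z`
#' splits the base rate between the two reactions: the first reaction's
#' reverse constant is pinned at `lambda * z` and the second reaction's
#' forward constant at `lambda * (1 - z)`; the remaining two constants are
#' solved from the steady state (see [table1_constants()] for their closed
#' forms).
#'
#' @param alpha1 presence probability of the substrate pair, in (0, 1).
#' @param alpha2 partition parameter, must satisfy `alpha2 > alpha1`.
#' @param z rate split in (0, 1).
#' @param lambda base rate.
#' @return a `generative_model` with two reaction annotations.
#' @export
coupled_reaction_model <- function(alpha1, alpha2, z = 0.5, lambda = 1) {
  stopifnot(alpha1 > 0, alpha1 < 1, alpha2 > alpha1, alpha2 < 1,
            z > 0, z < 1)
  x <- (alpha2 - alpha1) / alpha2        # marginal of the intermediate
  sp <- paste0("S", 1:5)
  f1 <- cond_factor(c("S1", "S2"),
                    table = matrix(c(alpha1, 0, 0, 1 - alpha1), ncol = 1))
  # S3 given S2: absent when the substrates are present, else present with
  # probability x / (1 - alpha1)
  f2 <- cond_factor("S3", parents = "S2",
                    table = cbind(c(0, 1),
                                  c(x / (1 - alpha1), 1 - x / (1 - alpha1))))
  # S4, S5 given (S2, S3): jointly present only when both are absent
  f3 <- cond_factor(c("S4", "S5"), parents = c("S2", "S3"),
                    table = cbind(c(0, 0, 0, 1),   # S2+, S3+ (off support)
                                  c(0, 0, 0, 1),   # S2+, S3-
                                  c(0, 0, 0, 1),   # S2-, S3+
                                  c(1, 0, 0, 0)))  # S2-, S3-
  generative_model(
    sp, factors = list(f1, f2, f3),
    reactions = list(
      model_reaction(c("S1", "S2"), "S3", rate = lambda * z,
                     pinned = "product"),
      model_reaction("S3", c("S4", "S5"), rate = lambda * (1 - z),
                     pinned = "substrate")),
    lambda = lambda)
}

#' Enzymatic reaction model with non-equilibrium throughput
#'
#' A four-species generative model for `S + E <-> C <-> P + E` (substrate,
#' enzyme, complex, product). The enzyme and complex are mutually
#' exclusive: the free enzyme's steady-state marginal is `alpha1` and the
#' complex's `1 - alpha1`. Conditioned on the free enzyme, the substrate is
#' present with probability `alpha2` and the product with `1 - alpha2`;
#' conditioned on the complex both are absent. A constant source `c` feeds
#' the substrate and an equal sink drains the product, so the steady state
#' is maintained away from equilibrium (detailed balance is broken);
#' non-negativity of the solved rate constants requires
#' `c <= (1 - z)(1 - alpha1)`. The resulting constants are the closed
#' forms in [table2_constants()].
#'
#' @param alpha1 free-enzyme marginal, in (0, 1).
#' @param alpha2 substrate share of the enzyme-free state, in (0, 1).
#' @param z rate split in (0, 1): binding reverse constant pinned at
#'   `lambda * z`, catalysis forward at `lambda * (1 - z)`.
#' @param c constant throughput (probability mass per unit time).
#' @param lambda base rate.
#' @return a `generative_model` with two reaction annotations and
#'   source/sink terms.
#' @export
enzymatic_model <- function(alpha1, alpha2, z = 0.5, c = 0, lambda = 1) {
  stopifnot(alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1,
            z > 0, z < 1, c >= 0)
  if (c > (1 - z) * (1 - alpha1) + 1e-12)
    stop("enzymatic_model: c must not exceed (1 - z)(1 - alpha1) = ",
         signif((1 - z) * (1 - alpha1), 4),
         "; larger throughput makes a rate constant negative")
  # joint block (C, E): complex and enzyme mutually exclusive
  f1 <- cond_factor(c("C", "E"),
                    table = matrix(c(0, 1 - alpha1, alpha1, 0), ncol = 1))
  # S | (C, E): columns over (C+, E+), (C+, E-), (C-, E+), (C-, E-)
  f2 <- cond_factor("S", parents = c("C", "E"),
                    table = cbind(c(0, 1), c(0, 1),
                                  c(alpha2, 1 - alpha2), c(0, 1)))
  f3 <- cond_factor("P", parents = c("C", "E"),
                    table = cbind(c(0, 1), c(0, 1),
                                  c(1 - alpha2, alpha2), c(0, 1)))
  generative_model(
    c("S", "E", "C", "P"),
    factors = list(f1, f2, f3),
    reactions = list(
      model_reaction(c("S", "E"), "C", rate = lambda * z,
                     pinned = "product"),
      model_reaction("C", c("P", "E"), rate = lambda * (1 - z),
                     pinned = "substrate")),
    lambda = lambda,
    sources = c(S = c, P = -c))
}
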