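test_that("joint steady state multiplies the factors", {
  m <- reaction_model(alpha = 1/4)
  js <- joint_steady_state(m)
  on <- js$probs > 0
  expect_equal(sum(on), 2)
  expect_equal(unname(js$probs[js$labels == "S1+S2+S3-S4-"]), 1/4)
  expect_equal(unname(js$probs[js$labels == "S1-S2-S3+S4+"]), 3/4)
  expect_equal(model_marginals(m),
               c(S1 = 0.25, S2 = 0.25, S3 = 0.75, S4 = 0.75))

  # single unconditioned factor: the joint is its table
  tb <- c(0.1, 0.2, 0.3, 0.4)
  solo <- generative_model(c("A", "B"), list(
    cond_factor(c("A", "B"), table = matrix(tb, ncol = 1))))
  expect_equal(joint_steady_state(solo)$probs, tb)

  # enzymatic model: complex and enzyme never simultaneously present
  em <- enzymatic_model(0.3, 0.6)
  js <- joint_steady_state(em)
  grid <- catflow:::joint_states(4)
  both <- grid[, match("C", em$species)] == 1 &
          grid[, match("E", em$species)] == 1
  expect_equal(sum(js$probs[both]), 0)
})

test_that("model validation catches structural errors", {
  f <- function(...) cond_factor(...)
  expect_error(generative_model(c("A", "B"), list(
    f("A", table = matrix(c(.5, .5), ncol = 1)))), "exactly one factor")
  expect_error(generative_model(c("A", "B"), list(
    f("A", parents = "B", table = cbind(c(.5, .5), c(.2, .8))),
    f("B", parents = "A", table = cbind(c(.5, .5), c(.2, .8))))),
    "cyclic")
  expect_error(cond_factor("A", table = matrix(c(0.7, 0.7), ncol = 1)),
               "sum to 1")
})

test_that("Markov blankets follow the factor graph", {
  em <- enzymatic_model(0.3, 0.6)
  expect_setequal(markov_blanket(em, "S"), c("C", "E"))
  expect_setequal(markov_blanket(em, "P"), c("C", "E"))

  solo <- generative_model(c("A", "B", "C"), list(
    cond_factor(c("A", "B", "C"),
                table = matrix(rep(1/8, 8), ncol = 1))))
  expect_setequal(markov_blanket(solo, "B"), c("A", "C"))

  chain <- generative_model(c("A", "B", "C"), list(
    cond_factor("A", table = matrix(c(.3, .7), ncol = 1)),
    cond_factor("B", parents = "A", table = cbind(c(.8, .2), c(.1, .9))),
    cond_factor("C", parents = "B", table = cbind(c(.6, .4), c(.2, .8)))))
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  # brute-force conditional-independence oracle on the joint table
  expect_true(blanket_suffices(chain, "B", c("A", "C")))
  expect_error(markov_blanket(chain, "Z"), "unknown species")
})

test_that("operators reproduce the reaction's marginal dynamics", {
  m <- reaction_model(alpha = 1/4)
  op <- build_operator(m, "S1")     # uncorrected
  subsets <- lapply(op$terms, `[[`, "subset")
  betas <- vapply(op$terms, `[[`, numeric(1), "beta")
  i_loss <- which(vapply(subsets, setequal, logical(1), c("S1", "S2")))
  i_gain <- which(vapply(subsets, setequal, logical(1), c("S3", "S4")))
  expect_equal(betas[i_loss], -1)
  expect_equal(betas[i_gain], (1/4) / (3/4))   # beta = alpha / (1 - alpha)
  expect_lte(abs(operator_orthogonality(op, m)), 1e-12)

  opc <- build_operator(m, "S1", corrected = TRUE)
  betac <- vapply(opc$terms, `[[`, numeric(1), "beta")
  expect_equal(betac[i_gain], corrected_beta(1/4, 2, 2))

  # operator output vanishes at the steady-state marginals (corrected)
  q <- model_marginals(m)
  val <- sum(vapply(opc$terms, function(tm)
    tm$beta * prod(q[tm$subset]), numeric(1)))
  expect_lte(abs(val), 1e-14)
})

test_that("orthogonality holds for uncorrected operators across models", {
  set.seed(21)
  for (i in 1:10) {
    a1 <- runif(1, 0.05, 0.4); a2 <- runif(1, a1 + 0.05, 0.95)
    z <- runif(1, 0.1, 0.9)
    cm <- coupled_reaction_model(a1, a2, z = z)
    for (sp in cm$species) {
      op <- build_operator(cm, sp)
      expect_lte(abs(operator_orthogonality(op, cm)), 1e-12)
    }
  }
  # operators only reach the species' blanket/coupling set
  em <- enzymatic_model(0.3, 0.6, z = 0.7, c = 0.01)
  opS <- build_operator(em, "S")
  touched <- unique(unlist(lapply(opS$terms, `[[`, "subset")))
  expect_true(all(touched %in% c("S", markov_blanket(em, "S"))))
})

test_that("corrected beta applies the substrate/product power rule", {
  expect_equal(corrected_beta(1/4, 2, 2), 1/9)
  expect_equal(corrected_beta(1/2, 3, 3), 1)
  expect_equal(corrected_beta(1/4, 1, 1), (1/4) / (3/4))
  expect_error(corrected_beta(0, 2, 2), "strictly inside")
  expect_error(corrected_beta(1, 2, 2), "strictly inside")
})

test_that("mean-field dynamics reach the model's marginals", {
  m <- reaction_model(alpha = 1/4)
  marg <- model_marginals(m)
  # steady-state start stays put
  tr0 <- meanfield_simulate(m, marg, seq(0, 10, 0.5))
  expect_lte(max(abs(sweep(tr0$states, 2, marg))), 1e-8)

  # substrates initially at maximum presence
  tr <- meanfield_simulate(m, c(S1 = 1, S2 = 1, S3 = 0, S4 = 0),
                           seq(0, 80, 0.25), model = m)
  expect_equal(unname(final_state(tr)), c(0.25, 0.25, 0.75, 0.75),
               tolerance = 1e-4)
  expect_lte(max(diff(tr$free_energy)), 1e-6)
  # summed presence probability of each conserved pair is constant
  expect_lte(diff(range(tr$states[, 1] + tr$states[, 3])), 1e-8)
  expect_lte(diff(range(tr$states[, 2] + tr$states[, 4])), 1e-8)
})

test_that("independent sub-models factorize: mean field equals the exact
           master equation", {
  # two decoupled one-substrate/one-product conversions
  mk_pair <- function(a, s1, s2) list(
    cond_factor(s1, table = matrix(c(a, 1 - a), ncol = 1)),
    cond_factor(s2, parents = s1, table = cbind(c(0, 1), c(1, 0))))
  model <- generative_model(
    c("A1", "A2", "B1", "B2"),
    c(mk_pair(0.3, "A1", "A2"), mk_pair(0.6, "B1", "B2")),
    reactions = list(model_reaction("A1", "A2", rate = 1),
                     model_reaction("B1", "B2", rate = 1)))
  q0 <- c(A1 = 0.9, A2 = 0.1, B1 = 0.2, B2 = 0.8)
  times <- seq(0, 10, 0.25)
  tr <- meanfield_simulate(model, q0, times)
  # exact 2-state master equations for each pair: dq1 = beta q2 - q1
  exact_pair <- function(a, q1_0) {
    L <- rate_matrix(matrix(c(-1, 1, a / (1 - a), -a / (1 - a)), 2))
    expm_solution(L, c(q1_0, 1 - q1_0), times)[, 1]
  }
  expect_lte(max(abs(tr$states[, "A1"] - exact_pair(0.3, 0.9))), 1e-6)
  expect_lte(max(abs(tr$states[, "B1"] - exact_pair(0.6, 0.2))), 1e-6)
})

test_that("coupled-reaction models settle on their prescribed marginals", {
  cm <- coupled_reaction_model(0.2, 0.5, z = 0.5)
  marg <- model_marginals(cm)
  expect_equal(marg, c(S1 = 0.2, S2 = 0.2, S3 = 0.6, S4 = 0.2, S5 = 0.2))
  tr <- meanfield_simulate(cm, c(S1 = 1, S2 = 1, S3 = 0, S4 = 0, S5 = 0),
                           seq(0, 150, 0.5), model = cm)
  expect_lte(max(abs(final_state(tr) - marg)), 1e-4)
  # the declared moiety: marginal of S1 + S3 + S4 stays one
  tot <- tr$states[, "S1"] + tr$states[, "S3"] + tr$states[, "S4"]
  expect_lte(diff(range(tot)), 1e-8)
})
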