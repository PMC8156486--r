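enzyme_network <- function(k = c(1, 1, 1, 1)) {
  reaction_network(c("S", "E", "C", "P"), list(
    bind = mass_action_reaction(c(S = 1, E = 1), c(C = 1),
                                kf = k[1], kr = k[2]),
    catalyze = mass_action_reaction(c(C = 1), c(P = 1, E = 1),
                                    kf = k[3], kr = k[4])))
}

test_that("assembly builds the stoichiometry column per directed reaction", {
  net1 <- reaction_network(c("A", "B"), list(
    conv = mass_action_reaction(c(A = 1), c(B = 1), kf = 1)))
  expect_equal(unname(net1$stoichiometry), matrix(c(-1, 1), 2))

  enz <- enzyme_network()
  Om <- enz$stoichiometry
  expect_equal(ncol(Om), 4)
  # the enzyme row sums to zero across each reversible pair
  expect_equal(unname(Om["E", "bind.f"] + Om["E", "bind.r"]), 0)
  expect_equal(unname(Om["E", "catalyze.f"] + Om["E", "catalyze.r"]), 0)
  # enzyme moiety E + C is a stored conserved quantity
  expect_true(any(apply(enz$moieties, 1, function(m)
    isTRUE(all.equal(unname(m["E"] + m["C"]), 0)) &&
      abs(m["E"]) > 1e-8)))

  expect_error(reaction_network("A", list(
    bad = mass_action_reaction(c(A = 1), c(Z = 1), kf = 1))),
    "unknown\\s+species")
})

test_that("simulation conserves closed-system moieties and positivity", {
  net <- metabolic_network()
  # nothing in, nothing happens
  empty <- metabolic_network(influx = 0)
  tr0 <- simulate_network(empty, rep(0, 7), seq(0, 10, 1))
  expect_equal(max(abs(tr0$states)), 0)

  # with the source on, every species eventually becomes positive
  tr <- simulate_network(net, rep(0, 7), seq(0, 150, 1))
  expect_true(all(final_state(tr) > 0))
  expect_gte(min(tr$states), -1e-10)

  # a closed mass-action loop conserves its moiety exactly
  enz <- enzyme_network()
  u0 <- c(S = 0.8, E = 0.5, C = 0.1, P = 0)
  tre <- simulate_network(enz, u0, seq(0, 50, 0.5))
  expect_lte(diff(range(tre$states[, "E"] + tre$states[, "C"])), 1e-8)
  expect_lte(diff(range(tre$states[, "S"] + tre$states[, "C"] +
                          tre$states[, "P"])), 1e-8)
})

test_that("steady-state search converges, reports residuals, and refuses
           to fake convergence on oscillators", {
  net <- metabolic_network()
  pre <- find_steady_state(net, rep(0, 7))
  expect_true(pre$converged)
  expect_lt(pre$residual, 1e-8)
  expect_true(all(pre$u > 0))

  again <- find_steady_state(net, pre$u)
  expect_true(again$converged)
  expect_equal(again$time, 0)

  # throughput balance: source influx equals sink efflux
  rates <- catflow:::network_rates(net, pre$u)
  expect_lte(abs(sum(net$sources) - rates[["S5_out"]] - rates[["S7_out"]]),
             1e-8)

  # a conservative predator-prey loop never settles
  lv <- reaction_network(c("X", "Y"), list(
    grow = mass_action_reaction(c(X = 1), c(X = 2), kf = 1),
    pred = mass_action_reaction(c(X = 1, Y = 1), c(Y = 2), kf = 1),
    die = mass_action_reaction(c(Y = 1), c(X = 0), kf = 1)))
  osc <- find_steady_state(lv, c(X = 2, Y = 1), horizon = 150)
  expect_false(osc$converged)
})

test_that("lesions silence one reaction and reshape the whole steady
           state", {
  net <- metabolic_network()
  les <- lesion(net, "S1_to_S4")
  expect_equal(les$reactions$S1_to_S4$v_max, 0)
  expect_identical(les$stoichiometry, net$stoichiometry)
  expect_identical(lesion(les, "S1_to_S4")$reactions, les$reactions)
  expect_error(lesion(net, "nope"), "unknown reaction")

  pre <- find_steady_state(net, rep(0, 7))
  post <- find_steady_state(les, pre$u)
  expect_true(post$converged)
  expect_lt(post$residual, 1e-8)

  # flux through the lesioned reaction is identically zero
  trl <- simulate_network(les, rep(0, 7), seq(0, 50, 1))
  flux <- apply(trl$states, 1, function(u) {
    names(u) <- les$species
    catflow:::network_rates(les, u)[["S1_to_S4"]]
  })
  expect_equal(max(abs(flux)), 0)

  d <- diaschisis(pre, post)
  cls <- setNames(d$class, d$species)
  expect_equal(unname(cls[c("S4", "S5")]), c("lost", "lost"))
  expect_equal(unname(cls[c("S2", "S6")]), c("increased", "increased"))
  # distant species change although the lesion touched one reaction
  expect_true(cls[["S3"]] != "unchanged")

  # post-lesion throughput balance holds at the new steady state
  rates <- catflow:::network_rates(les, post$u)
  expect_lte(abs(sum(les$sources) - rates[["S5_out"]] - rates[["S7_out"]]),
             1e-8)
})

test_that("diaschisis classification is null for identical states and
           local for disconnected components", {
  net <- metabolic_network()
  pre <- find_steady_state(net, rep(0, 7))
  expect_true(all(diaschisis(pre, pre)$class == "unchanged"))

  # two disconnected enzyme loops; lesioning one leaves the other alone
  two <- reaction_network(c("A1", "B1", "A2", "B2"), list(
    c1 = mass_action_reaction(c(A1 = 1), c(B1 = 1), kf = 1, kr = 2),
    c2 = mass_action_reaction(c(A2 = 1), c(B2 = 1), kf = 1, kr = 2)))
  p1 <- find_steady_state(two, c(A1 = 1, B1 = 0, A2 = 1, B2 = 0))
  p2 <- find_steady_state(lesion(two, "c1"),
                          c(A1 = 1, B1 = 0, A2 = 1, B2 = 0))
  d <- diaschisis(p1, p2)
  expect_equal(d$class[d$species %in% c("A2", "B2")],
               c("unchanged", "unchanged"))
})

test_that("SBML export writes parseable Level 3 with exact numbers", {
  net <- metabolic_network()
  u0 <- setNames(seq(0.1, 0.7, 0.1), net$species)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, f, u0 = u0)
  x <- xml2::read_xml(f)
  ns <- "//*[local-name()='%s']"
  sp <- xml2::xml_find_all(x, sprintf(ns, "species"))
  expect_equal(xml2::xml_attr(sp, "id"), net$species)
  expect_equal(as.numeric(xml2::xml_attr(sp, "initialConcentration")),
               unname(u0), tolerance = 1e-15)
  rx <- xml2::xml_find_all(x, sprintf(ns, "reaction"))
  expect_equal(length(rx), 15)   # 14 reactions + 1 source
  vmax <- xml2::xml_find_all(x,
    "//*[local-name()='localParameter'][@id='v_max']")
  expect_equal(as.numeric(xml2::xml_attr(vmax, "value")),
               vapply(net$reactions, `[[`, numeric(1), "v_max"),
               tolerance = 1e-15, ignore_attr = TRUE)

  # numerical round trip: rebuild the MM rates from the parsed document
  # and compare the implied derivatives at u0
  kms <- as.numeric(xml2::xml_attr(xml2::xml_find_all(x,
    "//*[local-name()='localParameter'][@id='kappa_m']"), "value"))
  subs <- xml2::xml_attr(xml2::xml_find_all(x, paste0(
    sprintf(ns, "reaction"), "//*[local-name()='speciesReference']")),
    "species")
  expect_true(all(kms == 1))
  du_pkg <- catflow:::network_rhs(net, u0)
  vm <- as.numeric(xml2::xml_attr(vmax, "value"))
  # reconstruct: reaction list order matches the document order
  du_doc <- setNames(numeric(7), net$species)
  for (i in seq_along(net$reactions)) {
    r <- net$reactions[[i]]
    rate <- vm[i] * u0[[r$substrate]] / (kms[i] + u0[[r$substrate]])
    du_doc[r$substrate] <- du_doc[r$substrate] - rate
    if (!is.na(r$product)) du_doc[r$product] <- du_doc[r$product] + rate
  }
  du_doc["S3"] <- du_doc["S3"] + 0.1
  expect_lte(max(abs(du_doc - du_pkg)), 1e-9)
})
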