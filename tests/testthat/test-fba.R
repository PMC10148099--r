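test_that("a unique bottleneck sets every chained maximum", {
  m <- make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "G1", NA),
                         bottleneck_index = 2)
  sol <- maximize_flux(m, "R2")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  # all internal reactions are flux-coupled through the bottleneck
  res <- max_over_all(m, c("R1", "R2", "R3"))
  expect_equal(res$max_flux, rep(10, 3))
})

test_that("closing the source blocks the chain", {
  m <- make_linear_chain(ubs = c(100, 10, 100), exchange_ub = 1000)
  sol <- maximize_flux(m, "R2", overrides = list(EX_in = c(0, 0)))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0)
})

test_that("parallel routes add up (diamond network)", {
  m <- make_diamond_model(direct_ub = 4, via_ub = 3)
  sol <- maximize_flux(m, "Rdemand")
  # brute-force oracle fixes the expected optimum
  expect_equal(oracle_max_flux(m, "Rdemand")$value, 7, tolerance = 1e-9)
  expect_equal(sol$objective_value, 7, tolerance = 1e-6)
})

test_that("optimal solutions are feasible within tolerance", {
  for (seed in 1:5) {
    m <- make_random_network(seed = seed)
    S <- stoichiometric_matrix(m, sparse = FALSE)
    for (rid in m$reactions$id[!m$reactions$is_exchange]) {
      sol <- maximize_flux(m, rid)
      expect_equal(sol$status, "optimal")
      v <- sol$fluxes
      expect_lt(max(abs(S %*% v)), 1e-9 * max(1, max(abs(v))))
      expect_true(all(v >= m$reactions$lower_bound - 1e-9))
      expect_true(all(v <= m$reactions$upper_bound + 1e-9))
      expect_equal(unname(v[rid]), sol$objective_value, tolerance = 1e-9)
    }
  }
})

test_that("per-reaction maxima match the brute-force oracle on small fixtures", {
  fixtures <- list(
    make_linear_chain(ubs = c(100, 10, 100)),
    make_diamond_model(),
    make_bypass_model(),
    make_linear_chain(ubs = c(5, 8), lbs = c(-5, 0))
  )
  for (m in fixtures) {
    for (rid in m$reactions$id) {
      got <- maximize_flux(m, rid)
      want <- oracle_max_flux(m, rid)
      expect_equal(got$status, want$status)
      if (want$status == "optimal") {
        expect_equal(got$objective_value, want$value, tolerance = 1e-6)
      }
    }
  }
})

test_that("shrinking bounds can never raise an optimum (containment)", {
  for (seed in 1:10) {
    m <- make_random_network(seed = seed)
    rxns <- m$reactions
    # shrink every bound toward zero by a random per-reaction factor
    ov <- list()
    set.seed(seed + 1000)
    f <- runif(nrow(rxns), 0.2, 1)
    for (i in seq_len(nrow(rxns))) {
      ov[[rxns$id[i]]] <- c(
        if (rxns$lower_bound[i] < 0) f[i] * rxns$lower_bound[i]
        else rxns$lower_bound[i],
        if (rxns$upper_bound[i] > 0) f[i] * rxns$upper_bound[i]
        else rxns$upper_bound[i])
    }
    base <- max_over_all(m)
    shrunk <- max_over_all(m, overrides = ov)
    ok <- base$status == "optimal" & shrunk$status == "optimal"
    expect_true(all(shrunk$max_flux[ok] <= base$max_flux[ok] + 1e-6))
  }
})

test_that("optima scale linearly with the bounds (LP homogeneity)", {
  m <- make_random_network(seed = 11)
  k <- 3.5
  ov <- list()
  for (i in seq_len(nrow(m$reactions))) {
    ov[[m$reactions$id[i]]] <- k * c(m$reactions$lower_bound[i],
                                     m$reactions$upper_bound[i])
  }
  base <- max_over_all(m)
  scaled <- max_over_all(m, overrides = ov)
  expect_equal(scaled$max_flux, k * base$max_flux, tolerance = 1e-8)
})

test_that("max_over_all is order-independent and reports model order", {
  m <- make_linear_chain(ubs = c(100, 10, 100))
  a <- max_over_all(m, c("R3", "R1", "R2"))
  b <- max_over_all(m, c("R1", "R2", "R3"))
  expect_identical(a, b)
  expect_equal(a$reaction_id, c("R1", "R2", "R3"))
})

test_that("unknown objective reactions are rejected by name", {
  m <- make_bypass_model()
  expect_error(maximize_flux(m, "NOPE"), "NOPE")
  expect_error(max_over_all(m, c("Rknock", "NOPE")), "NOPE")
})

test_that("infeasible and unbounded statuses are reported, not capped", {
  # forced positive flux with no source: infeasible
  m <- make_linear_chain(ubs = c(10, 10))
  sol <- maximize_flux(m, "R1",
                       overrides = list(EX_in = c(0, 0), R1 = c(5, 10)))
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))

  # an uncapped two-reaction loop is unbounded
  mets <- data.frame(id = "A", name = "A", compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("Rf", "Rb"), name = c("f", "b"),
                     lower_bound = -Inf, upper_bound = Inf,
                     gene_rule = "", subsystem = "Loop",
                     stringsAsFactors = FALSE)
  loop <- metabolic_model("loop", mets, rxns,
                          list(Rf = c(A = 1), Rb = c(A = -1)))
  expect_equal(maximize_flux(loop, "Rf")$status, "unbounded")
})
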