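test_that("apply_knockdown scales bound magnitudes toward zero", {
  m <- make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "G1", NA))
  ov <- apply_knockdown(m, knockdown_spec("G1", 0.5))
  expect_equal(ov, list(R2 = c(0, 5)))

  # reversible reaction shrinks symmetrically
  m2 <- make_linear_chain(ubs = c(10, 10), lbs = c(-10, 0),
                          genes = c("G1", NA))
  ov2 <- apply_knockdown(m2, knockdown_spec("G1", 0.5))
  expect_equal(ov2, list(R1 = c(-5, 5)))

  # factor 1 is the identity on bounds
  ov3 <- apply_knockdown(m, knockdown_spec("G1", 1))
  expect_equal(ov3, list(R2 = c(0, 10)))
})

test_that("a gene mapping to no reactions is an error", {
  m <- make_linear_chain(ubs = c(10, 10), genes = c("G1", NA))
  m <- metabolic_model(m$id, m$metabolites, m$reactions, m$stoichiometry,
                       genes = c("G1", "LONE"))
  expect_error(apply_knockdown(m, knockdown_spec("LONE", 0.5)),
               "maps to no reactions")
  # explicit targets bypass the gene lookup
  ov <- apply_knockdown(m, knockdown_spec("LONE", 0.5,
                                          target_reactions = "R2"))
  expect_equal(names(ov), "R2")
})

test_that("invalid knockdown specs are rejected", {
  expect_error(knockdown_spec("G1", -0.1), "scale_factor")
  expect_error(knockdown_spec("G1", 1.5), "scale_factor")
  m <- make_bypass_model()
  expect_error(
    ensemble_screen(m, knockdown_spec("G1", 0.5,
                                      target_reactions = "NOPE")),
    "NOPE")
  expect_error(ensemble_screen(m, "G1", threshold = 0), "threshold")
})

test_that("halving a unique bottleneck halves every chained maximum", {
  m <- make_linear_chain(ubs = c(100, 80, 10, 90, 100),
                         genes = c(NA, NA, "HIBCH", NA, NA),
                         bottleneck_index = 3)
  res <- ensemble_screen(m, knockdown_spec("HIBCH", 0.5))
  expect_equal(res$records$reduction_fraction,
               rep(0.5, 5), tolerance = 1e-9)
  expect_setequal(res$compromised_ids, paste0("R", 1:5))
})

test_that("scale factor 1 gives identically zero reductions", {
  m <- make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "G1", NA))
  res <- ensemble_screen(m, knockdown_spec("G1", 1))
  expect_true(all(res$records$reduction_fraction == 0))
  expect_length(res$compromised_ids, 0)
})

test_that("an equal-capacity bypass attenuates downstream reductions", {
  m <- make_bypass_model(b1 = 5, b2 = 5, source_ub = 100)
  res <- ensemble_screen(m, knockdown_spec("G1", 0.5))
  rec <- res$records
  # downstream sees (5+5) -> (2.5+5): reduction 0.25, confirmed by oracle
  wt_oracle <- oracle_max_flux(m, "Rdown")$value
  kd_oracle <- oracle_max_flux(m, "Rdown",
                               apply_knockdown(m, "G1"))$value
  expect_equal(wt_oracle, 10)
  expect_equal(kd_oracle, 7.5)
  expect_equal(rec$reduction_fraction[rec$reaction_id == "Rdown"], 0.25,
               tolerance = 1e-6)
  # bypass branch itself is untouched
  expect_equal(rec$reduction_fraction[rec$reaction_id == "Rbypass"], 0,
               tolerance = 1e-6)
  # knocked branch sees the full factor
  expect_equal(rec$reduction_fraction[rec$reaction_id == "Rknock"], 0.5,
               tolerance = 1e-6)

  # degenerate bypass (b2 = 0) recovers chain behavior
  m0 <- make_bypass_model(b1 = 5, b2 = 0)
  res0 <- ensemble_screen(m0, "G1")
  expect_equal(
    res0$records$reduction_fraction[res0$records$reaction_id == "Rdown"],
    0.5, tolerance = 1e-6)
})

test_that("scale factor 0 equals outright reaction deletion", {
  m <- make_bypass_model(b1 = 5, b2 = 3, source_ub = 100)
  res <- ensemble_screen(m, knockdown_spec("G1", 0))
  # delete Rknock and recompute maxima independently
  keep <- m$reactions$id != "Rknock"
  mdel <- metabolic_model("deleted", m$metabolites,
                          m$reactions[keep, , drop = FALSE],
                          m$stoichiometry[keep], genes = m$genes)
  for (rid in setdiff(res$records$reaction_id, "Rknock")) {
    expect_equal(res$records$kd_max[res$records$reaction_id == rid],
                 maximize_flux(mdel, rid)$objective_value,
                 tolerance = 1e-6)
  }
  expect_equal(res$records$kd_max[res$records$reaction_id == "Rknock"], 0,
               tolerance = 1e-9)
})

test_that("blocked reactions are flagged and never compromised", {
  # R2 blocked by a zero-capacity downstream exchange
  m <- make_linear_chain(ubs = c(10, 10), genes = c("G1", NA))
  res <- ensemble_screen(m, "G1",
                         objective_set = c("R1", "R2"))
  expect_false(any(res$records$blocked))
  m$reactions$upper_bound[m$reactions$id == "EX_out"] <- 0
  res2 <- ensemble_screen(m, "G1", objective_set = c("R1", "R2"))
  expect_true(all(res2$records$blocked))
  expect_equal(res2$records$reduction_fraction, c(0, 0))
  expect_length(res2$compromised_ids, 0)
})

test_that("classification applies the threshold with tolerance", {
  rec <- data.frame(
    reaction_id = c("a", "b", "c", "d"),
    reduction_fraction = c(0.5, 0, 0.25 - 1e-8, 0.9),
    blocked = c(FALSE, FALSE, FALSE, TRUE),
    excluded = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  expect_setequal(classify_compromised(rec, 0.25), c("a", "c"))
  expect_setequal(classify_compromised(rec, 0.5), c("a"))
  expect_error(classify_compromised(rec, 0), "threshold")
})

test_that("subsystem summary sorts by count then name and sums correctly", {
  m <- make_valine_pathway_model()
  res <- ensemble_screen(m, "HIBCH")
  tab <- subsystem_summary(res)
  expect_equal(tab$subsystem, c("BCAA metabolism", "Propanoate metabolism"))
  expect_equal(sum(tab$n_compromised), length(res$compromised_ids))
  expect_true(all(diff(tab$n_compromised) <= 0))

  # empty compromised set -> empty table
  res0 <- ensemble_screen(m, knockdown_spec("HIBCH", 1))
  expect_equal(nrow(subsystem_summary(res0)), 0)
})

test_that("screens are deterministic and order-independent", {
  m <- make_random_network(seed = 21)
  r1 <- ensemble_screen(m, knockdown_spec("G1", 0.5))
  r2 <- ensemble_screen(m, knockdown_spec("G1", 0.5))
  expect_identical(r1, r2)
  ids <- m$reactions$id[!m$reactions$is_exchange]
  r3 <- ensemble_screen(m, knockdown_spec("G1", 0.5),
                        objective_set = rev(ids))
  expect_identical(r1$records, r3$records)
})
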