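test_that("the 3-reaction toy SBML fixture reads as specified", {
  f <- system.file("extdata", "toy3.xml", package = "fluxscreen")
  m <- read_sbml(f)
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(m$reactions$is_exchange, c(TRUE, FALSE, TRUE))
  expect_equal(m$reactions$upper_bound, c(1000, 10, 1000))
  expect_equal(m$reactions$gene_rule, c("", "GAB", ""))
  expect_equal(m$reactions$subsystem[2], "Toy pathway")
})

test_that("write/read round-trip is the identity on all screened fields", {
  models <- list(
    make_valine_pathway_model(),
    make_linear_chain(ubs = c(100, 10, 100), genes = c(NA, "HIBCH", NA)),
    make_bypass_model(),
    make_random_network(seed = 3)
  )
  for (m in models) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, f)
    m2 <- read_sbml(f)
    expect_equal(m2$reactions$id, m$reactions$id)
    expect_equal(m2$metabolites$id, m$metabolites$id)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
    expect_equal(m2$reactions$gene_rule, m$reactions$gene_rule)
    expect_equal(m2$stoichiometry, m$stoichiometry)
    expect_true(setequal(m2$genes, m$genes))
    # second round trip equals the first read exactly
    f2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m2, f2)
    expect_equal(read_sbml(f2), m2)
  }
})

test_that("reversible bounds survive the round trip exactly", {
  m <- make_linear_chain(ubs = c(10, 7), lbs = c(-10, 0))
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(m2$reactions$lower_bound[2], -10)
  expect_identical(m2$reactions$upper_bound[2], 10)
})

test_that("empty gene rules produce no association element", {
  m <- make_bypass_model()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  doc <- readLines(f)
  expect_length(grep("geneProductAssociation", doc), 2)  # open+close, Rknock only
})

test_that("format errors are reported with context", {
  expect_error(read_sbml(tempfile("nope")), "not found")

  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f)
  expect_error(read_sbml(f), "not parseable")

  # reaction referencing an undeclared metabolite names it
  fx <- system.file("extdata", "toy3.xml", package = "fluxscreen")
  txt <- readLines(fx)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(gsub('species="B" stoichiometry="1"',
                  'species="X" stoichiometry="1"', txt), f2)
  expect_error(read_sbml(f2), "X")

  # flux-bound reference resolving to no parameter names the reaction
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(gsub('fbc:upperFluxBound="ten"',
                  'fbc:upperFluxBound="missing_par"', txt), f3)
  expect_error(read_sbml(f3), "R_AB")
})

test_that("kinetic-law bounds and defaults are used when fbc is absent", {
  fx <- system.file("extdata", "toy3.xml", package = "fluxscreen")
  txt <- readLines(fx)
  # strip fbc bound attributes from R_AB and give it a kinetic law
  txt <- sub('fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">', ">",
             txt, fixed = TRUE)
  kl <- c("<kineticLaw><listOfLocalParameters>",
          '<localParameter id="LOWER_BOUND" value="0"/>',
          '<localParameter id="UPPER_BOUND" value="7"/>',
          "</listOfLocalParameters></kineticLaw>")
  i <- grep("</listOfProducts>", txt)[2]
  txt <- append(txt, kl, after = i)
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, f)
  m <- read_sbml(f)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "R_AB"], 7)

  # no bounds anywhere: defaults with a warning
  txt2 <- readLines(fx)
  txt2 <- sub('fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">', ">",
              txt2, fixed = TRUE)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt2, f2)
  expect_warning(m2 <- read_sbml(f2), "defaults")
  expect_equal(m2$reactions$upper_bound[m2$reactions$id == "R_AB"], 1000)
  expect_equal(m2$reactions$lower_bound[m2$reactions$id == "R_AB"], 0)
})

test_that("boundaryCondition species are dropped from stoichiometries", {
  fx <- system.file("extdata", "toy3.xml", package = "fluxscreen")
  txt <- readLines(fx)
  j <- grep('id="B"', txt) + 1L  # species B attribute continuation line
  txt[j] <- sub('boundaryCondition="false"', 'boundaryCondition="true"',
                txt[j])
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, f)
  # EX_B is left with only boundary species and is dropped with a warning
  expect_warning(m <- read_sbml(f), "boundary")
  expect_false("B" %in% m$metabolites$id)
  expect_false("EX_B" %in% m$reactions$id)
  # R_AB now touches only A, hence is classified as boundary by convention
  expect_equal(m$stoichiometry$R_AB, c(A = -1))
  expect_true(m$reactions$is_exchange[m$reactions$id == "R_AB"])
})
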