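test_that("assembled neutral formulas equal component sums minus water", {
  # oracle: explicit element bookkeeping per condensation bond
  cases <- list(
    list(s = assemble_ndmm(side_chain(7)), formula = "C13H24O6"),
    list(s = assemble_ndmm(side_chain(7),
                           first_unit = assemble_ndmm(side_chain(7)),
                           linkage = "4'"),
         formula = "C26H46O11"),                       # 2x C13H24O6 - H2O
    list(s = assemble_ndmm(side_chain(5), head = "UB"),
         formula = "C16H28N2O8"),                      # C11H20O6 + C5H10N2O3 - H2O
    list(s = assemble_ndmm(side_chain(3, attachment = "omega")),
         formula = "C9H16O6"),
    list(s = assemble_ndmm(side_chain(7, unsaturated = TRUE)),
         formula = "C13H22O6")
  )
  for (cs in cases) {
    expect_identical(render_formula(cs$s$formula), cs$formula)
  }
  # class labels follow the components
  expect_identical(cases[[2]]$s$class, "DASC")
  expect_identical(cases[[3]]$s$class, "UBAS")
  expect_identical(assemble_ndmm(side_chain(4), head = "UP")$class, "UPAS")
  expect_identical(cases[[1]]$s$class, "simple")
})

test_that("element conservation: decomposing an assembly recovers components", {
  first <- assemble_ndmm(side_chain(5))
  dimer <- assemble_ndmm(side_chain(4), head = "UB",
                         first_unit = first, linkage = "2'")
  # formula + 3 waters (glycoside, dimer ester, head ester) = sum of parts
  back <- fml_add(dimer$formula, fml_multiply("H2O", 3))
  parts <- Reduce(fml_add, list(parse_formula("C6H12O4"),
                                parse_formula("C4H8O3"),
                                parse_formula("C5H10N2O3"),
                                first$formula))
  expect_identical(render_formula(back), render_formula(parts))
})

test_that("unsupported building blocks are rejected", {
  expect_error(side_chain(2), "unsupported chain length")
  expect_error(side_chain(12), "unsupported chain length")
  expect_error(assemble_ndmm(side_chain(4), head = "UB",
                             first_unit = assemble_ndmm(side_chain(5)),
                             linkage = "4'"),
               "occupied")
  expect_error(assemble_ndmm(side_chain(4), linkage = "2'"), "without")
})

test_that("diagnostic fragments reproduce the printed ion formulas", {
  dasc3 <- parse_name("2'-(asc-C5)-asc-C4")
  fr <- diagnostic_fragments(dasc3)
  expect_identical(fr$ion_formula, "C17H28NaO8+")
  expect_identical(fr$adduct, "M+Na")
  expect_identical(unname(fr$polarity), "positive")

  dasc14 <- parse_name("4'-(asc-\u0394C7)-asc-C5")
  expect_identical(diagnostic_fragments(dasc14)$ion_formula, "C19H30NaO8+")

  ubas <- parse_name("4'-UB-asc-C5")
  fru <- diagnostic_fragments(ubas)
  expect_identical(fru$ion_formula, "C11H19N2O5+")
  expect_identical(fru$adduct, "M+H")

  upas <- parse_name("4'-UP-asc-C4")
  frp <- diagnostic_fragments(upas)
  expect_identical(frp$ion_formula, "C4H7N2O3-")
  expect_identical(unname(frp$polarity), "negative")
})

test_that("fragment rules do not apply to simple or registry compounds", {
  expect_error(diagnostic_fragments(assemble_ndmm(side_chain(5))),
               "no diagnostic fragment rule")
  expect_error(diagnostic_fragments(registry_ndmm("npar#1", "C24H38N4O11")),
               "no diagnostic fragment rule")
})

test_that("registry compounds carry their supplied formula and class", {
  r <- registry_ndmm("pasc#9", "C20H34O9", class = "PASC")
  expect_identical(r$class, "PASC")
  expect_identical(render_formula(r$formula), "C20H34O9")
  expect_error(registry_ndmm("x", "C4H7N2O3-"), "neutral")
})
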