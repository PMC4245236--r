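test_that("formula parsing, formatting and round-trips", {
  cases <- list(
    list(text = "C5H9NO4", counts = c(C = 5L, H = 9L, N = 1L, O = 4L)),
    list(text = "H2O", counts = c(H = 2L, O = 1L)),
    list(text = "C10H18N2O5S", counts = c(C = 10L, H = 18L, N = 2L, O = 5L, S = 1L)),
    list(text = "CO2", counts = c(C = 1L, O = 2L))
  )
  for (cs in cases) {
    f <- parse_formula(cs$text)
    expect_identical(unclass(f), cs$counts[order(names(cs$counts))])
    expect_identical(format_formula(f), cs$text)
    expect_identical(parse_formula(format_formula(f)), f)
  }
  expect_identical(format_formula(ms_formula()), "")
  expect_error(parse_formula("C5H9XO4"), "unknown element")
  expect_error(parse_formula("c5"), "malformed|unknown")
  expect_error(ms_formula(c(C = -1)), "negative")
})

test_that("monoisotopic masses match reference values", {
  expect_equal(formula_mass("C5H9NO4"), 147.0532, tolerance = 1e-4)
  expect_equal(round(formula_mass("NH3"), 4), 17.0265)
  expect_equal(round(formula_mass("NH3"), 3), 17.027)
  expect_equal(formula_mass(ms_formula()), 0)
  expect_equal(formula_mass("C10H18N2O5S"), 278.09364, tolerance = 1e-4)
  expect_error(formula_mass(ms_formula(c(Xx = 1))), "unknown element")
})

test_that("formula arithmetic is elementwise with negative-count errors", {
  expect_identical(
    format_formula(formula_arith("C10H18N2O5S", "C5H11NO2S", "subtract")),
    "C5H7NO3")
  f <- parse_formula("C5H9NO4")
  expect_identical(formula_arith(f, ms_formula(), "add"), f)
  expect_error(formula_arith("C5H9NO4", "C6H12O6", "subtract"), "negative")
  # additivity of mass under addition (property over random formulas)
  set.seed(1)
  for (i in 1:20) {
    a <- ms_formula(c(C = sample(0:10, 1), H = sample(0:20, 1),
                      N = sample(0:4, 1), O = sample(0:6, 1)))
    b <- ms_formula(c(C = sample(0:10, 1), H = sample(0:20, 1),
                      S = sample(0:2, 1)))
    expect_equal(formula_mass(a + b), formula_mass(a) + formula_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("formula_contains implements elementwise >=", {
  expect_true(formula_contains("C6H12O6", "H2O"))
  expect_false(formula_contains("C5H9NO4", "C6H12O6"))
  expect_true(formula_contains("C5H9NO4", ms_formula()))
})

test_that("ion m/z arithmetic reproduces printed reference offsets", {
  il <- default_ion_list("positive")
  labs <- vapply(il, `[[`, "", "label")
  mh <- il[[which(labs == "[M+H]+")]]
  mna <- il[[which(labs == "[M+Na]+")]]
  m2h <- il[[which(labs == "[2M+H]+")]]
  expect_equal(ion_mz(100, mh), 101.00728, tolerance = 1e-5)
  # the sodium-vs-proton adduct offset, printed as 21.9819 Da
  expect_equal(round(mna$delta_mass - mh$delta_mass, 4), 21.9819)
  # mixed-label glutamate dimer: theory within 0.005 of the observed 300.1309
  expect_equal(ion_mz(147.0532, m2h, 5), 300.1304, tolerance = 1e-4)
  expect_lt(abs(ion_mz(formula_mass("C5H9NO4"), m2h, 5) - 300.1309), 0.005)
})

test_that("ion_mz and neutral_mass_from_mz are mutual inverses", {
  for (mode in c("positive", "negative")) {
    for (ion in default_ion_list(mode)) {
      for (M in c(80.05, 147.0532, 512.2)) {
        expect_equal(neutral_mass_from_mz(ion_mz(M, ion), ion), M,
                     tolerance = 1e-9)
      }
    }
  }
  mh <- default_ion_list("positive")[[1]]
  expect_equal(neutral_mass_from_mz(148.0604, mh), 147.0532, tolerance = 1e-4)
  m2h <- default_ion_list("positive")[[11]]
  expect_identical(m2h$label, "[2M+H]+")
  expect_equal(neutral_mass_from_mz(295.1136, m2h), 147.0532, tolerance = 1e-3)
  expect_error(neutral_mass_from_mz(0.5, mh), "non-positive")
})

test_that("shifted_label inserts the 13C increment marker", {
  expect_identical(shifted_label("[M+H]+", 5), "[M+5+H]+")
  expect_identical(shifted_label("[2M+H]+", 5), "[2M+5+H]+")
  expect_identical(shifted_label("[M+H-H2O]+", 3), "[M+3+H-H2O]+")
  expect_identical(shifted_label("[M+H]+", 0), "[M+H]+")
})

test_that("ion lists round-trip through TSV and validate species", {
  path <- tempfile(fileext = ".tsv")
  ions <- default_ion_list("positive")
  write_ion_list(ions, path)
  back <- read_ion_list(path)
  expect_length(back, length(ions))
  expect_identical(vapply(back, `[[`, "", "label"),
                   vapply(ions, `[[`, "", "label"))
  expect_equal(vapply(back, `[[`, 0, "delta_mass"),
               vapply(ions, `[[`, 0, "delta_mass"), tolerance = 1e-9)
  expect_error(ion_species("[M+H]3+", 1, 3L), "charge")
  expect_error(ion_species("[2M+H]+", 1, 1L, multiplicity = 2, is_seed = TRUE),
               "seed")
})
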