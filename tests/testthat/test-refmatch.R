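test_that("dot product: identity, disjoint, hand-computed, symmetric", {
  a <- data.frame(mz = c(100, 150), intensity = c(1, 0.5))
  b <- data.frame(mz = 100, intensity = 1)
  expect_equal(dot_product_score(a, a), 1.0)
  expect_equal(dot_product_score(a, b), 1 / sqrt(1.25), tolerance = 1e-9)
  expect_equal(round(dot_product_score(a, b), 3), 0.894)
  disj <- data.frame(mz = c(333, 444), intensity = c(1, 1))
  expect_equal(dot_product_score(a, disj), 0.0)
  expect_error(dot_product_score(a, a[0, ]), "empty")
  set.seed(5)
  for (i in 1:10) {
    x <- data.frame(mz = sort(runif(5, 100, 500)), intensity = runif(5))
    y <- data.frame(mz = sort(runif(4, 100, 500)), intensity = runif(4))
    expect_equal(dot_product_score(x, y), dot_product_score(y, x),
                 tolerance = 1e-12)
    expect_equal(dot_product_score(x, x), 1.0, tolerance = 1e-12)
  }
})

confirmed_glutamate <- function() {
  out <- run_preset("glutamate")
  spectra <- out$res$spectra
  gi <- which(vapply(spectra, function(s) abs(s$M - 147.0532) < 0.01, TRUE))
  spectra[[gi]]$status <- "confirmed"
  spectra[[gi]]$compound_name <- "glutamate"
  list(out = out, spectra = spectra, gi = gi)
}

test_that("reference lists store 12C members of confirmed spectra only", {
  cg <- confirmed_glutamate()
  expect_warning(
    ref <- create_reference_list(cg$spectra, cg$out$res$peaks),
    "unconfirmed")
  expect_length(ref$entries, 1)
  entry <- ref$entries[[1]]
  expect_identical(entry$compound, "glutamate")
  # 12C species only: no shifted labels, no isotopes
  expect_false(any(grepl("\\+[0-9]+\\+", entry$peaks$ion_label)))
  expect_false(any(grepl("i\\]$", entry$peaks$ion_label)))
  expect_equal(max(entry$peaks$intensity), 1.0)
  expect_length(suppressWarnings(
    create_reference_list(cg$out$res$spectra, cg$out$res$peaks))$entries, 0)
})

test_that("applying a reference list to its source re-annotates everything", {
  cg <- confirmed_glutamate()
  suppressWarnings(ref <- create_reference_list(cg$spectra, cg$out$res$peaks))
  applied <- apply_reference_list(ref, cg$out$res$spectra, cg$out$res$peaks)
  expect_identical(nrow(applied$matches), length(ref$entries))
  expect_equal(applied$matches$score, rep(1.0, nrow(applied$matches)),
               tolerance = 1e-9)
  hit <- Filter(function(s) s$id == applied$matches$spectrum_id[1],
                applied$spectra)[[1]]
  expect_identical(hit$compound_name, "glutamate")
  expect_identical(hit$status, "confirmed")
})

test_that("reference lists tolerate bounded intensity jitter and honor rt", {
  cg <- confirmed_glutamate()
  suppressWarnings(ref <- create_reference_list(cg$spectra, cg$out$res$peaks))
  # jitter the target chromatogram's intensities by 10%
  jit <- run_preset("glutamate", noise_model(intensity_cv = 0.1, seed = 8))
  applied <- apply_reference_list(ref, jit$res$spectra, jit$res$peaks)
  expect_identical(nrow(applied$matches), 1L)
  expect_gt(applied$matches$score, 0.95)
  # outside the rt tolerance nothing is annotated
  ref2 <- ref; ref2$entries[[1]]$rt <- ref$entries[[1]]$rt + 500
  applied2 <- apply_reference_list(ref2, jit$res$spectra, jit$res$peaks)
  expect_identical(nrow(applied2$matches), 0L)
})

test_that("assembly mode builds a spectrum from a raw peak table", {
  cg <- confirmed_glutamate()
  suppressWarnings(ref <- create_reference_list(cg$spectra, cg$out$res$peaks))
  applied <- apply_reference_list(ref, list(), cg$out$res$peaks)
  expect_identical(nrow(applied$matches), 1L)
  expect_true(applied$matches$assembled)
  expect_length(applied$spectra, 1)
  expect_identical(applied$spectra[[1]]$compound_name, "glutamate")
})

test_that("reference lists round-trip through JSON", {
  cg <- confirmed_glutamate()
  suppressWarnings(ref <- create_reference_list(cg$spectra, cg$out$res$peaks))
  path <- tempfile(fileext = ".json")
  write_reference_list(ref, path)
  back <- read_reference_list(path)
  expect_identical(back$name, ref$name)
  expect_equal(back$score_threshold, ref$score_threshold)
  expect_identical(length(back$entries), length(ref$entries))
  expect_equal(back$entries[[1]]$peaks$mz, ref$entries[[1]]$peaks$mz,
               tolerance = 1e-12)
  applied <- apply_reference_list(back, cg$out$res$spectra, cg$out$res$peaks)
  expect_equal(applied$matches$score, 1.0, tolerance = 1e-9)
})

test_that("pseudo fragment spectra keep the pseudo-molecular ion + fragments", {
  cg <- confirmed_glutamate()
  s <- cg$spectra[[cg$gi]]
  pf <- pseudo_fragment_spectrum(s, cg$out$res$peaks)
  expect_setequal(pf$ion_label, c("[M+H]+", "[M+H-H2O]+", "[M+H-HCOOH]+"))
  # no Na adducts, homoadducts or 13C peaks
  expect_false(any(grepl("Na|2M|\\+5", pf$ion_label)))
  # a spectrum without a pseudo-molecular ion errors
  s2 <- s
  s2$annotations <- s2$annotations[s2$annotations$species_label != "[M+H]+", ]
  expect_error(pseudo_fragment_spectrum(s2, cg$out$res$peaks),
               "pseudo-molecular")
})

write_record <- function(path, accession, name, peaks) {
  lines <- c(paste0("ACCESSION: ", accession),
             paste0("CH$NAME: ", name),
             sprintf("PK$NUM_PEAK: %d", nrow(peaks)),
             "PK$PEAK: m/z int. rel.int.",
             sprintf("  %.4f %.1f %d", peaks$mz, peaks$intensity,
                     round(999 * peaks$intensity / max(peaks$intensity))),
             "//")
  writeLines(lines, path)
}

test_that("local record files are parsed, scored and ranked", {
  dir <- tempfile(); dir.create(dir)
  q <- data.frame(mz = c(148.0604, 130.0499, 102.0550),
                  intensity = c(1, 0.25, 0.15))
  write_record(file.path(dir, "rec1.txt"), "PB000462", "Glutamic acid",
               data.frame(mz = q$mz, intensity = q$intensity * 1000))
  write_record(file.path(dir, "rec2.txt"), "XX000001", "Unrelated",
               data.frame(mz = c(400.1, 401.1), intensity = c(900, 100)))
  writeLines("no peaks here", file.path(dir, "rec3.txt"))
  expect_warning(ranked <- match_record_file(q, dir), "unparseable")
  expect_identical(nrow(ranked), 2L)
  expect_identical(ranked$accession[1], "PB000462")
  expect_equal(ranked$score[1], 1.0, tolerance = 1e-9)
  expect_equal(ranked$score[2], 0.0)
  expect_identical(nrow(suppressWarnings(
    match_record_file(q, character(0)))), 0L)
})
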