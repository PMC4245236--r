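mkpeaks <- function(mz, maxo, rt = 300, id = sprintf("P%02d", seq_along(mz))) {
  rt <- rep_len(rt, length(mz))
  data.frame(id = id, mz = mz, rt = rt, rtmin = rt - 5, rtmax = rt + 5,
             maxo = maxo, into = maxo * 7.5, intb = maxo * 7.5,
             sample = rep_len("S1", length(mz)), stringsAsFactors = FALSE)
}

test_that("isotope chains follow spacing and decreasing-intensity rules", {
  cfg <- sd_config()
  # singly charged chain of three
  ch <- detect_isotope_chains(
    mkpeaks(c(200.0, 201.00336, 202.00671), c(1e6, 8e4, 5e3)), cfg)
  expect_length(ch, 1)
  expect_identical(ch[[1]]$charge, 1L)
  expect_length(ch[[1]]$members, 3)
  expect_false(ch[[1]]$mirrored)
  # half spacing indicates z = 2
  ch2 <- detect_isotope_chains(
    mkpeaks(c(200.0, 200.50168), c(1e6, 3e5)), cfg)
  expect_length(ch2, 1)
  expect_identical(ch2[[1]]$charge, 2L)
  # increasing intensity forbids a (natural) chain, but the same pair read
  # downward is a legal mirrored chain in labeled mode
  ch3 <- detect_isotope_chains(
    mkpeaks(c(200.0, 201.0034), c(1e4, 1e6)), sd_config(labeled = FALSE))
  expect_length(ch3, 0)
})

test_that("mirrored chains descend from the 13C monoisotopic peak", {
  cfg <- sd_config(labeled = TRUE)
  # 13C mono at the top, mirrored isotopes below it
  ch <- detect_isotope_chains(
    mkpeaks(c(153.0772, 152.0739, 151.0705), c(5e5, 2.5e4, 5e2)), cfg)
  mir <- Filter(function(x) x$mirrored, ch)
  expect_length(mir, 1)
  expect_identical(mir[[1]]$monoisotopic, "P01")
  expect_length(mir[[1]]$members, 3)
})

test_that("seed-adduct pairs assemble pseudo spectra with consistent M", {
  cfg <- sd_config()
  # [M+H]+ / [M+Na]+ pair of glutamate
  sp <- assemble_pseudo_spectra(mkpeaks(c(148.0604, 170.0423), c(1e6, 3e5)),
                                list(), cfg)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$M, 147.0532, tolerance = 2e-3)
  expect_setequal(sp[[1]]$annotations$ion_label, c("[M+H]+", "[M+Na]+"))
  # water-loss fragment + [M+H]+
  sp2 <- assemble_pseudo_spectra(mkpeaks(c(130.0499, 148.0604), c(3e5, 1e6)),
                                 list(), cfg)
  expect_length(sp2, 1)
  expect_setequal(sp2[[1]]$annotations$ion_label, c("[M+H]+", "[M+H-H2O]+"))
  expect_equal(sp2[[1]]$M, 147.0532, tolerance = 2e-3)
  # two non-seed species at a matching distance do not anchor a spectrum:
  # [M+H-H2O]+ vs [M+H-HCOOH]+ distance without any seed peak
  sp3 <- assemble_pseudo_spectra(mkpeaks(c(102.0550, 130.0499), c(2e5, 3e5)),
                                 list(), cfg)
  expect_true(all(vapply(sp3, function(s)
    any(s$annotations$role == "seed_adduct"), TRUE)))
})

test_that("pipeline handles degenerate inputs", {
  cfg <- sd_config()
  empty <- run_deconvolution(mkpeaks(numeric(0), numeric(0)), cfg)
  expect_length(empty$spectra, 0)
  lone <- run_deconvolution(mkpeaks(412.34, 1e5), cfg)
  expect_length(lone$spectra, 0)
  expect_identical(lone$orphans, "P01")
})

test_that("full pipeline recovers every planted annotation at zero noise", {
  for (nm in names(preset_scenarios())) {
    out <- run_preset(nm)
    flags <- recovered_flags(out$sim, out$res)
    expect_true(all(flags),
                label = sprintf("%s: missing %s", nm,
                                paste(names(flags)[!flags], collapse = ",")))
  }
})

test_that("pseudo spectra satisfy seed, m/z- and rt-consistency invariants", {
  for (nm in c("glutamate", "glu_met_dipeptide")) {
    out <- run_preset(nm)
    peaks <- out$res$peaks
    for (s in out$res$spectra) {
      expect_true(any(s$annotations$role == "seed_adduct"))
      idx <- match(s$annotations$peak_id, peaks$id)
      expect_true(all(abs(peaks$rt[idx] - s$rt) <= out$preset$cfg$eps_rt))
      expect_match(s$id, "^M[0-9.]+T[0-9.]+$")
    }
  }
})

test_that("label pairs carry the correct carbon count n", {
  out <- run_preset("glutamate")
  lp <- out$res$label_pairs
  truth <- out$sim$truth
  expect_gt(nrow(lp), 0)
  for (r in seq_len(nrow(lp))) {
    tr <- truth[truth$peak_id == lp$c13_peak[r], ]
    expect_identical(lp$n[r], as.integer(tr$n_shift))
    # spacing invariant
    p12 <- out$res$peaks[out$res$peaks$id == lp$c12_peak[r], ]
    p13 <- out$res$peaks[out$res$peaks$id == lp$c13_peak[r], ]
    expect_lt(abs(p13$mz - p12$mz - lp$n[r] * 1.003355 / lp$charge[r]), 0.005)
  }
  # dipeptide: the primary pair has n = 10
  out2 <- run_preset("glu_met_dipeptide")
  lp2 <- out2$res$label_pairs
  prim <- lp2[lp2$n == 10, ]
  expect_gt(nrow(prim), 0)
})

test_that("homoadducts are annotated including mixed-label shifts", {
  out <- run_preset("glutamate")
  ann <- all_annotations(out$res)
  expect_true("[2M+H]+" %in% ann$ion_label)
  expect_true("[2M+5+H]+" %in% ann$ion_label)
})

test_that("uncommon losses yield a unique conserved sum-formula triplet", {
  out <- run_preset("glu_met_dipeptide")
  s <- Filter(function(s) abs(s$M - 278.0936) < 0.01, out$res$spectra)
  expect_length(s, 1)
  frag <- s[[1]]$annotations[s[[1]]$annotations$ion_label == "[M+H-C5H7NO3]+", ]
  expect_identical(nrow(frag), 1L)
  expect_false(frag$ambiguous)
  expect_identical(frag$loss_formula, "C5H7NO3")
  # conservation: primary = fragment + loss
  expect_identical(
    format_formula(formula_arith("C5H11NO2S", frag$loss_formula)),
    "C10H18N2O5S")
  # 13C partner of the fragment annotated with its own carbon count
  expect_true("[M+5+H-C5H7NO3]+" %in% s[[1]]$annotations$ion_label)
})

test_that("spectra whose primary lacks a 13C partner skip loss annotation", {
  out <- run_preset("unlabeled_standard_missing")
  expect_identical(nrow(out$res$label_pairs), 0L)
  ann <- all_annotations(out$res)
  expect_false(any(grepl("-C[0-9]", ann$ion_label)))
})

test_that("EIC correlation is scale-invariant and penalizes RT offsets", {
  a <- gauss_trace(300)
  expect_equal(eic_correlation(a, a), 1.0, tolerance = 1e-12)
  b <- a; b$intensity <- 2 * b$intensity
  expect_equal(eic_correlation(a, b), 1.0, tolerance = 1e-12)
  offset <- gauss_trace(309)  # 3 sigma away
  expect_lt(eic_correlation(a, offset), 0.5)
  # unavailability is NA, not a low value
  expect_true(is.na(eic_correlation(a, NULL)))
  expect_true(is.na(eic_correlation(a, gauss_trace(800))))
})

test_that("correlation pruning removes poorly correlated members only", {
  out <- run_preset("glutamate")
  eics <- simulate_eics(out$sim)
  # make one non-primary member anticorrelated
  s1 <- out$res$spectra[[which.max(vapply(out$res$spectra, function(s)
    nrow(s$annotations), 0L))]]
  victim <- setdiff(
    s1$annotations$peak_id[is.na(s1$annotations$parent_id)], s1$primary)[1]
  eics[[victim]] <- gauss_trace(out$sim$compounds[[1]]$rt + 9)
  pruned <- prune_by_correlation(out$res$spectra, eics, out$preset$cfg)
  ps1 <- Filter(function(s) s$id == s1$id, pruned)[[1]]
  expect_false(victim %in% ps1$annotations$peak_id)
  expect_true(s1$primary %in% ps1$annotations$peak_id)
  # everything else correlates ~1 and stays
  expect_identical(
    setdiff(s1$annotations$peak_id, ps1$annotations$peak_id) %in%
      c(victim, s1$annotations$peak_id[s1$annotations$parent_id %in% victim]),
    rep(TRUE, length(setdiff(s1$annotations$peak_id, ps1$annotations$peak_id))))
  # no EICs at all: skipped with a warning
  expect_warning(prune_by_correlation(out$res$spectra, NULL, out$preset$cfg),
                 "skipped")
})

test_that("claim_peaks enforces single membership", {
  out <- run_preset("coeluting_pair")
  spectra <- out$res$spectra
  glu <- Filter(function(s) abs(s$M - 147.0532) < 0.01, spectra)[[1]]
  other_ids <- setdiff(vapply(spectra, `[[`, "", "id"), glu$id)
  shared <- unique(unlist(lapply(spectra, function(s) {
    if (s$id == glu$id) return(NULL)
    intersect(s$annotations$peak_id, glu$annotations$peak_id)
  })))
  expect_gt(length(shared), 0)  # the coelution scenario shares peaks
  claimed <- claim_peaks(spectra, glu$id, shared)
  for (pid in shared) {
    holders <- vapply(claimed, function(s) pid %in% s$annotations$peak_id, TRUE)
    expect_identical(sum(holders), 1L)
  }
  # claiming peaks present only in the target is a no-op
  only_mine <- setdiff(glu$annotations$peak_id, shared)
  expect_identical(length(claim_peaks(claimed, glu$id, only_mine[1])),
                   length(claimed))
  expect_error(claim_peaks(spectra, glu$id, "PXX"), "not member")
})

test_that("orphan browsing filters by window and intensity", {
  out <- run_preset("glutamate",
                    noise_model(n_contaminants = 5L, seed = 3))
  orph <- list_orphans(out$res$peaks, out$res$spectra)
  cont <- out$sim$truth$peak_id[out$sim$truth$expected_role == "contaminant"]
  expect_setequal(orph, cont)
  expect_length(
    list_orphans(out$res$peaks, out$res$spectra, min_intensity = 1e9), 0)
  rtw <- c(out$sim$peaks$rt[match(cont[1], out$sim$peaks$id)] - 0.5,
           out$sim$peaks$rt[match(cont[1], out$sim$peaks$id)] + 0.5)
  expect_true(cont[1] %in% list_orphans(out$res$peaks, out$res$spectra,
                                        rt_window = rtw))
})

test_that("find_correlating_peaks ranks co-shaped orphans", {
  out <- run_preset("glutamate")
  eics <- simulate_eics(out$sim)
  # plant a co-eluting orphan with an identical profile
  peaks <- rbind(out$res$peaks,
                 mkpeaks(500.321, 4e4, rt = out$sim$compounds[[1]]$rt,
                         id = "PX1"))
  eics[["PX1"]] <- gauss_trace(out$sim$compounds[[1]]$rt, apex = 4e4)
  res2 <- run_deconvolution(peaks, out$preset$cfg)
  glu <- Filter(function(s) abs(s$M - 147.0532) < 0.01, res2$spectra)[[1]]
  hits <- find_correlating_peaks(glu, peaks, res2$spectra, eics,
                                 threshold = 0.75)
  expect_true("PX1" %in% hits$peak_id)
  expect_true(all(hits$corr >= 0.75))
  none <- find_correlating_peaks(glu, peaks, res2$spectra, eics,
                                 threshold = 1.0 - 1e-12)
  expect_true(all(none$corr >= 1.0 - 1e-12))
})

test_that("pipeline output is deterministic for fixed input and seed", {
  a <- run_preset("glutamate", noise_model(mz_sd = 0.001, seed = 99))
  b <- run_preset("glutamate", noise_model(mz_sd = 0.001, seed = 99))
  expect_identical(a$sim$peaks, b$sim$peaks)
  expect_identical(a$res$spectra, b$res$spectra)
  expect_identical(a$res$label_pairs, b$res$label_pairs)
})

test_that("two coeluting compounds without m/z coincidences stay disjoint", {
  ps <- preset_scenarios()
  comps <- c(ps$glutamate$compounds, ps$glu_met_dipeptide$compounds)
  comps[[2]]$rt <- comps[[1]]$rt  # force coelution
  sim <- simulate_peak_table(comps, noise_model(seed = 5), sd_config())
  res <- run_deconvolution(sim$peaks, sd_config())
  glu <- Filter(function(s) abs(s$M - 147.0532) < 0.01, res$spectra)
  pep <- Filter(function(s) abs(s$M - 278.0936) < 0.01, res$spectra)
  expect_length(glu, 1); expect_length(pep, 1)
  expect_length(intersect(glu[[1]]$annotations$peak_id,
                          pep[[1]]$annotations$peak_id), 0)
})
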