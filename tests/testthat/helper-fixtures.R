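# Shared fixtures: a brute-force decomposition oracle (independent of the
# recursive search it checks) and preset-based pipeline runners.

.em <- mass_constants()$elements

# all CHNOPS combinations (H solved arithmetically) with mass <= 400 Da
oracle_grid <- local({
  g <- expand.grid(C = 0:33, N = 0:20, O = 0:20, P = 0:9, S = 0:10)
  g$m5 <- 12 * g$C + .em[["N"]] * g$N + .em[["O"]] * g$O +
    .em[["P"]] * g$P + .em[["S"]] * g$S
  g[g$m5 <= 400.1, ]
})

# naive enumeration: every (C,N,O,P,S) lattice point, hydrogen from the
# mass remainder, then the same filter stack as the query
oracle_decompose <- function(mass, tol = 0.005, q = decomp_query(mass, tol)) {
  rem <- mass - oracle_grid$m5
  hlo <- ceiling((rem - tol) / .em[["H"]])
  hhi <- floor((rem + tol) / .em[["H"]])
  sel <- which(hlo <= hhi & hhi >= 0 & hlo <= 72)
  out <- character(0)
  for (i in sel) {
    for (h in max(hlo[i], 0):min(hhi[i], 72)) {
      cnt <- c(C = oracle_grid$C[i], H = h, N = oracle_grid$N[i],
               O = oracle_grid$O[i], P = oracle_grid$P[i],
               S = oracle_grid$S[i])
      f <- ms_formula(cnt[cnt > 0])
      if (abs(formula_mass(f) - mass) <= tol && passes_filters(f, q)$passed) {
        out <- c(out, format_formula(f))
      }
    }
  }
  sort(out)
}

run_preset <- function(name, noise = noise_model(seed = 1)) {
  p <- preset_scenario(name)
  sim <- simulate_peak_table(p$compounds, noise, p$cfg)
  res <- run_deconvolution(sim$peaks, p$cfg)
  list(preset = p, sim = sim, res = res)
}

all_annotations <- function(res) {
  do.call(rbind, c(lapply(res$spectra, function(s) s$annotations),
                   list(empty_ann_df())))
}

empty_ann_df <- function() {
  data.frame(peak_id = character(0), ion_label = character(0),
             species_label = character(0), role = character(0),
             n_shift = integer(0), loss_formula = character(0),
             ambiguous = logical(0), parent_id = character(0),
             corr = numeric(0), stringsAsFactors = FALSE)
}

# fraction of planted monoisotopic ion labels recovered verbatim
recovered_flags <- function(sim, res) {
  tr <- sim$truth[sim$truth$isotope_index == 0 &
                    sim$truth$expected_role != "contaminant", , drop = FALSE]
  ann <- all_annotations(res)
  flags <- mapply(function(pid, lab) {
    any(ann$peak_id == pid & ann$ion_label == lab)
  }, tr$peak_id, tr$expected_label)
  names(flags) <- tr$expected_label
  flags
}

# a tiny two-peak gaussian trace builder for correlation tests
gauss_trace <- function(center, sigma = 3, apex = 1e5,
                        from = center - 12, to = center + 12, by = 0.25) {
  ts <- seq(from, to, by = by)
  data.frame(rt = ts, intensity = apex * exp(-(ts - center)^2 / (2 * sigma^2)))
}
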