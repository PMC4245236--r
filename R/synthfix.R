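# Synthetic LC-ESI-MS fixtures with full ground truth: coeluting compounds
# emitting configured adduct/fragment species, natural isotope patterns,
# mirrored patterns for the U-13C-labeled internal standard, homoadducts
# (including mixed-label dimers), contaminant peaks and configurable noise.
#
# The generator is deliberately a carbon-only isotope model: it emulates
# exactly the features the deconvolution logic keys on (chain spacing,
# decreasing intensities, mirrored direction, pair distances) and is NOT a
# general isotope-pattern simulator.

#' Noise model for the synthetic generator
#'
#' Defaults are the noiseless "stated world" used by the exact recovery
#' checks; stochastic checks use `mz_sd = eps_mz / 3`.
#'
#' @param mz_sd gaussian m/z noise SD, Da.
#' @param rt_jitter_sd per-peak retention-time jitter SD, seconds.
#' @param intensity_cv multiplicative intensity coefficient of variation.
#' @param n_contaminants number of random unrelated peaks.
#' @param seed integer RNG seed; the generator is deterministic per seed.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(mz_sd = 0, rt_jitter_sd = 0, intensity_cv = 0,
                        n_contaminants = 0L, seed = 1L) {
  stopifnot(mz_sd >= 0, rt_jitter_sd >= 0, intensity_cv >= 0,
            n_contaminants >= 0)
  structure(list(mz_sd = mz_sd, rt_jitter_sd = rt_jitter_sd,
                 intensity_cv = intensity_cv,
                 n_contaminants = as.integer(n_contaminants),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Define a ground-truth compound
#'
#' @param name compound name.
#' @param formula sum formula (string or [ms_formula()]).
#' @param rt retention time, seconds.
#' @param rt_sigma chromatographic peak width (gaussian SD), seconds.
#' @param base_abundance apex intensity of the most abundant 12C species.
#' @param label_abundance apex intensity of the fully 13C-labeled
#'   counterpart (the internal standard); 0 disables labeling.
#' @param species named numeric vector, ion label -> relative yield; labels
#'   must exist in the ion list used at simulation time.
#' @param extra_fragments optional named numeric vector, neutral-loss
#'   formula string -> relative yield, for analyte-specific (uncommon)
#'   losses not present in the ion list.
#' @param label_purity fraction of 13C at each carbon of the internal
#'   standard (drives the mirrored pattern).
#' @return list of class `gt_compound`.
#' @export
gt_compound <- function(name, formula, rt, rt_sigma = 3,
                        base_abundance = 1e6, label_abundance = 0,
                        species = c("[M+H]+" = 1.0),
                        extra_fragments = NULL, label_purity = 0.99) {
  stopifnot(rt > 0, rt_sigma > 0, base_abundance > 0, label_abundance >= 0,
            all(species > 0), label_purity > 0, label_purity <= 1)
  structure(list(name = name, formula = as_formula(formula), rt = rt,
                 rt_sigma = rt_sigma, base_abundance = base_abundance,
                 label_abundance = label_abundance, species = species,
                 extra_fragments = extra_fragments,
                 label_purity = label_purity),
            class = "gt_compound")
}

#' Natural isotopologue pattern (carbon binomial model)
#'
#' Relative intensities of M, M+1, ..., M+k-1 from a binomial model on the
#' carbon count with p(13C) = 0.0107, normalized to the monoisotopic peak.
#' Strictly decreasing for any realistic carbon count.
#'
#' @param f formula (or string); only the carbon count matters.
#' @param k number of isotopologues including the monoisotopic peak.
#' @return numeric vector of length k, first element 1.
#' @export
#' @examples
#' natural_isotope_pattern("C5H9NO4", 3)
natural_isotope_pattern <- function(f, k = 3L) {
  stopifnot(k >= 1)
  nC <- fcount(as_formula(f), "C")
  .binomial_pattern(nC, k, 0.0107)
}

#' Mirrored isotopologue pattern of an incompletely labeled compound
#'
#' Relative intensities of M_full, M_full - 1, ... for a U-13C-labeled
#' compound with the given per-carbon purity: a binomial on the carbon
#' count with p(12C) = 1 - purity, decreasing toward lower mass.
#'
#' @param f formula (or string).
#' @param k number of isotopologues.
#' @param purity 13C incorporation fraction in (0, 1].
#' @return numeric vector of length k, first element 1.
#' @export
mirrored_pattern <- function(f, k = 3L, purity = 0.99) {
  stopifnot(k >= 1, purity > 0, purity <= 1)
  nC <- fcount(as_formula(f), "C")
  .binomial_pattern(nC, k, 1 - purity)
}

.binomial_pattern <- function(nC, k, p) {
  j <- seq_len(k) - 1
  out <- ifelse(j <= nC, choose(nC, j) * (p / (1 - p))^j, 0)
  out / out[1]
}

# carbon count of the ion emitted by a species for a compound
.ion_carbons <- function(comp, sp) {
  nC <- sp$multiplicity * fcount(comp$formula, "C")
  if (nzchar(sp$loss)) nC <- nC - fcount(as_formula(sp$loss), "C")
  max(nC, 0L)
}

#' Simulate an XCMS-style peak table with ground truth
#'
#' Every compound emits, per configured ion species: the 12C monoisotopic
#' peak with its natural isotopologues, and (when `label_abundance > 0`)
#' the fully 13C-labeled monoisotopic peak n carbons higher with its
#' mirrored isotopologues. Multimer species additionally emit the
#' mixed-label homoadduct (one labeled moiety, shift = carbon count of one
#' moiety). Analyte-specific `extra_fragments` emit `[M+H-loss]+`-type
#' pairs. Contaminant peaks are uniform in m/z and RT.
#'
#' @param compounds list of [gt_compound()].
#' @param noise [noise_model()].
#' @param cfg [sd_config()] providing the ion list and polarity.
#' @param min_abundance emission floor for isotopologue peaks.
#' @param max_isotopes isotopologues beyond the monoisotopic peak per chain.
#' @return list with `peaks` (data.frame: id, mz, rt, rtmin, rtmax, maxo,
#'   into, intb, sample) and `truth` (data.frame: peak_id, compound,
#'   species_label, expected_label, expected_role, isotope_index, labeled,
#'   n_shift, theo_mz).
#' @export
simulate_peak_table <- function(compounds, noise = noise_model(),
                                cfg = sd_config(), min_abundance = 500,
                                max_isotopes = 3L) {
  stopifnot(length(compounds) > 0)
  set.seed(noise$seed)
  labels <- vapply(cfg$ion_list, `[[`, "", "label")
  rows <- list(); truths <- list()
  emit <- function(theo_mz, rt, abundance, rt_sigma, compound, species_label,
                   expected_label, role, iso_idx, labeled, n_shift) {
    mz <- theo_mz + stats::rnorm(1, 0, noise$mz_sd)
    rt_obs <- rt + stats::rnorm(1, 0, noise$rt_jitter_sd)
    a <- abundance * max(1 + stats::rnorm(1, 0, noise$intensity_cv), 0.05)
    into <- a * rt_sigma * sqrt(2 * pi)
    rows[[length(rows) + 1L]] <<- data.frame(
      mz = mz, rt = rt_obs, rtmin = rt_obs - 2 * rt_sigma,
      rtmax = rt_obs + 2 * rt_sigma, maxo = a, into = into, intb = into,
      sample = "S1", stringsAsFactors = FALSE)
    truths[[length(truths) + 1L]] <<- data.frame(
      compound = compound, species_label = species_label,
      expected_label = expected_label, expected_role = role,
      isotope_index = iso_idx, labeled = labeled, n_shift = n_shift,
      theo_mz = theo_mz, stringsAsFactors = FALSE)
  }
  emit_chain <- function(mz0, rel, z, dir, rt, rt_sigma, A, compound,
                         species_label, expected_label, role, iso_role,
                         labeled, n_shift) {
    for (j in seq_along(rel)) {
      a <- A * rel[j]
      if (j > 1 && a < min_abundance) break
      emit(mz0 + dir * (j - 1) * .MASS$c13_delta / z, rt, a, rt_sigma,
           compound, species_label,
           if (j == 1) expected_label else
             sprintf("%s %s%di", expected_label, if (dir > 0) "[+" else "[-", j - 1),
           if (j == 1) role else iso_role, j - 1L, labeled, n_shift)
    }
  }

  for (comp in compounds) {
    M <- formula_mass(comp$formula)
    nC_M <- fcount(comp$formula, "C")
    for (si in seq_along(comp$species)) {
      lab <- names(comp$species)[si]
      yld <- comp$species[[si]]
      sp <- species_by_label(cfg, lab)
      if (is.null(sp)) stop("species '", lab, "' not in the ion list")
      z <- abs(sp$charge)
      nC_ion <- .ion_carbons(comp, sp)
      role12 <- if (sp$multiplicity > 1) "homoadduct"
                else if (sp$is_seed) "seed_adduct"
                else if (nzchar(sp$loss)) "fragment" else "adduct"
      rel12 <- natural_isotope_pattern(ms_formula(c(C = nC_ion)),
                                       max_isotopes + 1L)
      emit_chain(ion_mz(M, sp), rel12, z, +1, comp$rt, comp$rt_sigma,
                 comp$base_abundance * yld, comp$name, lab, lab, role12,
                 "isotope", FALSE, 0L)
      if (comp$label_abundance > 0) {
        if (sp$multiplicity == 1) {
          rel13 <- mirrored_pattern(ms_formula(c(C = nC_ion)),
                                    max_isotopes + 1L, comp$label_purity)
          emit_chain(ion_mz(M, sp, nC_ion), rel13, z, -1, comp$rt,
                     comp$rt_sigma, comp$label_abundance * yld, comp$name,
                     lab, shifted_label(lab, nC_ion), "c13_monoisotopic",
                     "c13_isotope", TRUE, nC_ion)
        } else {
          # mixed-label homoadduct: one 12C + one fully labeled moiety
          emit(ion_mz(M, sp, nC_M), comp$rt, comp$label_abundance * yld,
               comp$rt_sigma, comp$name, lab, shifted_label(lab, nC_M),
               "c13_monoisotopic", 0L, TRUE, nC_M)
        }
      }
    }
    for (li in seq_along(comp$extra_fragments)) {
      loss <- names(comp$extra_fragments)[li]
      yld <- comp$extra_fragments[[li]]
      frag <- formula_arith(comp$formula, loss, "subtract")
      nC_f <- fcount(frag, "C")
      sgn <- if (cfg$mode == "positive") "+" else "-"
      lab12 <- sprintf("[M%sH-%s]%s", sgn, loss, sgn)
      frag_mass <- formula_mass(frag)
      mz0 <- if (cfg$mode == "positive") frag_mass + .MASS$proton_mass
             else frag_mass - .MASS$proton_mass
      rel12 <- natural_isotope_pattern(frag, max_isotopes + 1L)
      emit_chain(mz0, rel12, 1L, +1, comp$rt, comp$rt_sigma,
                 comp$base_abundance * yld, comp$name, lab12, lab12,
                 "uncommon_fragment", "isotope", FALSE, 0L)
      if (comp$label_abundance > 0 && nC_f > 0) {
        rel13 <- mirrored_pattern(frag, max_isotopes + 1L, comp$label_purity)
        emit_chain(mz0 + nC_f * .MASS$c13_delta, rel13, 1L, -1, comp$rt,
                   comp$rt_sigma, comp$label_abundance * yld, comp$name,
                   lab12, shifted_label(lab12, nC_f), "c13_monoisotopic",
                   "c13_isotope", TRUE, nC_f)
      }
    }
  }
  if (noise$n_contaminants > 0) {
    rt_range <- range(vapply(compounds, `[[`, 0, "rt"))
    for (k in seq_len(noise$n_contaminants)) {
      emit(stats::runif(1, 80, 600),
           stats::runif(1, max(rt_range[1] - 60, 10), rt_range[2] + 60),
           stats::runif(1, 1e3, 1e5), 3, "<contaminant>", "",
           "", "contaminant", 0L, FALSE, 0L)
    }
  }
  peaks <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  peaks$id <- sprintf("P%03d", seq_len(nrow(peaks)))
  truth$peak_id <- peaks$id
  peaks <- peaks[, c("id", "mz", "rt", "rtmin", "rtmax", "maxo", "into",
                     "intb", "sample")]
  truth <- truth[, c("peak_id", "compound", "species_label", "expected_label",
                     "expected_role", "isotope_index", "labeled", "n_shift",
                     "theo_mz")]
  list(peaks = peaks, truth = truth,
       compounds = compounds, noise = noise)
}

#' Simulate EIC traces for a generated peak table
#'
#' Gaussian profiles; all peaks of one compound share the same underlying
#' retention-time profile (pairwise Pearson correlation ~ 1), contaminants
#' get independent profiles centered on their own RT.
#'
#' @param sim result of [simulate_peak_table()].
#' @param grid scan interval, seconds (> 0).
#' @param span half-width of the simulated window in units of rt_sigma.
#' @return named list of data.frames (`rt`, `intensity`) keyed by peak id.
#' @export
simulate_eics <- function(sim, grid = 0.5, span = 4) {
  stopifnot(is.numeric(grid), grid > 0)
  comp_rt <- stats::setNames(vapply(sim$compounds, `[[`, 0, "rt"),
                             vapply(sim$compounds, `[[`, "", "name"))
  comp_sigma <- stats::setNames(vapply(sim$compounds, `[[`, 0, "rt_sigma"),
                                vapply(sim$compounds, `[[`, "", "name"))
  eics <- list()
  for (i in seq_len(nrow(sim$peaks))) {
    id <- sim$peaks$id[i]
    cname <- sim$truth$compound[sim$truth$peak_id == id]
    if (cname %in% names(comp_rt)) {
      center <- comp_rt[[cname]]; sigma <- comp_sigma[[cname]]
    } else {
      center <- sim$peaks$rt[i]; sigma <- 3
    }
    ts <- seq(center - span * sigma, center + span * sigma, by = grid)
    eics[[id]] <- data.frame(
      rt = ts,
      intensity = sim$peaks$maxo[i] * exp(-(ts - center)^2 / (2 * sigma^2)))
  }
  eics
}

#' Built-in simulation scenarios
#'
#' Four presets exercising the main pipeline paths:
#' \describe{
#'   \item{glutamate}{C5H9NO4 with six 12C ion species (seeds, water and
#'     formic-acid losses, `[2M+H]+` and the mixed-label `[2M+5+H]+`) plus
#'     labeled counterparts.}
#'   \item{glu_met_dipeptide}{C10H18N2O5S emitting the y1'' residue
#'     fragment via an uncommon C5H7NO3 loss — the sum-formula-triplet
#'     path.}
#'   \item{coeluting_pair}{glutamate with consecutive small losses whose
#'     fragment peaks also assemble into a second spectrum at M = 129.04 —
#'     the [claim_peaks()] scenario. Use the bundled `cfg`, which extends
#'     the ion list by the combined `[M+H-HCOOH-H2O]+` loss.}
#'   \item{unlabeled_standard_missing}{N-acetylglutamate-like compound with
#'     no 13C internal standard (undefined isotopomer ratios).}
#' }
#'
#' @return named list; each preset has `compounds` (list of
#'   [gt_compound()]) and `cfg` (an [sd_config()] suited to it).
#' @export
preset_scenarios <- function() {
  cfg <- sd_config()
  combined_loss <- ion_species("[M+H-HCOOH-H2O]+",
                               .MASS$proton_mass - formula_mass("CH4O3"),
                               +1L, 1L, FALSE, "positive", loss = "CH4O3")
  cfg_co <- sd_config(ion_list = c(default_ion_list("positive"),
                                   list(combined_loss)))
  list(
    glutamate = list(
      compounds = list(gt_compound(
        "glutamate", "C5H9NO4", rt = 287.92, base_abundance = 1e6,
        label_abundance = 5e5,
        species = c("[M+H]+" = 1.0, "[M+Na]+" = 0.3, "[M+H-H2O]+" = 0.25,
                    "[M+H-HCOOH]+" = 0.15, "[2M+H]+" = 0.05))),
      cfg = cfg),
    glu_met_dipeptide = list(
      compounds = list(gt_compound(
        "glutamyl-methionine", "C10H18N2O5S", rt = 350, base_abundance = 8e5,
        label_abundance = 4e5,
        species = c("[M+H]+" = 1.0, "[M+Na]+" = 0.2, "[M+H-NH3]+" = 0.2),
        extra_fragments = c("C5H7NO3" = 0.3))),
      cfg = cfg),
    coeluting_pair = list(
      compounds = list(gt_compound(
        "glutamate", "C5H9NO4", rt = 287.92, base_abundance = 1e6,
        label_abundance = 5e5,
        species = c("[M+H]+" = 1.0, "[M+Na]+" = 0.3, "[M+H-H2O]+" = 0.25,
                    "[M+H-HCOOH]+" = 0.15, "[M+H-HCOOH-H2O]+" = 0.1))),
      cfg = cfg_co),
    unlabeled_standard_missing = list(
      compounds = list(gt_compound(
        "N-acetylglutamate", "C7H11NO5", rt = 420, base_abundance = 3e5,
        label_abundance = 0,
        species = c("[M+H]+" = 1.0, "[M+Na]+" = 0.2, "[M+H-H2O]+" = 0.2))),
      cfg = cfg)
  )
}

#' Fetch one preset by name
#' @param name preset name, see [preset_scenarios()].
#' @return the preset list.
#' @export
preset_scenario <- function(name) {
  ps <- preset_scenarios()
  if (!name %in% names(ps)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(ps), collapse = ", "))
  }
  ps[[name]]
}
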