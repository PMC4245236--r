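# Seven-step pseudo-spectrum deconvolution:
#   1 read peaks  2 isotope chains (natural + mirrored)  3 seed-adduct
#   assembly  4 12C/13C pair association  5 homoadducts  6 uncommon-loss
#   triplets  7 correlation pruning
# plus the curation operations (claim peaks, orphan browsing, find
# correlating peaks).

#' Deconvolution configuration
#'
#' @param eps_rt allowed retention-time error between peaks, seconds.
#' @param eps_mz accepted m/z error, Da.
#' @param labeled TRUE for U-13C internal-standard experiments: enables the
#'   mirrored-isotope pass, 12C/13C pair association and uncommon-loss
#'   annotation.
#' @param correlation_threshold minimum EIC Pearson correlation of a member
#'   to the primary peak (step 7); pruning only runs when EIC traces exist.
#' @param max_isotopes maximum isotopologues beyond the monoisotopic peak
#'   in one chain.
#' @param isotope_slack multiplicative slack on the decreasing-intensity
#'   rule (0.05 tolerates 5 percent integration noise).
#' @param mode acquisition polarity, `"positive"` or `"negative"`.
#' @param ion_list list of [ion_species()]; default [default_ion_list()].
#' @param bounds [element_bounds()] used for carbon-range vetting.
#' @param decomp_tol mass tolerance (Da) for decompositions inside steps
#'   4 and 6.
#' @return list of class `sd_config`.
#' @export
sd_config <- function(eps_rt = 5, eps_mz = 0.005, labeled = TRUE,
                      correlation_threshold = 0.85, max_isotopes = 4L,
                      isotope_slack = 0.05,
                      mode = c("positive", "negative"),
                      ion_list = NULL, bounds = element_bounds(),
                      decomp_tol = 0.005) {
  mode <- match.arg(mode)
  stopifnot(eps_rt > 0, eps_mz > 0,
            correlation_threshold >= 0, correlation_threshold <= 1)
  if (is.null(ion_list)) ion_list <- default_ion_list(mode)
  structure(list(eps_rt = eps_rt, eps_mz = eps_mz, labeled = labeled,
                 correlation_threshold = correlation_threshold,
                 max_isotopes = as.integer(max_isotopes),
                 isotope_slack = isotope_slack, mode = mode,
                 ion_list = ion_list, bounds = bounds,
                 decomp_tol = decomp_tol),
            class = "sd_config")
}

validate_peaks <- function(peaks) {
  need <- c("id", "mz", "rt")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0) stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("rtmin", "rtmax")) if (is.null(peaks[[col]])) peaks[[col]] <- peaks$rt
  for (col in c("maxo", "into", "intb")) if (is.null(peaks[[col]])) peaks[[col]] <- NA_real_
  if (is.null(peaks$sample)) peaks$sample <- "S1"
  if (anyDuplicated(peaks$id)) stop("peak ids must be unique")
  if (any(peaks$mz <= 0)) stop("non-positive m/z in peak table")
  peaks$id <- as.character(peaks$id)
  peaks
}

peak_intensity <- function(peaks) {
  # apex intensity drives ordering decisions; fall back to area
  ifelse(is.na(peaks$maxo), ifelse(is.na(peaks$into), 0, peaks$into), peaks$maxo)
}

# ---------------------------------------------------------------------------
# Step 2: isotope chains

#' Detect natural and mirrored isotope chains
#'
#' Natural chains climb from a monoisotopic peak in steps of 1.003355/z Da
#' (z in 1:2) with decreasing intensity; mirrored chains (labeled
#' experiments) descend from a candidate fully-13C-labeled monoisotopic
#' peak toward lower m/z, again with decreasing intensity. A peak joins at
#' most one chain per direction.
#'
#' @param peaks peak data.frame (columns id, mz, rt, intensity columns).
#' @param cfg [sd_config()].
#' @return list of chains, each `list(monoisotopic, members, charge,
#'   mirrored)` with members ordered starting at the monoisotopic peak.
#' @export
detect_isotope_chains <- function(peaks, cfg = sd_config()) {
  peaks <- validate_peaks(peaks)
  if (nrow(peaks) < 2) return(list())
  ints <- peak_intensity(peaks)
  ord <- order(-ints, peaks$mz, peaks$id)  # strongest seeds first
  chains <- list()
  for (mirrored in if (cfg$labeled) c(FALSE, TRUE) else FALSE) {
    used <- character(0)
    dir <- if (mirrored) -1 else 1
    for (i in ord) {
      seed_id <- peaks$id[i]
      if (seed_id %in% used) next
      best <- NULL
      for (z in c(1L, 2L)) {
        members <- seed_id
        prev_int <- ints[i]
        prev_mz <- peaks$mz[i]
        for (k in seq_len(cfg$max_isotopes)) {
          target <- prev_mz + dir * .MASS$c13_delta / z
          cand <- which(!(peaks$id %in% used) & !(peaks$id %in% members) &
                          abs(peaks$mz - target) <= cfg$eps_mz &
                          abs(peaks$rt - peaks$rt[i]) <= cfg$eps_rt &
                          ints < prev_int * (1 + cfg$isotope_slack) &
                          ints < ints[i])
          if (length(cand) == 0) break
          j <- cand[which.min(abs(peaks$mz[cand] - target))]
          members <- c(members, peaks$id[j])
          prev_int <- ints[j]
          prev_mz <- peaks$mz[j]
        }
        if (length(members) >= 2 &&
            (is.null(best) || length(members) > length(best$members))) {
          best <- list(monoisotopic = seed_id, members = members,
                       charge = z, mirrored = mirrored)
        }
      }
      if (!is.null(best)) {
        chains[[length(chains) + 1L]] <- best
        used <- c(used, best$members)
      }
    }
  }
  chains
}

chain_lookup <- function(chains) {
  # per direction: map peak id -> chain index, and the set of non-mono members
  nat <- list(); mir <- list()
  nat_nonmono <- character(0); mir_members <- character(0)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    if (ch$mirrored) {
      mir_members <- c(mir_members, ch$members)
      for (id in ch$members) mir[[id]] <- ci
    } else {
      nat_nonmono <- c(nat_nonmono, ch$members[-1])
      for (id in ch$members) nat[[id]] <- ci
    }
  }
  list(nat = nat, mir = mir, nat_nonmono = nat_nonmono, mir_members = mir_members)
}

peak_charge <- function(id, chains, lk) {
  ci <- lk$nat[[id]]
  if (!is.null(ci)) return(chains[[ci]]$charge)
  ci <- lk$mir[[id]]
  if (!is.null(ci)) return(chains[[ci]]$charge)
  NA_integer_
}

# ---------------------------------------------------------------------------
# Pseudo-spectrum container helpers

empty_annotations <- function() {
  data.frame(peak_id = character(0), ion_label = character(0),
             species_label = character(0), role = character(0),
             n_shift = integer(0), loss_formula = character(0),
             ambiguous = logical(0), parent_id = character(0),
             corr = numeric(0), stringsAsFactors = FALSE)
}

annot_row <- function(peak_id, ion_label, species_label, role, n_shift = 0L,
                      loss_formula = NA_character_, ambiguous = FALSE,
                      parent_id = NA_character_, corr = NA_real_) {
  data.frame(peak_id = peak_id, ion_label = ion_label,
             species_label = species_label, role = role,
             n_shift = as.integer(n_shift), loss_formula = loss_formula,
             ambiguous = ambiguous, parent_id = parent_id, corr = corr,
             stringsAsFactors = FALSE)
}

new_pseudo_spectrum <- function(M, rt, primary, annotations,
                                status = "auto", compound_name = NA_character_) {
  structure(list(id = sprintf("M%.3fT%.2f", M, rt), M = M, rt = rt,
                 primary = primary, annotations = annotations,
                 status = status, compound_name = compound_name),
            class = "pseudo_spectrum")
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf("<pseudo spectrum %s> M=%.4f rt=%.2fs status=%s\n",
              x$id, x$M, x$rt, x$status))
  print(x$annotations[, c("peak_id", "ion_label", "role", "ambiguous")])
  invisible(x)
}

spectra_members <- function(spectra) {
  unique(unlist(lapply(spectra, function(s) s$annotations$peak_id)))
}

# attach natural-chain isotopologues of a member peak
isotope_annots <- function(peak_id, base_label, chains, lk) {
  ci <- lk$nat[[peak_id]]
  if (is.null(ci) || chains[[ci]]$monoisotopic != peak_id) return(empty_annotations())
  mem <- chains[[ci]]$members[-1]
  do.call(rbind, lapply(seq_along(mem), function(k) {
    annot_row(mem[k], sprintf("%s [+%di]", base_label, k), base_label,
              "isotope", parent_id = peak_id)
  }))
}

mirrored_isotope_annots <- function(peak_id, base_label, chains, lk) {
  ci <- lk$mir[[peak_id]]
  if (is.null(ci) || chains[[ci]]$monoisotopic != peak_id) return(empty_annotations())
  mem <- chains[[ci]]$members[-1]
  do.call(rbind, lapply(seq_along(mem), function(k) {
    annot_row(mem[k], sprintf("%s [-%di]", base_label, k), base_label,
              "c13_isotope", parent_id = peak_id)
  }))
}

# ---------------------------------------------------------------------------
# Step 3: seed-adduct pseudo-spectrum assembly

#' Assemble pseudo spectra from seed-adduct mass relations
#'
#' For every 12C monoisotopic peak and every ion species compatible with its
#' charge, the implied neutral mass is computed; hypotheses agreeing on M
#' (within `eps_mz`) and retention time (within `eps_rt`) are clustered. A
#' cluster with at least two distinct peaks, one of them explained by a seed
#' adduct, becomes a pseudo spectrum. Peaks may initially belong to several
#' pseudo spectra; [claim_peaks()] resolves such multi-memberships.
#'
#' @param peaks peak table.
#' @param chains output of [detect_isotope_chains()].
#' @param cfg [sd_config()].
#' @return list of `pseudo_spectrum` objects ordered by (M, rt).
#' @export
assemble_pseudo_spectra <- function(peaks, chains, cfg = sd_config()) {
  peaks <- validate_peaks(peaks)
  lk <- chain_lookup(chains)
  mono12 <- setdiff(peaks$id, c(lk$nat_nonmono, lk$mir_members))
  if (length(mono12) < 2) return(list())
  ints <- stats::setNames(peak_intensity(peaks), peaks$id)
  prow <- match(mono12, peaks$id)

  hyp <- list()
  for (k in seq_along(mono12)) {
    id <- mono12[k]
    i <- prow[k]
    z <- peak_charge(id, chains, lk)
    for (si in seq_along(cfg$ion_list)) {
      sp <- cfg$ion_list[[si]]
      if (sp$mode != cfg$mode) next
      zsp <- abs(sp$charge)
      if (is.na(z)) { if (zsp != 1L) next } else if (zsp != z) next
      M <- tryCatch(neutral_mass_from_mz(peaks$mz[i], sp), error = function(e) NA)
      if (is.na(M)) next
      hyp[[length(hyp) + 1L]] <- list(id = id, row = i, si = si, M = M,
                                      rt = peaks$rt[i])
    }
  }
  if (length(hyp) == 0) return(list())
  hM <- vapply(hyp, `[[`, 0, "M")
  ohyp <- order(hM)
  hyp <- hyp[ohyp]; hM <- hM[ohyp]

  # single-linkage clustering on M, then on rt within each M cluster
  brk <- which(diff(hM) > cfg$eps_mz)
  starts <- c(1L, brk + 1L); ends <- c(brk, length(hM))
  spectra <- list()
  for (g in seq_along(starts)) {
    grp <- hyp[starts[g]:ends[g]]
    rts <- vapply(grp, `[[`, 0, "rt")
    ort <- order(rts)
    grp <- grp[ort]; rts <- rts[ort]
    rbrk <- which(diff(rts) > cfg$eps_rt)
    rstarts <- c(1L, rbrk + 1L); rends <- c(rbrk, length(rts))
    for (h in seq_along(rstarts)) {
      sub <- grp[rstarts[h]:rends[h]]
      ids <- vapply(sub, `[[`, "", "id")
      if (length(unique(ids)) < 2) next
      seed_idx <- which(vapply(sub, function(x) cfg$ion_list[[x$si]]$is_seed, TRUE))
      if (length(seed_idx) == 0) next
      # one species per peak: ion-list order is the priority; extra matches
      # mark the kept annotation as ambiguous
      keep <- integer(0)
      ambig <- logical(0)
      for (id in unique(ids)) {
        cand <- which(ids == id)
        cand <- cand[order(vapply(sub[cand], `[[`, 0L, "si"))]
        keep <- c(keep, cand[1])
        ambig <- c(ambig, length(cand) > 1)
      }
      sub <- sub[keep]
      seed_idx <- which(vapply(sub, function(x) cfg$ion_list[[x$si]]$is_seed, TRUE))
      if (length(seed_idx) == 0) next
      # primary: pseudo-molecular ion if present, else strongest seed peak
      pm <- which(vapply(sub, function(x) {
        cfg$ion_list[[x$si]]$label %in% c("[M+H]+", "[M-H]-")
      }, TRUE))
      prim_i <- if (length(pm) > 0) pm[1] else {
        seed_idx[which.max(ints[vapply(sub[seed_idx], `[[`, "", "id")])]
      }
      M <- sub[[prim_i]]$M
      rt <- peaks$rt[sub[[prim_i]]$row]
      ann <- empty_annotations()
      for (j in seq_along(sub)) {
        sp <- cfg$ion_list[[sub[[j]]$si]]
        role <- if (sp$multiplicity > 1) "homoadduct"
                else if (sp$is_seed) "seed_adduct"
                else if (nzchar(sp$loss)) "fragment" else "adduct"
        ann <- rbind(ann, annot_row(sub[[j]]$id, sp$label, sp$label, role,
                                    ambiguous = ambig[j]))
        ann <- rbind(ann, isotope_annots(sub[[j]]$id, sp$label, chains, lk))
      }
      spectra[[length(spectra) + 1L]] <-
        new_pseudo_spectrum(M, rt, sub[[prim_i]]$id, ann)
    }
  }
  # deterministic order; drop exact duplicates (same M id + same members)
  if (length(spectra) > 1) {
    key <- vapply(spectra, function(s) {
      paste(s$id, paste(sort(s$annotations$peak_id), collapse = ","))
    }, "")
    spectra <- spectra[!duplicated(key)]
    om <- order(vapply(spectra, `[[`, 0, "M"), vapply(spectra, `[[`, 0, "rt"))
    spectra <- spectra[om]
  }
  spectra
}

# ---------------------------------------------------------------------------
# Step 4: 12C/13C label-pair association

species_by_label <- function(cfg, label) {
  for (sp in cfg$ion_list) if (sp$label == label) return(sp)
  NULL
}

# neutral mass of the (possibly fragmented) moiety behind an annotation;
# carbon-range vetting happens on this mass
implied_neutral <- function(M, sp) {
  nm <- sp$multiplicity * M
  if (nzchar(sp$loss)) nm <- nm - formula_mass(sp$loss)
  nm
}

#' Associate 13C monoisotopic peaks with their 12C counterparts
#'
#' For every 12C annotation in every pseudo spectrum, candidate 13C peaks
#' (monoisotopic peaks of mirrored chains) at a distance of n x 1.003355/z
#' Da are vetted: n must be a natural number and lie in the carbon-count
#' range of the annotation's implied neutral mass (by mass decomposition).
#' Accepted partners are annotated in the spectrum with a shifted label
#' (e.g. `[M+5+H]+`).
#'
#' @param spectra list of pseudo spectra (modified and returned).
#' @param peaks peak table.
#' @param chains isotope chains.
#' @param cfg [sd_config()].
#' @return list with `spectra` (updated) and `label_pairs` (data.frame
#'   spectrum_id, c12_peak, c13_peak, n, charge).
#' @export
associate_label_pairs <- function(spectra, peaks, chains, cfg = sd_config()) {
  peaks <- validate_peaks(peaks)
  lk <- chain_lookup(chains)
  pairs <- data.frame(spectrum_id = character(0), c12_peak = character(0),
                      c13_peak = character(0), n = integer(0),
                      charge = integer(0), stringsAsFactors = FALSE)
  if (!cfg$labeled || length(spectra) == 0) {
    return(list(spectra = spectra, label_pairs = pairs))
  }
  mir_monos <- unique(vapply(Filter(function(ch) ch$mirrored, chains),
                             `[[`, "", "monoisotopic"))
  assigned <- spectra_members(spectra)
  cand13 <- setdiff(mir_monos, assigned)
  if (length(cand13) == 0) return(list(spectra = spectra, label_pairs = pairs))
  pidx <- stats::setNames(seq_len(nrow(peaks)), peaks$id)

  proposals <- list()
  for (sidx in seq_along(spectra)) {
    s <- spectra[[sidx]]
    ann <- s$annotations
    top <- ann[ann$role %in% c("seed_adduct", "adduct", "fragment"), , drop = FALSE]
    for (r in seq_len(nrow(top))) {
      sp <- species_by_label(cfg, top$species_label[r])
      if (is.null(sp) || sp$multiplicity != 1) next
      z <- abs(sp$charge)
      i12 <- pidx[[top$peak_id[r]]]
      nm <- implied_neutral(s$M, sp)
      if (nm <= 0) next
      crange <- carbon_count_range(nm, cfg$decomp_tol, cfg$bounds)
      if (length(crange) == 0) next
      for (qid in cand13) {
        q <- pidx[[qid]]
        if (abs(peaks$rt[q] - s$rt) > cfg$eps_rt) next
        if (peaks$mz[q] <= peaks$mz[i12]) next
        n <- round((peaks$mz[q] - peaks$mz[i12]) * z / .MASS$c13_delta)
        if (n < 1) next
        resid <- abs(peaks$mz[q] - (peaks$mz[i12] + n * .MASS$c13_delta / z))
        if (resid > cfg$eps_mz) next
        if (!(n %in% crange)) next
        proposals[[length(proposals) + 1L]] <-
          list(sidx = sidx, c12 = top$peak_id[r], c13 = qid, n = as.integer(n),
               z = z, resid = resid, label = top$species_label[r])
      }
    }
  }
  if (length(proposals) == 0) return(list(spectra = spectra, label_pairs = pairs))
  proposals <- proposals[order(vapply(proposals, `[[`, 0, "resid"),
                               vapply(proposals, `[[`, "", "c13"))]
  # one partner per 12C annotation and one use per 13C peak -- within each
  # spectrum; across spectra multi-membership is allowed until claim_peaks
  used12 <- character(0); used13 <- character(0)
  for (p in proposals) {
    key12 <- paste(p$sidx, p$c12)
    key13 <- paste(p$sidx, p$c13)
    if (key12 %in% used12 || key13 %in% used13) next
    used12 <- c(used12, key12); used13 <- c(used13, key13)
    lab <- shifted_label(p$label, p$n)
    s <- spectra[[p$sidx]]
    s$annotations <- rbind(
      s$annotations,
      annot_row(p$c13, lab, p$label, "c13_monoisotopic", n_shift = p$n,
                parent_id = p$c12),
      mirrored_isotope_annots(p$c13, lab, chains, chain_lookup(chains))
    )
    spectra[[p$sidx]] <- s
    pairs <- rbind(pairs, data.frame(spectrum_id = s$id, c12_peak = p$c12,
                                     c13_peak = p$c13, n = p$n, charge = p$z,
                                     stringsAsFactors = FALSE))
  }
  list(spectra = spectra, label_pairs = pairs)
}

# ---------------------------------------------------------------------------
# Step 5: homoadducts

#' Annotate homoadducts (multi-mass ions) of known pseudo spectra
#'
#' With M known, multimer species (multiplicity >= 2) are predicted
#' directly, including mixed-label shifts: for a labeled experiment the
#' dimer of one unlabeled and one fully labeled moiety appears n carbons
#' higher (`[2M+n+H]+`), the doubly labeled dimer 2n higher.
#'
#' @param spectra list of pseudo spectra.
#' @param peaks peak table.
#' @param chains isotope chains.
#' @param cfg [sd_config()].
#' @return updated spectra list.
#' @export
detect_homoadducts <- function(spectra, peaks, chains, cfg = sd_config()) {
  peaks <- validate_peaks(peaks)
  lk <- chain_lookup(chains)
  multimers <- Filter(function(sp) sp$multiplicity > 1 && sp$mode == cfg$mode,
                      cfg$ion_list)
  if (length(multimers) == 0 || length(spectra) == 0) return(spectra)
  for (sidx in seq_along(spectra)) {
    s <- spectra[[sidx]]
    shifts <- 0L
    if (cfg$labeled) {
      crange <- carbon_count_range(s$M, cfg$decomp_tol, cfg$bounds)
      shifts <- sort(unique(c(0L, crange, 2L * crange)))
    }
    for (sp in multimers) {
      for (n in shifts) {
        theo <- ion_mz(s$M, sp, n)
        cand <- which(abs(peaks$mz - theo) <= cfg$eps_mz &
                        abs(peaks$rt - s$rt) <= cfg$eps_rt &
                        !(peaks$id %in% s$annotations$peak_id) &
                        !(peaks$id %in% lk$nat_nonmono))
        if (length(cand) == 0) next
        j <- cand[which.min(abs(peaks$mz[cand] - theo))]
        lab <- shifted_label(sp$label, n)
        role <- if (n == 0) "homoadduct" else "c13_monoisotopic"
        s$annotations <- rbind(
          s$annotations,
          annot_row(peaks$id[j], lab, sp$label, role, n_shift = n),
          if (n == 0) isotope_annots(peaks$id[j], lab, chains, lk)
          else mirrored_isotope_annots(peaks$id[j], lab, chains, lk)
        )
      }
    }
    spectra[[sidx]] <- s
  }
  spectra
}

# ---------------------------------------------------------------------------
# Step 6: uncommon neutral losses via sum-formula triplets

#' Annotate large uncommon neutral losses using 13C carbon counts
#'
#' For a pseudo spectrum whose pseudo-molecular ion has an associated 13C
#' partner (carbon count n_p), every still-unassigned 12C/13C peak pair
#' below the primary m/z (carbon count n_f) is tested: the primary mass is
#' decomposed with exactly n_p carbons (S_p), the fragment with n_f (S_f)
#' and the loss mass with n_p - n_f carbons (S_l). If at least one triplet
#' satisfies s_p = s_f + s_l the pair is annotated as `[M+H-loss]+`; the
#' loss formula is recorded when the triplet is unique, otherwise the
#' annotation is flagged ambiguous.
#'
#' @param spectra list of pseudo spectra.
#' @param peaks peak table.
#' @param label_pairs data.frame from [associate_label_pairs()].
#' @param chains isotope chains.
#' @param cfg [sd_config()].
#' @return list with updated `spectra` and `label_pairs` (fragment pairs
#'   appended).
#' @export
annotate_uncommon_losses <- function(spectra, peaks, label_pairs, chains,
                                     cfg = sd_config()) {
  peaks <- validate_peaks(peaks)
  if (!cfg$labeled || length(spectra) == 0) {
    return(list(spectra = spectra, label_pairs = label_pairs))
  }
  lk <- chain_lookup(chains)
  pm_label <- if (cfg$mode == "positive") "[M+H]+" else "[M-H]-"
  sgn <- if (cfg$mode == "positive") 1 else -1
  pidx <- stats::setNames(seq_len(nrow(peaks)), peaks$id)
  # snapshot of the unassigned set: every spectrum sees the same orphan
  # pool, so one orphan pair may be explained by several spectra
  # (multi-membership, resolved by claim_peaks)
  assigned0 <- spectra_members(spectra)

  for (sidx in seq_along(spectra)) {
    s <- spectra[[sidx]]
    prim <- s$annotations[s$annotations$species_label == pm_label &
                            s$annotations$role == "seed_adduct", , drop = FALSE]
    if (nrow(prim) == 0) next
    lp <- label_pairs[label_pairs$spectrum_id == s$id &
                        label_pairs$c12_peak == prim$peak_id[1], , drop = FALSE]
    if (nrow(lp) == 0) next  # primary lacks a 13C partner: skip
    n_p <- lp$n[1]
    S_p <- decompose_mass(decomp_query(s$M, cfg$decomp_tol, cfg$bounds,
                                       fixed_carbon = n_p))
    if (nrow(S_p) == 0) next
    prim_mz <- peaks$mz[pidx[[prim$peak_id[1]]]]

    orphans <- peaks[!(peaks$id %in% assigned0) &
                       abs(peaks$rt - s$rt) <= cfg$eps_rt, , drop = FALSE]
    if (nrow(orphans) < 2) next
    orphans <- orphans[order(orphans$mz), , drop = FALSE]
    for (a in seq_len(nrow(orphans) - 1)) {
      if (orphans$mz[a] >= prim_mz) break
      for (b in (a + 1):nrow(orphans)) {
        n_f <- round((orphans$mz[b] - orphans$mz[a]) / .MASS$c13_delta)
        if (n_f < 1 || n_f >= n_p) next
        resid <- abs(orphans$mz[b] - (orphans$mz[a] + n_f * .MASS$c13_delta))
        if (resid > cfg$eps_mz) next
        frag_neutral <- orphans$mz[a] - sgn * .MASS$proton_mass
        loss_mass <- s$M - frag_neutral
        if (frag_neutral <= 0 || loss_mass <= 0) next
        S_f <- decompose_mass(decomp_query(frag_neutral, cfg$decomp_tol,
                                           cfg$bounds, fixed_carbon = n_f))
        if (nrow(S_f) == 0) next
        S_l <- decompose_mass(decomp_query(loss_mass, cfg$decomp_tol,
                                           cfg$bounds,
                                           fixed_carbon = n_p - n_f))
        if (nrow(S_l) == 0) next
        trip <- .find_triplets(S_p, S_f, S_l)
        if (nrow(trip) == 0) next
        uniq <- nrow(trip) == 1
        loss_str <- trip$loss[1]
        base <- sub("\\+$|-$", "", pm_label)  # "[M+H]" / "[M-H]"
        chg <- if (cfg$mode == "positive") "+" else "-"
        lab12 <- sprintf("%s-%s]%s", sub("\\]$", "", base), loss_str, chg)
        lab13 <- shifted_label(lab12, n_f)
        s$annotations <- rbind(
          s$annotations,
          annot_row(orphans$id[a], lab12, pm_label, "fragment",
                    loss_formula = if (uniq) loss_str else NA_character_,
                    ambiguous = !uniq),
          isotope_annots(orphans$id[a], lab12, chains, lk),
          annot_row(orphans$id[b], lab13, pm_label, "c13_monoisotopic",
                    n_shift = n_f, parent_id = orphans$id[a],
                    ambiguous = !uniq),
          mirrored_isotope_annots(orphans$id[b], lab13, chains, lk)
        )
        label_pairs <- rbind(label_pairs,
                             data.frame(spectrum_id = s$id,
                                        c12_peak = orphans$id[a],
                                        c13_peak = orphans$id[b],
                                        n = as.integer(n_f), charge = 1L,
                                        stringsAsFactors = FALSE))
        spectra[[sidx]] <- s
        break  # this 12C orphan is now explained
      }
    }
    spectra[[sidx]] <- s
  }
  list(spectra = spectra, label_pairs = label_pairs)
}

.find_triplets <- function(S_p, S_f, S_l) {
  out <- data.frame(primary = character(0), fragment = character(0),
                    loss = character(0), stringsAsFactors = FALSE)
  for (fi in seq_len(nrow(S_f))) {
    for (li in seq_len(nrow(S_l))) {
      sum_str <- format_formula(formula_arith(S_f$formula[fi], S_l$formula[li]))
      if (sum_str %in% S_p$formula) {
        out <- rbind(out, data.frame(primary = sum_str,
                                     fragment = S_f$formula[fi],
                                     loss = S_l$formula[li],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Step 7: correlation pruning + curation tools

#' Pearson correlation of two peaks' EIC traces
#'
#' Traces are intersected on their overlapping retention-time window and
#' the second trace is linearly interpolated onto the grid of the first.
#' Returns `NA` when correlation is unavailable (missing trace, no overlap,
#' or a constant trace) — distinct from a low value.
#'
#' @param eic_a,eic_b data.frames with columns `rt` and `intensity`.
#' @return Pearson coefficient in \[-1, 1\], or `NA`.
#' @export
eic_correlation <- function(eic_a, eic_b) {
  if (is.null(eic_a) || is.null(eic_b)) return(NA_real_)
  lo <- max(min(eic_a$rt), min(eic_b$rt))
  hi <- min(max(eic_a$rt), max(eic_b$rt))
  grid <- eic_a$rt[eic_a$rt >= lo & eic_a$rt <= hi]
  if (length(grid) < 3) return(NA_real_)
  ya <- eic_a$intensity[eic_a$rt >= lo & eic_a$rt <= hi]
  yb <- stats::approx(eic_b$rt, eic_b$intensity, xout = grid, rule = 2)$y
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) return(NA_real_)
  stats::cor(ya, yb)
}

#' Remove poorly correlating members from pseudo spectra
#'
#' Members whose EIC correlation to the primary peak falls below the
#' configured threshold are removed (together with their dependent isotope
#' annotations). The primary is always retained. Members without an
#' available correlation are retained and left with `corr = NA`
#' (unverified). When no EICs are given at all, pruning is skipped with a
#' warning: peak tables alone cannot support peak-shape correlation.
#'
#' @param spectra list of pseudo spectra.
#' @param eics named list of EIC data.frames keyed by peak id, or NULL.
#' @param cfg [sd_config()].
#' @return updated spectra list.
#' @export
prune_by_correlation <- function(spectra, eics, cfg = sd_config()) {
  if (is.null(eics) || length(eics) == 0) {
    warning("no EIC traces available; correlation pruning skipped")
    return(spectra)
  }
  for (sidx in seq_along(spectra)) {
    s <- spectra[[sidx]]
    prim_eic <- eics[[s$primary]]
    ann <- s$annotations
    drop_ids <- character(0)
    for (r in seq_len(nrow(ann))) {
      pid <- ann$peak_id[r]
      if (pid == s$primary || !is.na(ann$parent_id[r])) next
      cc <- eic_correlation(eics[[pid]], prim_eic)
      ann$corr[r] <- cc
      if (!is.na(cc) && cc < cfg$correlation_threshold) {
        drop_ids <- c(drop_ids, pid)
      }
    }
    if (length(drop_ids) > 0) {
      ann <- ann[!(ann$peak_id %in% drop_ids) &
                   !(ann$parent_id %in% drop_ids), , drop = FALSE]
    }
    s$annotations <- ann
    spectra[[sidx]] <- s
  }
  spectra
}

#' Claim peaks for one pseudo spectrum
#'
#' Removes the claimed peaks (and their dependent isotope annotations) from
#' every other pseudo spectrum, guaranteeing that each claimed peak is a
#' member of exactly one spectrum afterwards. Spectra that lose their last
#' seed-adduct annotation are dropped entirely.
#'
#' @param spectra list of pseudo spectra.
#' @param target_id id of the spectrum that keeps the peaks.
#' @param peak_ids character vector of peak ids; all must be members of the
#'   target spectrum.
#' @return updated spectra list.
#' @export
claim_peaks <- function(spectra, target_id, peak_ids) {
  ids <- vapply(spectra, `[[`, "", "id")
  ti <- match(target_id, ids)
  if (is.na(ti)) stop("no pseudo spectrum with id ", target_id)
  target <- spectra[[ti]]
  foreign <- setdiff(peak_ids, target$annotations$peak_id)
  if (length(foreign) > 0) {
    stop("peak(s) not member of ", target_id, ": ",
         paste(foreign, collapse = ", "))
  }
  for (si in seq_along(spectra)) {
    if (si == ti) next
    ann <- spectra[[si]]$annotations
    ann <- ann[!(ann$peak_id %in% peak_ids) &
                 !(ann$parent_id %in% peak_ids), , drop = FALSE]
    spectra[[si]]$annotations <- ann
  }
  keep <- vapply(spectra, function(s) {
    nrow(s$annotations) > 0 && any(s$annotations$role == "seed_adduct")
  }, TRUE)
  keep[ti] <- TRUE
  spectra[keep]
}

#' List orphan peaks
#'
#' Peaks not assigned to any pseudo spectrum, optionally filtered by a
#' retention-time window and a minimum apex intensity.
#'
#' @param peaks peak table.
#' @param spectra list of pseudo spectra.
#' @param rt_window numeric length-2 `c(lo, hi)` in seconds, or NULL.
#' @param min_intensity minimum apex intensity.
#' @return character vector of peak ids.
#' @export
list_orphans <- function(peaks, spectra, rt_window = NULL, min_intensity = 0) {
  peaks <- validate_peaks(peaks)
  ids <- setdiff(peaks$id, spectra_members(spectra))
  sel <- peaks[peaks$id %in% ids, , drop = FALSE]
  if (!is.null(rt_window)) {
    sel <- sel[sel$rt >= rt_window[1] & sel$rt <= rt_window[2], , drop = FALSE]
  }
  ints <- peak_intensity(sel)
  sel$id[ints >= min_intensity]
}

#' Find orphan peaks correlating with a pseudo spectrum's primary peak
#'
#' @param spectrum a `pseudo_spectrum`.
#' @param peaks peak table.
#' @param spectra all pseudo spectra (to determine orphans).
#' @param eics named list of EIC traces keyed by peak id.
#' @param threshold minimum Pearson correlation (the curation default used
#'   in practice is 0.75).
#' @param eps_rt retention-time window around the spectrum, seconds.
#' @return data.frame (peak_id, corr) ranked by decreasing correlation.
#' @export
find_correlating_peaks <- function(spectrum, peaks, spectra, eics,
                                   threshold = 0.75, eps_rt = 5) {
  peaks <- validate_peaks(peaks)
  orph <- list_orphans(peaks, spectra,
                       rt_window = c(spectrum$rt - eps_rt, spectrum$rt + eps_rt))
  prim_eic <- eics[[spectrum$primary]]
  cc <- vapply(orph, function(id) eic_correlation(eics[[id]], prim_eic), 0.0)
  keep <- !is.na(cc) & cc >= threshold
  out <- data.frame(peak_id = orph[keep], corr = cc[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$corr, out$peak_id), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# The full pipeline

#' Run the full spectra-deconvolution pipeline
#'
#' Executes steps 2-7 in order on one chromatogram's peak table:
#' isotope-chain detection, seed-adduct pseudo-spectrum assembly, 12C/13C
#' pair association, homoadduct detection, uncommon-loss annotation and
#' (when EIC traces are available) correlation pruning.
#'
#' @param peaks peak table (see [read_peak_table()]).
#' @param cfg [sd_config()].
#' @param eics optional named list of EIC data.frames keyed by peak id.
#' @return An `sd_result`: list with `spectra`, `chains`, `label_pairs`,
#'   `orphans` (peak ids), `peaks` and `cfg`.
#' @export
#' @examples
#' fx <- simulate_peak_table(preset_scenarios()$glutamate$compounds,
#'                           noise_model(seed = 1))
#' res <- run_deconvolution(fx$peaks)
#' res$spectra[[1]]
run_deconvolution <- function(peaks, cfg = sd_config(), eics = NULL) {
  peaks <- validate_peaks(peaks)
  if (nrow(peaks) == 0) {
    return(structure(list(spectra = list(), chains = list(),
                          label_pairs = data.frame(), orphans = character(0),
                          peaks = peaks, cfg = cfg), class = "sd_result"))
  }
  chains <- detect_isotope_chains(peaks, cfg)
  spectra <- assemble_pseudo_spectra(peaks, chains, cfg)
  lp <- associate_label_pairs(spectra, peaks, chains, cfg)
  spectra <- detect_homoadducts(lp$spectra, peaks, chains, cfg)
  ul <- annotate_uncommon_losses(spectra, peaks, lp$label_pairs, chains, cfg)
  spectra <- ul$spectra
  if (!is.null(eics)) spectra <- prune_by_correlation(spectra, eics, cfg)
  structure(list(spectra = spectra, chains = chains,
                 label_pairs = ul$label_pairs,
                 orphans = list_orphans(peaks, spectra),
                 peaks = peaks, cfg = cfg),
            class = "sd_result")
}

#' @export
print.sd_result <- function(x, ...) {
  cat(sprintf("<deconvolution result> %d peaks -> %d pseudo spectra, %d chains, %d label pairs, %d orphans\n",
              nrow(x$peaks), length(x$spectra), length(x$chains),
              nrow(x$label_pairs), length(x$orphans)))
  invisible(x)
}
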