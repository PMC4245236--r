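# Reference-spectrum lists: store curated pseudo spectra, re-apply them to
# other chromatograms with dot-product (cosine) scoring, derive pseudo
# fragment spectra, and match against local MassBank-format record files.

#' Dot-product (cosine) similarity of two peak lists
#'
#' Peaks are paired greedily by nearest m/z within `mz_tol`; unpaired peaks
#' contribute zero to the cross term but full weight to the norms. Plain
#' cosine on relative intensities (intensity weight 1, m/z weight 0);
#' symmetric, 1 for identical spectra, 0 for disjoint m/z sets.
#'
#' @param a,b data.frames with columns `mz` and `intensity` (>= 1 row).
#' @param mz_tol pairing tolerance in Da.
#' @return score in \[0, 1\].
#' @export
#' @examples
#' a <- data.frame(mz = c(100, 150), intensity = c(1, 0.5))
#' dot_product_score(a, a)
dot_product_score <- function(a, b, mz_tol = 0.005) {
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) {
    stop("dot_product_score: empty spectrum")
  }
  cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  cand$d <- abs(a$mz[cand$i] - b$mz[cand$j])
  cand <- cand[cand$d <= mz_tol, , drop = FALSE]
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
  cross <- 0
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    cross <- cross + a$intensity[i] * b$intensity[j]
  }
  denom <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  if (denom == 0) return(0)
  cross / denom
}

ref_entry_from_spectrum <- function(s, peaks) {
  ann <- s$annotations
  keep <- ann[ann$role %in% c("seed_adduct", "adduct", "fragment",
                              "homoadduct"), , drop = FALSE]
  idx <- match(keep$peak_id, peaks$id)
  ints <- peak_intensity(peaks[idx, , drop = FALSE])
  list(compound = s$compound_name, M = s$M, rt = s$rt,
       peaks = data.frame(mz = peaks$mz[idx],
                          intensity = ints / max(ints),
                          ion_label = keep$ion_label,
                          stringsAsFactors = FALSE))
}

#' Create a reference list from confirmed pseudo spectra
#'
#' Only spectra with status `confirmed` or `manual` (i.e. with a compound
#' name attached by curation) are stored; each entry keeps the 12C member
#' peaks (seed adducts, adducts, fragments, homoadducts) with intensities
#' relative to the strongest member. 13C peaks and isotopologues are
#' excluded — they depend on the labeling, not the compound.
#'
#' @param spectra list of pseudo spectra.
#' @param peaks the chromatogram's peak table.
#' @param name list name.
#' @param score_threshold default dot-product threshold for application.
#' @param rt_tolerance retention-time window (s) when re-applying.
#' @return list of class `reference_list`.
#' @export
create_reference_list <- function(spectra, peaks, name = "reference",
                                  score_threshold = 0.8, rt_tolerance = 10) {
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  peaks <- validate_peaks(peaks)
  entries <- list()
  for (s in spectra) {
    if (!s$status %in% c("confirmed", "manual") || is.na(s$compound_name)) {
      warning("skipping unconfirmed spectrum ", s$id)
      next
    }
    entries[[length(entries) + 1L]] <- ref_entry_from_spectrum(s, peaks)
  }
  structure(list(name = name, entries = entries,
                 score_threshold = score_threshold,
                 rt_tolerance = rt_tolerance),
            class = "reference_list")
}

#' Apply a reference list to another chromatogram
#'
#' For each entry the best-matching pseudo spectrum within the RT tolerance
#' is scored by dot product and annotated when the score reaches the
#' threshold. If no deconvolved spectrum matches and a raw peak table is
#' given, assembly mode gathers peaks matching the entry's m/z pattern
#' (within `eps_mz`) into a new pseudo spectrum.
#'
#' @param ref a [create_reference_list()] result.
#' @param spectra list of pseudo spectra of the target chromatogram.
#' @param peaks the target chromatogram's peak table.
#' @param eps_mz m/z tolerance for peak pairing / assembly.
#' @return list with `spectra` (annotated, possibly extended) and
#'   `matches` (data.frame: compound, spectrum_id, score, assembled).
#' @export
apply_reference_list <- function(ref, spectra, peaks, eps_mz = 0.005) {
  stopifnot(inherits(ref, "reference_list"))
  peaks <- validate_peaks(peaks)
  matches <- data.frame(compound = character(0), spectrum_id = character(0),
                        score = numeric(0), assembled = logical(0),
                        stringsAsFactors = FALSE)
  for (entry in ref$entries) {
    best <- NULL; best_score <- -1; best_idx <- NA
    for (si in seq_along(spectra)) {
      s <- spectra[[si]]
      if (abs(s$rt - entry$rt) > ref$rt_tolerance) next
      cand <- ref_entry_from_spectrum(s, peaks)$peaks
      if (nrow(cand) == 0) next
      sc <- dot_product_score(entry$peaks, cand, eps_mz)
      if (sc > best_score) { best_score <- sc; best <- s; best_idx <- si }
    }
    if (!is.null(best) && best_score >= ref$score_threshold) {
      best$compound_name <- entry$compound
      best$status <- "confirmed"
      spectra[[best_idx]] <- best
      matches <- rbind(matches, data.frame(compound = entry$compound,
                                           spectrum_id = best$id,
                                           score = best_score,
                                           assembled = FALSE,
                                           stringsAsFactors = FALSE))
      next
    }
    # assembly mode: collect peaks matching the entry's m/z pattern
    sel <- integer(0)
    for (r in seq_len(nrow(entry$peaks))) {
      cand <- which(abs(peaks$mz - entry$peaks$mz[r]) <= eps_mz &
                      abs(peaks$rt - entry$rt) <= ref$rt_tolerance)
      if (length(cand) > 0) {
        sel <- c(sel, cand[which.min(abs(peaks$mz[cand] - entry$peaks$mz[r]))])
      } else {
        sel <- c(sel, NA_integer_)
      }
    }
    found <- which(!is.na(sel))
    if (length(found) < 2) next
    obs <- data.frame(mz = peaks$mz[sel[found]],
                      intensity = peak_intensity(peaks[sel[found], , drop = FALSE]))
    obs$intensity <- obs$intensity / max(obs$intensity)
    sc <- dot_product_score(entry$peaks, obs, eps_mz)
    if (sc < ref$score_threshold) next
    ann <- empty_annotations()
    for (k in seq_along(found)) {
      r <- found[k]
      lab <- entry$peaks$ion_label[r]
      ann <- rbind(ann, annot_row(peaks$id[sel[r]], lab, lab,
                                  if (lab %in% c("[M+H]+", "[M-H]-"))
                                    "seed_adduct" else "adduct"))
    }
    s_new <- new_pseudo_spectrum(entry$M, peaks$rt[sel[found[1]]],
                                 ann$peak_id[1], ann, status = "confirmed",
                                 compound_name = entry$compound)
    spectra[[length(spectra) + 1L]] <- s_new
    matches <- rbind(matches, data.frame(compound = entry$compound,
                                         spectrum_id = s_new$id, score = sc,
                                         assembled = TRUE,
                                         stringsAsFactors = FALSE))
  }
  list(spectra = spectra, matches = matches)
}

#' Pseudo fragment spectrum of a pseudo spectrum
#'
#' The pseudo-molecular ion (`[M+H]+` or `[M-H]-`) plus all fragment
#' members; other adducts, homoadducts, isotopologues and 13C peaks are
#' excluded. This approximates an MS2 spectrum from in-source
#' fragmentation and is the query for spectral-library matching.
#'
#' @param s a pseudo spectrum.
#' @param peaks peak table.
#' @return data.frame (`mz`, `intensity` relative to max, `ion_label`).
#' @export
pseudo_fragment_spectrum <- function(s, peaks) {
  peaks <- validate_peaks(peaks)
  ann <- s$annotations
  pm <- ann$species_label %in% c("[M+H]+", "[M-H]-") & ann$role == "seed_adduct"
  if (!any(pm)) stop("spectrum ", s$id, " has no pseudo-molecular ion")
  keep <- ann[pm | ann$role %in% c("fragment", "uncommon_fragment"), ,
              drop = FALSE]
  idx <- match(keep$peak_id, peaks$id)
  ints <- peak_intensity(peaks[idx, , drop = FALSE])
  data.frame(mz = peaks$mz[idx], intensity = ints / max(ints),
             ion_label = keep$ion_label, stringsAsFactors = FALSE)
}

#' Match a query spectrum against local spectral record files
#'
#' Records use the MassBank text format; only the `PK$PEAK:` block (lines
#' of `m/z intensity rel.intensity`) and a few header fields are read.
#' Unparseable records are skipped with a warning.
#'
#' @param query data.frame (`mz`, `intensity`).
#' @param record_paths character vector of record file paths (or a
#'   directory, expanded to `*.txt`).
#' @param mz_tol pairing tolerance, Da.
#' @return data.frame (record, accession, name, score) ranked by
#'   descending score.
#' @export
match_record_file <- function(query, record_paths, mz_tol = 0.005) {
  if (length(record_paths) == 1 && dir.exists(record_paths)) {
    record_paths <- list.files(record_paths, pattern = "\\.txt$",
                               full.names = TRUE)
  }
  out <- data.frame(record = character(0), accession = character(0),
                    name = character(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  for (path in record_paths) {
    rec <- tryCatch(read_massbank_record(path), error = function(e) {
      warning("skipping unparseable record ", path, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) next
    sc <- dot_product_score(query, rec$peaks, mz_tol)
    out <- rbind(out, data.frame(record = path, accession = rec$accession,
                                 name = rec$name, score = sc,
                                 stringsAsFactors = FALSE))
  }
  out[order(-out$score, out$record), , drop = FALSE]
}

#' Read a MassBank-format spectral record
#' @param path record file path.
#' @return list with `accession`, `name`, `peaks` (mz, intensity,
#'   rel_intensity).
#' @export
read_massbank_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  start <- grep("^PK\\$PEAK:", lines)
  if (length(start) == 0) stop("no PK$PEAK block")
  peaks <- list()
  for (i in (start[1] + 1):length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || ln == "//") break
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) < 2) stop("malformed peak line: ", ln)
    peaks[[length(peaks) + 1L]] <-
      data.frame(mz = as.numeric(fields[1]),
                 intensity = as.numeric(fields[2]),
                 rel_intensity = if (length(fields) >= 3)
                   as.numeric(fields[3]) else NA_real_)
  }
  pk <- do.call(rbind, peaks)
  if (is.null(pk) || anyNA(pk$mz) || anyNA(pk$intensity)) {
    stop("unparseable peak block")
  }
  pk$intensity <- pk$intensity / max(pk$intensity)
  list(accession = get_field("ACCESSION"),
       name = get_field("CH\\$NAME"), peaks = pk)
}

#' Write / read a reference list as JSON
#'
#' The on-disk schema is versioned (`format_version`). m/z values are
#' stored absolutely: reference lists are method-specific and assume a
#' fixed chromatographic protocol.
#'
#' @param ref a `reference_list`.
#' @param path file path.
#' @return `path` (write) or a `reference_list` (read).
#' @export
write_reference_list <- function(ref, path) {
  payload <- list(format_version = 1L, name = ref$name,
                  score_threshold = ref$score_threshold,
                  rt_tolerance = ref$rt_tolerance,
                  entries = lapply(ref$entries, function(e) {
                    list(compound = e$compound, M = e$M, rt = e$rt,
                         peaks = e$peaks)
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_list
#' @export
read_reference_list <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(payload$format_version) || payload$format_version != 1) {
    stop("unsupported reference list format in ", path)
  }
  entries <- payload$entries
  if (is.data.frame(entries)) {
    entries <- lapply(seq_len(nrow(entries)), function(i) {
      list(compound = entries$compound[i], M = entries$M[i],
           rt = entries$rt[i], peaks = entries$peaks[[i]])
    })
  }
  structure(list(name = payload$name, entries = entries,
                 score_threshold = payload$score_threshold,
                 rt_tolerance = payload$rt_tolerance),
            class = "reference_list")
}
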