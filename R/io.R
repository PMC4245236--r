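# On-disk formats: XCMS-dialect peak tables (CSV/TSV), CAMERA-style
# annotated peak-list export extended by a 13C-association column,
# molecule lists with isotopomer ratios, pseudo-spectrum JSON, and a
# deliberately minimal mzML MS1 reader/writer for EIC extraction.
# XLSX export is out of scope (no suitable writer in the supported stack);
# CSV/TSV cover the same content.

#' Column dialect of a peak table
#'
#' @param mz,rt,rtmin,rtmax,into,intb,maxo,sample column names in the file.
#' @param delimiter field separator ("," or "\t"); guessed from the file
#'   extension when reading if left NULL.
#' @param header does the file carry a header row.
#' @return list of class `peak_dialect`.
#' @export
peak_dialect <- function(mz = "mz", rt = "rt", rtmin = "rtmin",
                         rtmax = "rtmax", into = "into", intb = "intb",
                         maxo = "maxo", sample = "sample",
                         delimiter = NULL, header = TRUE) {
  structure(list(mz = mz, rt = rt, rtmin = rtmin, rtmax = rtmax,
                 into = into, intb = intb, maxo = maxo, sample = sample,
                 delimiter = delimiter, header = header),
            class = "peak_dialect")
}

.guess_delim <- function(path, dialect) {
  if (!is.null(dialect$delimiter)) return(dialect$delimiter)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an XCMS-style peak table
#'
#' One peak per row; ids are stable (`P` + row number) unless the file has
#' an `id` column. RT is taken as-is (seconds). `mz` and `rt` are required;
#' at least one abundance column must be present.
#'
#' @param path CSV/TSV file.
#' @param dialect a [peak_dialect()].
#' @return peak data.frame (id, mz, rt, rtmin, rtmax, maxo, into, intb,
#'   sample).
#' @export
read_peak_table <- function(path, dialect = peak_dialect()) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  sep <- .guess_delim(path, dialect)
  df <- utils::read.table(path, sep = sep, header = dialect$header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("mz", "rt")) {
    if (!dialect[[col]] %in% names(df)) {
      stop("peak table lacks required column '", dialect[[col]], "'")
    }
  }
  abund <- c(dialect$maxo, dialect$into, dialect$intb)
  if (!any(abund %in% names(df))) {
    stop("peak table lacks an abundance column (one of: ",
         paste(abund, collapse = ", "), ")")
  }
  get <- function(key, default = NA_real_) {
    nm <- dialect[[key]]
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  num <- function(key, x) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != "NA")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   dialect[[key]], bad[1], x[bad[1]]))
    }
    v
  }
  out <- data.frame(
    id = if ("id" %in% names(df)) as.character(df$id)
         else sprintf("P%03d", seq_len(nrow(df))),
    mz = num("mz", get("mz")), rt = num("rt", get("rt")),
    rtmin = num("rtmin", get("rtmin")), rtmax = num("rtmax", get("rtmax")),
    maxo = num("maxo", get("maxo")), into = num("into", get("into")),
    intb = num("intb", get("intb")),
    sample = as.character(get("sample", "S1")),
    stringsAsFactors = FALSE)
  out$sample[is.na(out$sample)] <- "S1"
  validate_peaks(out)
}

#' Write an annotated peak list
#'
#' CAMERA-like export: every input peak row extended by annotation columns
#' `isotopes`, `adduct`, `pcgroup` (pseudo-spectrum ids, `;`-separated when
#' a peak is multi-assigned, with `multiple` flagged) and `c13_partner`
#' (id of the associated 13C/12C counterpart, empty when none).
#'
#' @param result an `sd_result` from [run_deconvolution()].
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(result, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  peaks <- result$peaks
  iso <- stats::setNames(rep("", nrow(peaks)), peaks$id)
  add <- iso; grp <- iso; c13 <- iso
  for (s in result$spectra) {
    ann <- s$annotations
    for (r in seq_len(nrow(ann))) {
      pid <- ann$peak_id[r]
      if (ann$role[r] %in% c("isotope", "c13_isotope")) {
        iso[pid] <- paste0(iso[pid], if (nzchar(iso[pid])) ";", ann$ion_label[r])
      } else {
        add[pid] <- paste0(add[pid], if (nzchar(add[pid])) ";", ann$ion_label[r])
      }
      grp[pid] <- paste0(grp[pid], if (nzchar(grp[pid])) ";", s$id)
    }
  }
  lp <- result$label_pairs
  if (nrow(lp) > 0) {
    for (r in seq_len(nrow(lp))) {
      c13[lp$c12_peak[r]] <- lp$c13_peak[r]
      c13[lp$c13_peak[r]] <- lp$c12_peak[r]
    }
  }
  out <- cbind(peaks,
               isotopes = unname(iso), adduct = unname(add),
               pcgroup = unname(grp),
               multiple = unname(vapply(strsplit(grp, ";"),
                                        function(x) length(unique(x)) > 1,
                                        TRUE)),
               c13_partner = unname(c13))
  utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                     quote = TRUE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a molecule list
#'
#' One row per confirmed (or manually annotated) metabolite per sample:
#' compound, spectrum id, adduct inventory, quantitation ion, normalized
#' 12C abundance and the 12C/13C abundance quotient (empty when the
#' internal standard was not detected). Multiple chromatograms can be
#' concatenated into a single experiment-wide file.
#'
#' @param result an `sd_result`.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @param normalizer biomass / optical density for this sample (> 0).
#' @param quant_ion ion species used for quantitation.
#' @param abundance which abundance column to use: `into`, `maxo` or `intb`.
#' @return the exported data.frame, invisibly; written to `path`.
#' @export
write_molecule_list <- function(result, path, format = c("csv", "tsv"),
                                normalizer = 1, quant_ion = "[M+H]+",
                                abundance = c("into", "maxo", "intb")) {
  format <- match.arg(format)
  abundance <- match.arg(abundance)
  peaks <- result$peaks
  rows <- list()
  for (s in result$spectra) {
    if (!s$status %in% c("confirmed", "manual") || is.na(s$compound_name)) next
    ann <- s$annotations
    qi <- ann[ann$species_label == quant_ion & ann$n_shift == 0 &
                ann$role != "c13_monoisotopic", , drop = FALSE]
    if (nrow(qi) == 0) next
    c12_id <- qi$peak_id[1]
    lp <- result$label_pairs
    c13_id <- if (nrow(lp) > 0) {
      hit <- lp[lp$spectrum_id == s$id & lp$c12_peak == c12_id, , drop = FALSE]
      if (nrow(hit) > 0) hit$c13_peak[1] else NA_character_
    } else NA_character_
    a12 <- peaks[[abundance]][match(c12_id, peaks$id)]
    a13 <- if (!is.na(c13_id)) peaks[[abundance]][match(c13_id, peaks$id)]
           else NA_real_
    rec <- abundance_record(s$id, quant_ion, a12, a13, normalizer,
                            sample = peaks$sample[match(c12_id, peaks$id)])
    q <- isotopomer_ratio(rec)
    adducts <- paste(unique(ann$ion_label[!ann$role %in%
                                            c("isotope", "c13_isotope")]),
                     collapse = ";")
    rows[[length(rows) + 1L]] <- data.frame(
      compound = s$compound_name, spectrum_id = s$id, M = s$M, rt = s$rt,
      sample = rec$sample, quant_ion = quant_ion, adducts = adducts,
      abundance = a12, normalized_abundance = q$normalized_c12,
      c13_abundance = a13, ratio = q$ratio, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(compound = character(0), spectrum_id = character(0),
               M = numeric(0), rt = numeric(0), sample = character(0),
               quant_ion = character(0), adducts = character(0),
               abundance = numeric(0), normalized_abundance = numeric(0),
               c13_abundance = numeric(0), ratio = numeric(0),
               stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                     quote = TRUE, row.names = FALSE, na = "")
  invisible(out)
}

#' Export pseudo spectra as JSON
#'
#' Versioned schema: spectrum id, M, rt, status, compound, members with
#' labels/roles/flags, plus the label-pair table.
#'
#' @param result an `sd_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_json <- function(result, path) {
  payload <- list(
    format_version = 1L,
    spectra = lapply(result$spectra, function(s) {
      list(id = s$id, M = s$M, rt = s$rt, status = s$status,
           compound = s$compound_name, primary = s$primary,
           members = s$annotations)
    }),
    label_pairs = result$label_pairs,
    orphans = result$orphans)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal mzML support. Scope: MS1 centroid spectra, 64-bit little-endian
# float arrays, uncompressed or zlib. Enough for EIC extraction from
# converter output and for round-tripping the simulator; not a general
# mzML implementation.

#' Read MS1 scans from an mzML file
#'
#' @param path mzML file.
#' @return list of scans: `list(rt, mz, intensity)`, rt in seconds.
#' @export
read_mzml_scans <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  scans <- list()
  for (spec in xml2::xml_find_all(doc, ".//spectrum")) {
    level <- xml2::xml_find_first(
      spec, ".//cvParam[@accession='MS:1000511']")
    if (!inherits(level, "xml_missing") &&
        xml2::xml_attr(level, "value") != "1") next
    rt_node <- xml2::xml_find_first(
      spec, ".//scan/cvParam[@accession='MS:1000016']")
    if (inherits(rt_node, "xml_missing")) next
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitName")
    if (!is.na(unit) && grepl("minute", unit)) rt <- rt * 60
    arrays <- list(mz = NULL, intensity = NULL)
    for (arr in xml2::xml_find_all(spec, ".//binaryDataArray")) {
      is_mz <- length(xml2::xml_find_all(
        arr, ".//cvParam[@accession='MS:1000514']")) > 0
      is_int <- length(xml2::xml_find_all(
        arr, ".//cvParam[@accession='MS:1000515']")) > 0
      zlib <- length(xml2::xml_find_all(
        arr, ".//cvParam[@accession='MS:1000574']")) > 0
      b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
      if (zlib) raw <- memDecompress(raw, type = "gzip")
      vals <- readBin(raw, "double", n = length(raw) / 8, size = 8,
                      endian = "little")
      if (is_mz) arrays$mz <- vals
      if (is_int) arrays$intensity <- vals
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity)) next
    scans[[length(scans) + 1L]] <- list(rt = rt, mz = arrays$mz,
                                        intensity = arrays$intensity)
  }
  if (length(scans) == 0) stop("no MS1 scans found in ", path)
  scans
}

#' Write MS1 scans to a minimal mzML file
#'
#' Uncompressed 64-bit little-endian arrays; used by the simulator to
#' produce raw-data fixtures that [read_mzml_scans()] and [extract_eics()]
#' consume.
#'
#' @param scans list of `list(rt, mz, intensity)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzml_scans <- function(scans, path) {
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8, endian = "little"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <run id="synthetic">')
  w('    <spectrumList count="%d">', length(scans))
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    w('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      i - 1L, i, length(sc$mz))
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>')
    w('        <scanList count="1"><scan>')
    w('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitName="second"/>', sc$rt)
    w('        </scan></scanList>')
    w('        <binaryDataArrayList count="2">')
    for (kind in c("mz", "intensity")) {
      acc <- if (kind == "mz") "MS:1000514" else "MS:1000515"
      nm <- if (kind == "mz") "m/z array" else "intensity array"
      w('          <binaryDataArray>')
      w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
      w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
      w('            <cvParam cvRef="MS" accession="%s" name="%s"/>', acc, nm)
      w('            <binary>%s</binary>', enc(sc[[kind]]))
      w('          </binaryDataArray>')
    }
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

#' Extract ion chromatograms for peaks from an mzML file
#'
#' Per peak, sums the signal within `mz +/- mz_halfwidth` over scans in
#' `[rtmin - rt_pad, rtmax + rt_pad]`. Peaks whose window contains no scan
#' get an empty trace and are flagged.
#'
#' @param mzml_path mzML file with MS1 scans.
#' @param peaks peak table.
#' @param mz_halfwidth half-width of the m/z window, Da.
#' @param rt_pad extra RT margin, seconds.
#' @return named list of EIC data.frames (`rt`, `intensity`) keyed by peak
#'   id; empty traces carry attribute `empty = TRUE`.
#' @export
extract_eics <- function(mzml_path, peaks, mz_halfwidth = 0.01, rt_pad = 5) {
  peaks <- validate_peaks(peaks)
  scans <- read_mzml_scans(mzml_path)
  rts <- vapply(scans, `[[`, 0, "rt")
  eics <- list()
  for (i in seq_len(nrow(peaks))) {
    lo <- peaks$rtmin[i] - rt_pad; hi <- peaks$rtmax[i] + rt_pad
    sel <- which(rts >= lo & rts <= hi)
    if (length(sel) == 0) {
      tr <- data.frame(rt = numeric(0), intensity = numeric(0))
      attr(tr, "empty") <- TRUE
      eics[[peaks$id[i]]] <- tr
      next
    }
    intensity <- vapply(sel, function(k) {
      sc <- scans[[k]]
      sum(sc$intensity[abs(sc$mz - peaks$mz[i]) <= mz_halfwidth])
    }, 0.0)
    eics[[peaks$id[i]]] <- data.frame(rt = rts[sel], intensity = intensity)
  }
  eics
}

#' Write EIC scans for a simulated dataset to mzML
#'
#' Renders the gaussian profiles of [simulate_eics()] as full MS1 scans on
#' a shared time grid.
#'
#' @param sim result of [simulate_peak_table()].
#' @param path output mzML path.
#' @param grid scan interval, seconds.
#' @return `path`, invisibly.
#' @export
simulate_mzml <- function(sim, path, grid = 0.5) {
  eics <- simulate_eics(sim, grid)
  times <- sort(unique(round(unlist(lapply(eics, `[[`, "rt")), 6)))
  scans <- lapply(times, function(t) {
    mzs <- c(); ints <- c()
    for (id in names(eics)) {
      tr <- eics[[id]]
      j <- which(abs(tr$rt - t) < grid / 2)
      if (length(j) > 0 && tr$intensity[j[1]] > 0.5) {
        mzs <- c(mzs, sim$peaks$mz[sim$peaks$id == id])
        ints <- c(ints, tr$intensity[j[1]])
      }
    }
    o <- order(mzs)
    list(rt = t, mz = mzs[o], intensity = ints[o])
  })
  scans <- Filter(function(s) length(s$mz) > 0, scans)
  write_mzml_scans(scans, path)
}
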