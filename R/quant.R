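# Mass-isotopomer-ratio quantitation and group statistics: 12C/13C
# abundance quotients (immune to matrix effects because analyte and
# internal standard coelute), biomass normalization, group fold-changes,
# equal-variance t-tests and Benjamini-Hochberg adjustment.

#' One quantitation record for a metabolite in one sample
#'
#' @param spectrum_id pseudo-spectrum id.
#' @param ion_label ion species used for quantitation (typically `[M+H]+`).
#' @param c12_abundance 12C abundance (intensity, area or
#'   baseline-corrected area).
#' @param c13_abundance abundance of the fully 13C-labeled counterpart, or
#'   NA when the internal standard was below the detection limit.
#' @param normalizer biomass or optical density, > 0.
#' @param sample sample id.
#' @param group group label for downstream statistics.
#' @param abundance_kind which XCMS abundance was used.
#' @return list of class `abundance_record`.
#' @export
abundance_record <- function(spectrum_id, ion_label, c12_abundance,
                             c13_abundance = NA_real_, normalizer = 1,
                             sample = "S1", group = "A",
                             abundance_kind = c("area", "intensity",
                                                "baseline_corrected_area")) {
  abundance_kind <- match.arg(abundance_kind)
  if (is.na(c12_abundance) || c12_abundance < 0) {
    stop("c12_abundance must be a non-negative number")
  }
  if (!is.na(c13_abundance) && c13_abundance < 0) {
    stop("c13_abundance must be non-negative")
  }
  if (!is.numeric(normalizer) || normalizer <= 0) {
    stop("normalizer must be > 0")
  }
  structure(list(spectrum_id = spectrum_id, ion_label = ion_label,
                 c12_abundance = c12_abundance,
                 c13_abundance = c13_abundance, normalizer = normalizer,
                 sample = sample, group = group,
                 abundance_kind = abundance_kind),
            class = "abundance_record")
}

#' Mass isotopomer ratio of one record
#'
#' The 12C/13C abundance quotient. Undefined — `NA`, not zero and not an
#' error — when the 13C abundance is missing or zero (internal standard
#' below the detection limit).
#'
#' @param rec an [abundance_record()].
#' @return list with `normalized_c12` (c12 / normalizer) and `ratio`.
#' @export
#' @examples
#' isotopomer_ratio(abundance_record("M147.053T287.92", "[M+H]+", 1e6, 5e5))
isotopomer_ratio <- function(rec) {
  stopifnot(inherits(rec, "abundance_record"))
  ratio <- if (is.na(rec$c13_abundance) || rec$c13_abundance == 0) {
    NA_real_
  } else {
    rec$c12_abundance / rec$c13_abundance
  }
  list(normalized_c12 = rec$c12_abundance / rec$normalizer, ratio = ratio)
}

#' Normalize an abundance by biomass / optical density
#'
#' @param abundance non-negative abundance value.
#' @param normalizer biomass or optical density, > 0.
#' @return abundance / normalizer.
#' @export
normalize_abundance <- function(abundance, normalizer) {
  if (!is.numeric(normalizer) || any(normalizer <= 0)) {
    stop("normalizer must be > 0")
  }
  if (any(abundance < 0, na.rm = TRUE)) stop("abundance must be >= 0")
  abundance / normalizer
}

#' Fold-change between two groups of values
#'
#' `mean(a) / mean(b)`. Missing values (undefined ratios) are excluded
#' with a message reporting how many were dropped.
#'
#' @param group_a,group_b numeric vectors, each with at least one
#'   non-missing value.
#' @return fold-change (scalar).
#' @export
#' @examples
#' fold_change(c(2, 2, 2, 2), c(1, 1, 1, 1))
fold_change <- function(group_a, group_b) {
  na_n <- sum(is.na(group_a)) + sum(is.na(group_b))
  if (na_n > 0) message("fold_change: dropping ", na_n, " missing value(s)")
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group in fold_change")
  mb <- mean(b)
  if (mb == 0) stop("zero denominator group mean")
  mean(a) / mb
}

#' Two-sample equal-variance Student's t-test p-value
#'
#' @param group_a,group_b numeric vectors with >= 2 non-missing values each.
#' @return two-sided p-value.
#' @export
group_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("group_test needs >= 2 values per group")
  }
  if (stats::sd(c(a, b)) == 0) return(1.0)  # degenerate: identical constants
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' `p_(i) * m / i` on the ascending order statistics with running-minimum
#' (step-up) enforcement, capped at 1, returned in the original order.
#' Implemented directly so the exported statistics are self-contained and
#' auditable; agrees with `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04))
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(p[o] * m / (m:1)))[ro]
    out[ok] <- adj
  }
  out
}

#' Fold-change table from a long-format abundance table
#'
#' Input: one row per (compound, sample) with columns `compound`, `group`,
#' `value` and optionally `normalizer` (biomass / optical density; 1 when
#' absent). This is the layout of a normalized-peak-area supplementary
#' sheet. Values are normalized, averaged per group, and contrasted as
#' `mean(group_a) / mean(group_b)` with an equal-variance t-test and BH
#' adjustment over all compounds.
#'
#' @param df data.frame as described.
#' @param group_a,group_b group labels to contrast (fold-change = a / b).
#' @return data.frame: compound, n_a, n_b, mean_a, mean_b, fold_change,
#'   p_value, p_adjusted.
#' @export
fold_change_table <- function(df, group_a, group_b) {
  need <- c("compound", "group", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$normalizer)) df$normalizer <- 1
  df$value <- normalize_abundance(df$value, df$normalizer)
  out <- NULL
  for (cmp in unique(df$compound)) {
    a <- df$value[df$compound == cmp & df$group == group_a]
    b <- df$value[df$compound == cmp & df$group == group_b]
    out <- rbind(out, data.frame(
      compound = cmp, n_a = sum(!is.na(a)), n_b = sum(!is.na(b)),
      mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
      fold_change = tryCatch(fold_change(a, b), error = function(e) NA_real_),
      p_value = tryCatch(group_test(a, b), error = function(e) NA_real_),
      stringsAsFactors = FALSE))
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Group-wise quantitation table for confirmed metabolites
#'
#' Builds the molecule-level statistics used in labeling experiments: for
#' every spectrum id, per-sample normalized values (isotopomer ratio per
#' normalizer when the 13C partner exists, else normalized 12C abundance),
#' group means, fold-change between the two groups, Student's t p-value and
#' BH-adjusted p across all metabolites.
#'
#' @param records list of [abundance_record()]s covering two groups.
#' @param group_a,group_b the two group labels to contrast.
#' @return data.frame: one row per (spectrum_id, ion_label) with columns
#'   `mean_a`, `mean_b`, `fold_change`, `p_value`, `p_adjusted`,
#'   `n_missing`, `value_kind`.
#' @export
quantitation_table <- function(records, group_a, group_b) {
  stopifnot(length(records) > 0)
  df <- do.call(rbind, lapply(records, function(r) {
    q <- isotopomer_ratio(r)
    val <- if (!is.na(q$ratio)) q$ratio / r$normalizer else NA_real_
    data.frame(spectrum_id = r$spectrum_id, ion_label = r$ion_label,
               group = r$group, sample = r$sample,
               ratio_norm = val, c12_norm = q$normalized_c12,
               stringsAsFactors = FALSE)
  }))
  keys <- unique(df[, c("spectrum_id", "ion_label")])
  out <- NULL
  pvals <- numeric(0)
  for (k in seq_len(nrow(keys))) {
    sub <- df[df$spectrum_id == keys$spectrum_id[k] &
                df$ion_label == keys$ion_label[k], , drop = FALSE]
    use_ratio <- all(!is.na(sub$ratio_norm))
    v <- if (use_ratio) sub$ratio_norm else sub$c12_norm
    a <- v[sub$group == group_a]; b <- v[sub$group == group_b]
    fc <- tryCatch(fold_change(a, b), error = function(e) NA_real_)
    p <- tryCatch(group_test(a, b), error = function(e) NA_real_)
    pvals <- c(pvals, p)
    out <- rbind(out, data.frame(
      spectrum_id = keys$spectrum_id[k], ion_label = keys$ion_label[k],
      mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
      fold_change = fc, p_value = p,
      n_missing = sum(is.na(sub$ratio_norm)),
      value_kind = if (use_ratio) "ratio_normalized" else "c12_normalized",
      stringsAsFactors = FALSE))
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
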