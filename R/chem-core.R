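# Element masses, formula arithmetic, ion-species definitions and
# m/z <-> neutral-mass conversions. Everything downstream builds on this.

#' Mass constants used throughout the package
#'
#' Monoisotopic element masses (Da), the proton and electron masses, and the
#' 13C-12C mass increment. The 13C increment is fixed at 1.003355 Da, the
#' value conventionally used for isotope-chain spacing in LC-MS annotation
#' tools; the difference to the CODATA value (1.0033548) is far below any
#' m/z tolerance used here.
#'
#' @return A list with elements `elements` (named numeric vector of
#'   monoisotopic masses), `proton_mass`, `electron_mass` and `c13_delta`.
#' @export
#' @examples
#' mass_constants()$c13_delta
mass_constants <- function() {
  list(
    elements = c(
      C  = 12.0,
      H  = 1.0078250319,
      N  = 14.0030740052,
      O  = 15.9949146221,
      P  = 30.97376151,
      S  = 31.97207069,
      Na = 22.98976928,
      K  = 38.96370668,
      Cl = 34.96885271
    ),
    proton_mass   = 1.007276467,
    electron_mass = 0.00054857990,
    c13_delta     = 1.003355
  )
}

.MASS <- mass_constants()

#' Create a molecular formula
#'
#' A formula is a named integer vector of non-negative element counts with
#' class `ms_formula`. The default element universe is CHNOPS plus Na, K and
#' Cl (the latter three only appear in adduct arithmetic, never in mass
#' decomposition).
#'
#' @param counts named numeric vector or list, element symbol -> count.
#' @return An `ms_formula` object.
#' @export
#' @examples
#' ms_formula(c(C = 5, H = 9, N = 1, O = 4))
ms_formula <- function(counts = c()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    f <- structure(integer(0), class = "ms_formula")
    return(f)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("formula counts must be named by element symbol")
  }
  unknown <- setdiff(names(counts), names(.MASS$elements))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) {
    stop("negative element count in formula: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  structure(counts[order(names(counts))], class = "ms_formula")
}

#' @export
print.ms_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Parse a Hill-style formula string
#'
#' Accepts strings such as `"C5H9NO4"` or `"H2O"`: element symbols (one
#' upper-case letter optionally followed by one lower-case letter) each
#' followed by an optional count.
#'
#' @param text formula string.
#' @return An `ms_formula`.
#' @export
#' @examples
#' parse_formula("C5H9NO4")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("[[:space:]]", "", text)
  if (s == "" || s == "0") return(ms_formula())
  counts <- c()
  pos <- 1
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0 || m[1] == "") {
      stop(sprintf("malformed formula '%s' at position %d", text, pos))
    }
    sym <- m[2]
    if (!sym %in% names(.MASS$elements)) {
      # a two-letter guess may really be a one-letter element + garbage
      stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                   sym, text, pos))
    }
    n <- if (m[3] == "") 1L else as.integer(m[3])
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    pos <- pos + nchar(m[1])
  }
  ms_formula(counts)
}

#' Write a formula in Hill order
#'
#' Carbon first, then hydrogen, then all other elements alphabetically;
#' count 1 is implicit. Round-trips with [parse_formula()].
#'
#' @param f an `ms_formula`.
#' @return A character scalar, `""` for the empty formula.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) return("")
  syms <- names(f)
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(hill, function(s) {
    if (f[[s]] == 1L) s else paste0(s, f[[s]])
  }, ""), collapse = "")
}

as_formula <- function(f) {
  if (inherits(f, "ms_formula")) f else if (is.character(f)) parse_formula(f)
  else ms_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' @param f `ms_formula` or formula string.
#' @return Mass in Da; 0 for the empty formula.
#' @export
#' @examples
#' formula_mass("C5H9NO4")  # 147.0532
formula_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) return(0)
  sum(.MASS$elements[names(f)] * as.numeric(f))
}

#' Elementwise formula addition and subtraction
#'
#' Subtraction errors on any negative resulting count — this is how an
#' impossible neutral loss manifests.
#'
#' @param a,b formulas (or strings).
#' @param op `"add"` or `"subtract"`.
#' @return An `ms_formula`.
#' @export
#' @examples
#' formula_arith("C10H18N2O5S", "C5H11NO2S", "subtract")  # C5H7NO3
formula_arith <- function(a, b, op = c("add", "subtract")) {
  op <- match.arg(op)
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  ca <- stats::setNames(rep(0L, length(syms)), syms)
  ca[names(a)] <- a
  cb <- stats::setNames(rep(0L, length(syms)), syms)
  cb[names(b)] <- b
  res <- if (op == "add") ca + cb else ca - cb
  if (any(res < 0)) {
    stop("impossible subtraction: negative count for ",
         paste(syms[res < 0], collapse = ", "))
  }
  ms_formula(res)
}

#' @rdname formula_arith
#' @export
`+.ms_formula` <- function(a, b) formula_arith(a, b, "add")

#' @rdname formula_arith
#' @export
`-.ms_formula` <- function(a, b) formula_arith(a, b, "subtract")

#' Does formula `a` contain formula `b` elementwise?
#' @param a,b formulas (or strings).
#' @return logical.
#' @export
formula_contains <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  if (length(b) == 0) return(TRUE)
  all(names(b) %in% names(a)) && all(a[names(b)] >= b)
}

# ---------------------------------------------------------------------------
# Ion species

#' Define an ion species
#'
#' An ion species maps a neutral mass M to an observable m/z:
#' `mz = (multiplicity * M + delta_mass + n * c13_delta) / |charge|`
#' where n is an optional 13C label shift. `delta_mass` is a signed mass in
#' Da: the mass of whatever is attached minus whatever is lost, with ion
#' deltas computed on the physically correct charged-species convention
#' (proton = 1.007276 Da, i.e. atom masses corrected by the electron mass).
#'
#' @param label display label, e.g. `"[M+H]+"`.
#' @param delta_mass signed Da added to `multiplicity * M`.
#' @param charge signed integer, |charge| in 1:2.
#' @param multiplicity number of M moieties (2 for homoadducts).
#' @param is_seed seed adducts anchor pseudo spectra.
#' @param mode `"positive"` or `"negative"`.
#' @param loss optional neutral-loss formula string carried by the species
#'   (e.g. `"H2O"` for `[M+H-H2O]+`); used to reason about carbon counts.
#' @return A list of class `ion_species`.
#' @export
ion_species <- function(label, delta_mass, charge, multiplicity = 1L,
                        is_seed = FALSE, mode = c("positive", "negative"),
                        loss = "") {
  mode <- match.arg(mode)
  stopifnot(multiplicity >= 1, abs(charge) %in% c(1L, 2L), charge != 0)
  if (is_seed && multiplicity != 1) stop("seed species must have multiplicity 1")
  structure(list(label = label, delta_mass = delta_mass,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 is_seed = isTRUE(is_seed), mode = mode, loss = loss),
            class = "ion_species")
}

.proton <- function() .MASS$proton_mass
.el <- function(s) .MASS$elements[[s]]

#' Default adduct / neutral-loss lists
#'
#' The shipped positive-mode list uses `[M+H]+`, `[M+Na]+` and `[M+K]+` as
#' seeds; the negative-mode list uses `[M-H]-`. Both are plain lists of
#' [ion_species()] and can be edited, extended or replaced wholesale (see
#' [read_ion_list()]).
#'
#' @param mode `"positive"` or `"negative"`.
#' @return list of `ion_species`.
#' @export
default_ion_list <- function(mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  p <- .proton()
  if (mode == "positive") {
    list(
      ion_species("[M+H]+",        p,                               +1L, 1L, TRUE,  "positive"),
      ion_species("[M+Na]+",       .el("Na") - .MASS$electron_mass, +1L, 1L, TRUE,  "positive"),
      ion_species("[M+K]+",        .el("K") - .MASS$electron_mass,  +1L, 1L, TRUE,  "positive"),
      ion_species("[M+NH4]+",      formula_mass("NH3") + p,         +1L, 1L, FALSE, "positive"),
      ion_species("[M+2H]2+",      2 * p,                           +2L, 1L, FALSE, "positive"),
      ion_species("[M+H-H2O]+",    p - formula_mass("H2O"),         +1L, 1L, FALSE, "positive", loss = "H2O"),
      ion_species("[M+H-NH3]+",    p - formula_mass("NH3"),         +1L, 1L, FALSE, "positive", loss = "NH3"),
      ion_species("[M+H-HCOOH]+",  p - formula_mass("CH2O2"),       +1L, 1L, FALSE, "positive", loss = "CH2O2"),
      ion_species("[M+H-CO]+",     p - formula_mass("CO"),          +1L, 1L, FALSE, "positive", loss = "CO"),
      ion_species("[M+H-CO2]+",    p - formula_mass("CO2"),         +1L, 1L, FALSE, "positive", loss = "CO2"),
      ion_species("[2M+H]+",       p,                               +1L, 2L, FALSE, "positive"),
      ion_species("[2M+Na]+",      .el("Na") - .MASS$electron_mass, +1L, 2L, FALSE, "positive")
    )
  } else {
    list(
      ion_species("[M-H]-",       -p,                               -1L, 1L, TRUE,  "negative"),
      ion_species("[M+Cl]-",      .el("Cl") + .MASS$electron_mass,  -1L, 1L, FALSE, "negative"),
      ion_species("[M-H-H2O]-",   -p - formula_mass("H2O"),         -1L, 1L, FALSE, "negative", loss = "H2O"),
      ion_species("[2M-H]-",      -p,                               -1L, 2L, FALSE, "negative")
    )
  }
}

#' m/z of an ion species for a neutral mass
#'
#' @param M neutral monoisotopic mass (Da), > 0.
#' @param ion an [ion_species()].
#' @param label_shift n >= 0, number of 13C substitutions (adds
#'   `n * 1.003355` Da before the charge division).
#' @return m/z value.
#' @export
#' @examples
#' ion_mz(147.05316, default_ion_list()[[1]])  # [M+H]+ of glutamate
ion_mz <- function(M, ion, label_shift = 0L) {
  stopifnot(M > 0, label_shift >= 0)
  (ion$multiplicity * M + ion$delta_mass + label_shift * .MASS$c13_delta) /
    abs(ion$charge)
}

#' Neutral mass from an observed m/z under an ion-species hypothesis
#'
#' Inverse of [ion_mz()] at `label_shift = 0`.
#'
#' @param mz observed m/z, > 0.
#' @param ion an [ion_species()].
#' @return Neutral mass in Da; errors if the implied mass is not positive.
#' @export
neutral_mass_from_mz <- function(mz, ion) {
  stopifnot(mz > 0)
  M <- (mz * abs(ion$charge) - ion$delta_mass) / ion$multiplicity
  if (M <= 0) {
    stop(sprintf("non-positive neutral mass (%.4f) implied by m/z %.4f under %s",
                 M, mz, ion$label))
  }
  M
}

#' Insert a 13C label shift into an ion label
#'
#' `"[M+H]+"` with n = 5 becomes `"[M+5+H]+"`; `"[2M+H]+"` becomes
#' `"[2M+5+H]+"`. n = 0 returns the label unchanged.
#'
#' @param label ion label containing `"M"`.
#' @param n label shift.
#' @return character label.
#' @export
shifted_label <- function(label, n) {
  if (n == 0) return(label)
  sub("\\[([0-9]*)M", sprintf("[\\1M+%d", as.integer(n)), label)
}

# ---------------------------------------------------------------------------
# Ion list I/O (TSV or JSON config files)

#' Read an adduct/neutral-loss list from TSV or JSON
#'
#' TSV columns: label, delta_mass, charge, multiplicity, is_seed, mode and
#' optionally loss. JSON: an array of objects with the same fields.
#'
#' @param path file path (extension decides the format; `.json` vs table).
#' @return list of [ion_species()].
#' @export
read_ion_list <- function(path) {
  if (!file.exists(path)) stop("ion list file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("label", "delta_mass", "charge", "multiplicity", "is_seed", "mode")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) stop("ion list lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(rows$loss)) rows$loss <- ""
  lapply(seq_len(nrow(rows)), function(i) {
    ion_species(rows$label[i], rows$delta_mass[i], rows$charge[i],
                rows$multiplicity[i], as.logical(rows$is_seed[i]),
                rows$mode[i], loss = rows$loss[i])
  })
}

#' Write an adduct/neutral-loss list to TSV
#' @param ions list of [ion_species()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ion_list <- function(ions, path) {
  df <- do.call(rbind, lapply(ions, function(x) {
    data.frame(label = x$label, delta_mass = x$delta_mass, charge = x$charge,
               multiplicity = x$multiplicity, is_seed = x$is_seed,
               mode = x$mode, loss = x$loss, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
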