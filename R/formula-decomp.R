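# Accurate-mass decomposition over CHNOPS with a stack of chemical
# plausibility filters: element-count bounds, heteroatom-probability and
# element-ratio heuristics, Senior and Lewis (RDBE) rules, an
# oxygen/phosphorus rule, plus the two spectrum-aware constraints
# (required sub-formula from an observed neutral loss, fixed carbon count
# from a 12C/13C peak-pair distance).

DECOMP_ELEMENTS <- c("C", "H", "N", "O", "P", "S")

#' Element-count bounds for mass decomposition
#'
#' Defaults cover metabolites below ~500 Da: C 0-39, H 0-72, N 0-20,
#' O 0-20, P 0-9, S 0-10.
#'
#' @param ... per-element overrides given as `C = c(min, max)` or a single
#'   max (min 0), e.g. `element_bounds(C = c(5, 5), S = 0)`.
#' @return A named list of `c(min, max)` integer pairs over CHNOPS.
#' @export
#' @examples
#' element_bounds(N = 3)
element_bounds <- function(...) {
  b <- list(C = c(0L, 39L), H = c(0L, 72L), N = c(0L, 20L),
            O = c(0L, 20L), P = c(0L, 9L), S = c(0L, 10L))
  dots <- list(...)
  for (el in names(dots)) {
    if (!el %in% DECOMP_ELEMENTS) stop("unknown decomposition element: ", el)
    v <- as.integer(dots[[el]])
    if (length(v) == 1) v <- c(0L, v)
    if (length(v) != 2 || v[1] < 0 || v[1] > v[2]) {
      stop("bounds for ", el, " must be c(min, max) with 0 <= min <= max")
    }
    b[[el]] <- v
  }
  b
}

ALL_FILTERS <- c("element_number", "element_probability", "element_ratio",
                 "senior", "lewis", "oxygen_phosphorus")

#' Build a decomposition query
#'
#' @param target_mass neutral target mass in Da (> 0).
#' @param tolerance accepted mass error in Da (> 0); default 0.005.
#' @param bounds [element_bounds()] list.
#' @param fixed_carbon optional exact carbon count (the 13C filter: the
#'   12C/13C monoisotopic-pair distance fixes the carbon number).
#' @param required_subformula optional formula (or string); results must
#'   contain at least these element counts (the neutral-loss filter).
#' @param filters character vector of active filters, a subset of
#'   `element_number, element_probability, element_ratio, senior, lewis,
#'   oxygen_phosphorus`.
#' @return A `decomp_query` list.
#' @export
decomp_query <- function(target_mass, tolerance = 0.005,
                         bounds = element_bounds(), fixed_carbon = NULL,
                         required_subformula = NULL, filters = ALL_FILTERS) {
  if (!is.numeric(target_mass) || target_mass <= 0) {
    stop("target_mass must be > 0")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  bad <- setdiff(filters, ALL_FILTERS)
  if (length(bad) > 0) stop("unknown filter(s): ", paste(bad, collapse = ", "))
  if (!is.null(fixed_carbon)) {
    fixed_carbon <- as.integer(fixed_carbon)
    if (fixed_carbon < 0) stop("fixed_carbon must be >= 0")
  }
  if (!is.null(required_subformula)) {
    required_subformula <- as_formula(required_subformula)
  }
  structure(list(target_mass = target_mass, tolerance = tolerance,
                 bounds = bounds, fixed_carbon = fixed_carbon,
                 required_subformula = required_subformula,
                 filters = filters),
            class = "decomp_query")
}

fcount <- function(f, el) if (el %in% names(f)) as.integer(f[[el]]) else 0L

# Individual plausibility rules. Each returns TRUE when the formula passes.
.rule_element_number <- function(n, bounds) {
  all(vapply(DECOMP_ELEMENTS,
             function(el) n[[el]] >= bounds[[el]][1] && n[[el]] <= bounds[[el]][2],
             TRUE))
}

# Heteroatom probability heuristic: multiple simultaneously high NOPS counts
# are chemically implausible for small molecules.
.rule_element_probability <- function(n) {
  if (n$N > 1 && n$O > 1 && n$P > 1 && n$S > 1) {
    if (!(n$N < 10 && n$O < 20 && n$P < 4 && n$S < 3)) return(FALSE)
  }
  if (n$N > 3 && n$O > 3 && n$P > 3) {
    if (!(n$N < 11 && n$O < 22 && n$P < 6)) return(FALSE)
  }
  if (n$O > 1 && n$P > 1 && n$S > 1) {
    if (!(n$O < 14 && n$P < 3 && n$S < 3)) return(FALSE)
  }
  if (n$P > 1 && n$S > 1) {
    if (!(n$P < 3 && n$S < 3)) return(FALSE)
  }
  if (n$N > 1 && n$S > 1) {
    if (!(n$N < 10 && n$S < 4)) return(FALSE)
  }
  TRUE
}

.rule_element_ratio <- function(n) {
  if (n$C == 0) return(TRUE)
  hc <- n$H / n$C
  hc >= 0.1 && hc <= 6 && n$N / n$C <= 4 && n$O / n$C <= 3 &&
    n$P / n$C <= 2 && n$S / n$C <= 3
}

.VALENCE <- c(C = 4, H = 1, N = 3, O = 2, P = 3, S = 2)

# Senior: total valence even (even-electron species) and sufficient for a
# connected graph: sum of valences >= 2 * (atoms - 1).
.rule_senior <- function(n) {
  cnt <- c(n$C, n$H, n$N, n$O, n$P, n$S)
  atoms <- sum(cnt)
  if (atoms == 0) return(FALSE)
  vsum <- sum(.VALENCE[DECOMP_ELEMENTS] * cnt)
  (vsum %% 2 == 0) && (vsum >= 2 * (atoms - 1))
}

# Lewis: ring-plus-double-bond equivalents, RDBE = C - H/2 + N/2 + 1,
# must be a non-negative integer for an even-electron neutral molecule.
.rule_lewis <- function(n) {
  rdbe <- n$C - n$H / 2 + n$N / 2 + 1
  rdbe >= 0 && abs(rdbe - round(rdbe)) < 1e-9
}

# Phosphorus in metabolites is phosphate-like: require O >= 3.3 * P.
.rule_oxygen_phosphorus <- function(n) {
  n$P == 0 || n$O >= 3.3 * n$P
}

#' Evaluate the filter stack on one formula
#'
#' Each active filter in the query is checked independently; the report
#' lists every failed filter (including the spectrum-aware constraints
#' `fixed_carbon` and `required_subformula` and, when active, the mass
#' tolerance itself is *not* part of this report — it is a property of
#' [decompose_mass()]).
#'
#' @param f formula (or string).
#' @param q a [decomp_query()].
#' @return list with `formula`, `passed`, `failed_filters`.
#' @export
#' @examples
#' passes_filters("CPO", decomp_query(100))$failed_filters
passes_filters <- function(f, q) {
  f <- as_formula(f)
  n <- lapply(stats::setNames(DECOMP_ELEMENTS, DECOMP_ELEMENTS),
              function(el) fcount(f, el))
  failed <- character(0)
  chk <- function(name, ok) if (name %in% q$filters && !ok) failed <<- c(failed, name)
  chk("element_number", .rule_element_number(n, q$bounds))
  chk("element_probability", .rule_element_probability(n))
  chk("element_ratio", .rule_element_ratio(n))
  chk("senior", .rule_senior(n))
  chk("lewis", .rule_lewis(n))
  chk("oxygen_phosphorus", .rule_oxygen_phosphorus(n))
  if (!is.null(q$fixed_carbon) && n$C != q$fixed_carbon) {
    failed <- c(failed, "fixed_carbon")
  }
  if (!is.null(q$required_subformula) && !formula_contains(f, q$required_subformula)) {
    failed <- c(failed, "required_subformula")
  }
  list(formula = f, passed = length(failed) == 0, failed_filters = failed)
}

#' Decompose an accurate mass into candidate sum formulae
#'
#' Recursive descent over elements in order of decreasing mass with
#' branch-and-bound pruning on the remaining mass; hydrogen is resolved
#' arithmetically at the leaves. The result is complete with respect to the
#' bounds and exact within the tolerance: it equals brute-force enumeration.
#'
#' @param q a [decomp_query()], or a numeric mass (then `...` is passed to
#'   [decomp_query()]).
#' @param ... forwarded to [decomp_query()] when `q` is numeric.
#' @return A data.frame with columns `formula` (Hill string), `mass`,
#'   `error` (mass - target, Da), `C`..`S` counts, ordered by |error|
#'   ascending (ties: Hill string). Zero rows when nothing fits.
#' @export
#' @examples
#' decompose_mass(147.052, tolerance = 0.005, fixed_carbon = 5)
decompose_mass <- function(q, ...) {
  if (is.numeric(q)) q <- decomp_query(q, ...)
  stopifnot(inherits(q, "decomp_query"))
  b <- q$bounds
  if (!is.null(q$fixed_carbon)) {
    fc <- q$fixed_carbon
    b$C <- c(max(b$C[1], fc), min(b$C[2], fc))
    if (b$C[1] > b$C[2]) return(.decomp_result(list(), q))
  }
  if (!is.null(q$required_subformula)) {
    rs <- q$required_subformula
    for (el in names(rs)) {
      if (!el %in% DECOMP_ELEMENTS) return(.decomp_result(list(), q))
      b[[el]][1] <- max(b[[el]][1], as.integer(rs[[el]]))
      if (b[[el]][1] > b[[el]][2]) return(.decomp_result(list(), q))
    }
  }
  em <- .MASS$elements
  # heaviest first, hydrogen last
  order_els <- c("S", "P", "O", "N", "C")
  mH <- em[["H"]]
  hits <- list()
  counts <- stats::setNames(integer(6), DECOMP_ELEMENTS)

  # max mass attainable from elements order_els[i..] plus hydrogen
  suffix_max <- numeric(length(order_els) + 1)
  suffix_max[length(order_els) + 1] <- b$H[2] * mH
  for (i in rev(seq_along(order_els))) {
    el <- order_els[i]
    suffix_max[i] <- suffix_max[i + 1] + b[[el]][2] * em[[el]]
  }
  suffix_min <- numeric(length(order_els) + 1)
  suffix_min[length(order_els) + 1] <- b$H[1] * mH
  for (i in rev(seq_along(order_els))) {
    el <- order_els[i]
    suffix_min[i] <- suffix_min[i + 1] + b[[el]][1] * em[[el]]
  }

  recurse <- function(i, remaining) {
    if (remaining + q$tolerance < suffix_min[i] ||
        remaining - q$tolerance > suffix_max[i]) {
      return(invisible(NULL))
    }
    if (i > length(order_els)) {
      # solve remaining = h * mH within tolerance
      h_lo <- max(b$H[1], ceiling((remaining - q$tolerance) / mH))
      h_hi <- min(b$H[2], floor((remaining + q$tolerance) / mH))
      if (h_hi < h_lo) return(invisible(NULL))
      for (h in h_lo:h_hi) {
        counts[["H"]] <<- as.integer(h)
        f <- ms_formula(counts[counts > 0])
        rep <- passes_filters(f, q)
        if (rep$passed) hits[[length(hits) + 1L]] <<- f
      }
      counts[["H"]] <<- 0L
      return(invisible(NULL))
    }
    el <- order_els[i]
    m_el <- em[[el]]
    k_hi <- min(b[[el]][2], floor((remaining + q$tolerance - suffix_min[i + 1]) / m_el))
    k_lo <- b[[el]][1]
    if (k_hi < k_lo) return(invisible(NULL))
    for (k in k_lo:k_hi) {
      counts[[el]] <<- as.integer(k)
      recurse(i + 1, remaining - k * m_el)
    }
    counts[[el]] <<- 0L
    invisible(NULL)
  }
  recurse(1, q$target_mass)
  .decomp_result(hits, q)
}

.decomp_result <- function(hits, q) {
  if (length(hits) == 0) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      error = numeric(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), P = integer(0),
                      S = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(f) {
    m <- formula_mass(f)
    data.frame(formula = format_formula(f), mass = m, error = m - q$target_mass,
               C = fcount(f, "C"), H = fcount(f, "H"), N = fcount(f, "N"),
               O = fcount(f, "O"), P = fcount(f, "P"), S = fcount(f, "S"),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(abs(df$error), df$formula), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# memoised carbon-range lookups keyed on rounded mass; the pipeline calls
# this for every 13C pair hypothesis and masses repeat heavily.
.carbon_cache <- new.env(parent = emptyenv())

#' Possible carbon counts for a neutral mass
#'
#' The set of carbon numbers over all chemically plausible decompositions of
#' the mass (all plausibility filters active, no spectrum-aware constraints).
#' Used to vet candidate 12C/13C peak-pair distances.
#'
#' @param neutral_mass Da, > 0.
#' @param tolerance Da.
#' @param bounds [element_bounds()].
#' @param cache reuse memoised results (keyed on mass rounded to 4 d.p.).
#' @return Sorted integer vector (possibly empty).
#' @export
#' @examples
#' carbon_count_range(147.0532)  # contains 5
carbon_count_range <- function(neutral_mass, tolerance = 0.005,
                               bounds = element_bounds(), cache = TRUE) {
  key <- sprintf("%.4f|%.5f", neutral_mass, tolerance)
  if (cache && !is.null(.carbon_cache[[key]])) return(.carbon_cache[[key]])
  df <- decompose_mass(decomp_query(neutral_mass, tolerance, bounds))
  res <- sort(unique(df$C))
  if (cache) .carbon_cache[[key]] <- res
  res
}
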