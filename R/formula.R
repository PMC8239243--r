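#' Parse a molecular formula string
#'
#' Parses formulas written with element symbols, integer multipliers and
#' (nested) parenthesized groups, e.g. `"Cu(C10H9ClN4O2S)2Cl2"`. An optional
#' hydrate suffix (`".2H2O"` or `"·2H2O"`) is parsed into a separate
#' water-of-crystallization count, not into the core composition, because
#' thermal mass ledgers need the two bookkept apart. A leading integer
#' multiplier (`"2HCl"`) scales the whole formula, which is convenient for
#' decomposition-fragment lists.
#'
#' @param text A formula string (or a `chem_formula`, returned unchanged).
#' @param label Free-text label kept alongside the composition.
#' @return A `chem_formula` object: a list with `composition` (named integer
#'   vector of element counts), `hydrate_waters`, and `label`.
#' @examples
#' parse_formula("H2O")
#' parse_formula("Cu(C10H9ClN4O2S)2Cl2")
#' parse_formula("CuC20H18Cl4N8O4S2.2H2O")
#' @export
parse_formula <- function(text, label = NULL) {
  if (inherits(text, "chem_formula")) return(text)
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    abort("`text` must be a single formula string.")
  }
  label <- label %||% text
  raw <- gsub("\\s+", "", text)
  if (!nzchar(raw)) abort("Empty formula string.")

  # hydrate suffix: '.nH2O' or '·nH2O' (middle dot), n optional (= 1)
  waters <- 0L
  m <- regmatches(raw, regexec("[.·⋅](\\d*)H2O$", raw))[[1]]
  if (length(m) > 0) {
    waters <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    raw <- sub("[.·⋅]\\d*H2O$", "", raw)
    if (!nzchar(raw)) abort("Formula has a hydrate part but no core composition.")
  }

  # optional leading multiplier for fragment shorthand like '2HCl'
  mult <- 1L
  m <- regmatches(raw, regexec("^(\\d+)(.*)$", raw))[[1]]
  if (length(m) > 0) {
    mult <- as.integer(m[2])
    if (mult <= 0) abort("Non-positive leading multiplier.",
                         class = "coordkit_bad_multiplier")
    raw <- m[3]
    if (!nzchar(raw)) abort("Leading multiplier with no formula body.")
  }

  comp <- parse_group(strsplit(raw, "")[[1]], depth = 0)
  comp <- comp * mult
  comp <- comp[order(hill_rank(names(comp)), names(comp))]
  structure(
    list(composition = comp, hydrate_waters = waters, label = label),
    class = "chem_formula"
  )
}

# recursive-descent parse of one (sub)group; `chars` is consumed via an
# environment-held cursor so nested calls share position state
parse_group <- function(chars, depth) {
  if (depth > 10) abort("Parenthesis nesting too deep.")
  pos <- 1L
  n <- length(chars)
  counts <- numeric(0)
  add <- function(counts, sym, k) {
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + k
    counts
  }
  read_int <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) return(NA_integer_)
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "(") {
      # locate matching close
      bal <- 1L; j <- pos + 1L
      while (j <= n && bal > 0L) {
        if (chars[j] == "(") bal <- bal + 1L
        if (chars[j] == ")") bal <- bal - 1L
        j <- j + 1L
      }
      if (bal != 0L) abort("Unbalanced parentheses in formula.",
                           class = "coordkit_unbalanced_parens")
      inner <- parse_group(chars[(pos + 1L):(j - 2L)], depth + 1L)
      pos <- j
      k <- read_int()
      if (!is.na(k) && k <= 0) abort("Non-positive group multiplier.",
                                     class = "coordkit_bad_multiplier")
      if (is.na(k)) k <- 1L
      for (sym in names(inner)) counts <- add(counts, sym, inner[[sym]] * k)
    } else if (ch == ")") {
      abort("Unbalanced parentheses in formula.",
            class = "coordkit_unbalanced_parens")
    } else if (grepl("[A-Z]", ch)) {
      sym <- ch
      if (pos + 1L <= n && grepl("[a-z]", chars[pos + 1L])) {
        sym <- paste0(ch, chars[pos + 1L])
        pos <- pos + 1L
      }
      pos <- pos + 1L
      atomic_weight_of(sym)  # validates the symbol
      k <- read_int()
      if (!is.na(k) && k <= 0) abort("Non-positive element multiplier.",
                                     class = "coordkit_bad_multiplier")
      if (is.na(k)) k <- 1L
      counts <- add(counts, sym, k)
    } else {
      abort(sprintf("Unexpected character '%s' in formula.", ch))
    }
  }
  if (length(counts) == 0) abort("Formula group contains no elements.")
  counts
}

# Hill-system ordering: C, H first when carbon present, otherwise alphabetical
hill_rank <- function(elements) {
  if ("C" %in% elements) {
    match(elements, c("C", "H"), nomatch = 3L)
  } else {
    rep(3L, length(elements))
  }
}

#' Render a formula as a canonical string
#'
#' Hill-system ordering (C, H, then alphabetical; fully alphabetical when no
#' carbon is present) with a `·nH2O` hydrate suffix. Round-trips through
#' [parse_formula()].
#'
#' @param f A `chem_formula` or formula string.
#' @return A single string.
#' @examples
#' format_formula(parse_formula("Cu(C10H9ClN4O2S)2Cl2"))
#' @export
format_formula <- function(f) {
  f <- parse_formula(f)
  comp <- f$composition
  body <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  if (f$hydrate_waters > 0) {
    body <- paste0(body, "·", f$hydrate_waters, "H2O")
  }
  body
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  if (!identical(x$label, format_formula(x))) cat("label: ", x$label, "\n", sep = "")
  invisible(x)
}

# composition on a mass basis: hydrate adds the waters' H and O to the pool
basis_composition <- function(f, basis = c("anhydrous", "hydrate")) {
  basis <- match.arg(basis)
  comp <- f$composition
  if (basis == "hydrate" && f$hydrate_waters > 0) {
    add <- c(H = 2, O = 1) * f$hydrate_waters
    for (sym in names(add)) {
      comp[sym] <- (if (sym %in% names(comp)) comp[[sym]] else 0) + add[[sym]]
    }
    comp <- comp[order(hill_rank(names(comp)), names(comp))]
  }
  comp
}

#' Molecular weight of a formula
#'
#' @param f A `chem_formula` or formula string.
#' @param basis `"anhydrous"` (core composition only) or `"hydrate"`
#'   (includes waters of crystallization).
#' @return Molecular weight in g/mol.
#' @examples
#' molecular_weight("H2O")
#' molecular_weight("CuC20H18Cl4N8O4S2.2H2O", basis = "hydrate")
#' @export
molecular_weight <- function(f, basis = c("anhydrous", "hydrate")) {
  f <- parse_formula(f)
  comp <- basis_composition(f, basis)
  sum(comp * atomic_weight_of(names(comp)))
}

#' Elemental percent composition
#'
#' Mass percent of each element, mirroring the C/N/S/M columns of an
#' elemental-analysis table. Percents sum to 100.
#'
#' @inheritParams molecular_weight
#' @return A tibble with columns `element`, `count`, `mass_g_mol`, `percent`,
#'   carrying the molecular weight, basis and label as attributes.
#' @examples
#' percent_composition("Cu(C10H9ClN4O2S)2Cl2")
#' @export
percent_composition <- function(f, basis = c("anhydrous", "hydrate")) {
  f <- parse_formula(f)
  basis <- match.arg(basis)
  comp <- basis_composition(f, basis)
  mass <- comp * atomic_weight_of(names(comp))
  mw <- sum(mass)
  out <- tibble(
    element = names(comp),
    count = as.integer(comp),
    mass_g_mol = unname(mass),
    percent = unname(100 * mass / mw)
  )
  attr(out, "molecular_weight") <- mw
  attr(out, "basis") <- basis
  attr(out, "label") <- f$label
  out
}

# expand a fragment spec ('2HCl+2SO2', a chem_formula, or a list of either)
# into a list of chem_formula
expand_fragments <- function(fragments) {
  if (inherits(fragments, "chem_formula")) return(list(fragments))
  if (is.character(fragments)) {
    fragments <- unlist(strsplit(fragments, "+", fixed = TRUE))
    return(lapply(trimws(fragments), parse_formula))
  }
  if (is.list(fragments)) {
    return(unlist(lapply(fragments, expand_fragments), recursive = FALSE))
  }
  abort("`fragments` must be formula strings or chem_formula objects.")
}

fragment_counts <- function(frags) {
  counts <- numeric(0)
  for (f in frags) {
    comp <- basis_composition(f, if (f$hydrate_waters > 0) "hydrate" else "anhydrous")
    for (sym in names(comp)) {
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + comp[[sym]]
    }
  }
  counts
}

check_fragments_within <- function(parent_counts, frag_counts, context) {
  for (sym in names(frag_counts)) {
    have <- if (sym %in% names(parent_counts)) parent_counts[[sym]] else 0
    if (frag_counts[[sym]] > have + 1e-9) {
      abort(sprintf(
        "Mass-balance error in %s: fragments need %s x %g but parent has %g.",
        context, sym, frag_counts[[sym]], have),
        class = "coordkit_mass_balance")
    }
  }
  invisible(TRUE)
}

#' Mass-loss percent of assigned fragments
#'
#' Percent of the parent mass (on the stated basis) accounted for by a list
#' of decomposition fragments, as in a thermogravimetric step assignment.
#'
#' @param parent Parent `chem_formula` or string.
#' @param fragments Fragment spec: a `"+"`-joined string with optional
#'   leading multipliers (`"2HCl+2SO2"`), a `chem_formula`, or a list.
#' @param basis Mass basis of the parent (`"anhydrous"` or `"hydrate"`).
#' @return Mass-loss percent (scalar).
#' @examples
#' fragment_loss_percent("CuC20H18Cl4N8O4S2.2H2O", "2H2O", basis = "hydrate")
#' fragment_loss_percent("CuC20H18Cl4N8O4S2", "CuO")
#' @export
fragment_loss_percent <- function(parent, fragments,
                                  basis = c("anhydrous", "hydrate")) {
  parent <- parse_formula(parent)
  basis <- match.arg(basis)
  frags <- expand_fragments(fragments)
  fc <- fragment_counts(frags)
  check_fragments_within(basis_composition(parent, basis), fc, "fragment_loss_percent")
  frag_mass <- sum(fc * atomic_weight_of(names(fc)))
  100 * frag_mass / molecular_weight(parent, basis)
}

#' Classify electrolyte type from molar conductance
#'
#' Classification of DMF-solution molar conductance (10^-3 M) into
#' non-electrolyte, 1:1 or 2:1 electrolyte. Default cut-offs: below 20
#' non-electrolyte, 60--95 a 1:1 electrolyte, above 120 a 2:1 electrolyte;
#' the gaps are flagged `"ambiguous"`.
#'
#' @param lambda_m Molar conductance(s), ohm^-1 cm^2 mol^-1. Must be >= 0.
#' @param cutoffs Named numeric vector `c(non, one_lo, one_hi, two)`.
#' @return A tibble with columns `lambda_m` and `category`.
#' @examples
#' classify_electrolyte(c(94, 1.56, 152))
#' @export
classify_electrolyte <- function(lambda_m,
                                 cutoffs = c(non = 20, one_lo = 60,
                                             one_hi = 95, two = 120)) {
  if (!is.numeric(lambda_m) || any(!is.finite(lambda_m)) || any(lambda_m < 0)) {
    abort("`lambda_m` must be non-negative and finite.")
  }
  category <- dplyr::case_when(
    lambda_m < cutoffs[["non"]] ~ "non-electrolyte",
    lambda_m >= cutoffs[["one_lo"]] & lambda_m <= cutoffs[["one_hi"]] ~ "1:1 electrolyte",
    lambda_m > cutoffs[["two"]] ~ "2:1 electrolyte",
    TRUE ~ "ambiguous"
  )
  tibble(lambda_m = lambda_m, category = category)
}
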