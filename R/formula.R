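# Elemental-formula arithmetic over the C/H/N/O space used by NO3- chemical
# ionization of monoterpene oxidation products. All mass bookkeeping in the
# package goes through the chem_formula class defined here.

# CODATA/IUPAC 2021 monoisotopic masses (Da). Kept as a named constant and
# mirrored in inst/extdata/atomic_masses.json; the two must stay in sync.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196
)
ELECTRON_MASS <- 0.00054857990946

ELEMENTS <- names(ATOMIC_MASS)

#' Reference mass constants
#'
#' Monoisotopic masses of the supported elements (C, H, N, O) and the
#' electron mass, in Da. These are fixed reference values; they are also
#' shipped as a plain-text JSON file under `extdata` so downstream outputs
#' can record the mass table they were computed with.
#'
#' @return A list with components `elements` (named numeric vector of
#'   monoisotopic masses in Da) and `electron` (electron mass in Da).
#' @export
#' @examples
#' mass_constants()$elements[["O"]]
mass_constants <- function() {
  list(elements = ATOMIC_MASS, electron = ELECTRON_MASS)
}

#' Create an elemental formula
#'
#' The unit of all mass arithmetic in the package: non-negative counts of
#' C, H, N and O atoms, an integer charge (0 or -1; only singly charged
#' anions occur in NO3- chemical ionization), and a radical flag marking
#' odd-electron species such as peroxy-radical adducts RO2.NO3- observed as
#' radical anions.
#'
#' @param c,h,n,o Non-negative integer element counts.
#' @param charge Integer charge, 0 (neutral) or -1 (anion).
#' @param radical Logical; `TRUE` for odd-electron species.
#' @return An object of class `chem_formula`.
#' @export
#' @examples
#' chem_formula(c = 10, h = 15, n = 1, o = 11, charge = -1, radical = TRUE)
chem_formula <- function(c = 0, h = 0, n = 0, o = 0, charge = 0, radical = FALSE) {
  counts <- base::c(C = c, H = h, N = n, O = o)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  if (!charge %in% base::c(0L, -1L)) {
    stop("charge must be 0 or -1", call. = FALSE)
  }
  structure(
    as.integer(round(counts)),
    names = ELEMENTS,
    charge = as.integer(charge),
    radical = isTRUE(radical),
    class = "chem_formula"
  )
}

#' @export
is_chem_formula <- function(x) inherits(x, "chem_formula")

formula_charge <- function(f) attr(f, "charge")
formula_radical <- function(f) attr(f, "radical")

#' Parse a formula string
#'
#' Accepts the combined anion spelling (`"C10H15NO11-"`), the adduct
#' spelling (`"C10H15O8.NO3-"`, with `.` or the middle dot as separator),
#' an optional radical marker (`*` or the bullet character) and a trailing
#' `-` for an anion. Adduct spellings are normalized to the combined
#' composition (the NO3 part is folded into the element counts).
#'
#' @param x A single formula string.
#' @return A `chem_formula`.
#' @export
#' @examples
#' parse_formula("C10H15O8.NO3-")  # same composition as "C10H15NO11-"
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s", "", x)
  radical <- grepl("[*•]", s)
  s <- gsub("[*•]", "", s)
  charge <- 0L
  if (grepl("-$", s)) {
    charge <- -1L
    s <- sub("-$", "", s)
  }
  parts <- strsplit(s, "[.·]", fixed = FALSE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) < 1L) stop("empty formula string: ", sQuote(x), call. = FALSE)
  counts <- base::c(C = 0L, H = 0L, N = 0L, O = 0L)
  for (p in parts) {
    if (!grepl("^([CHNO][0-9]*)+$", p)) {
      stop("cannot parse formula ", sQuote(x), ": unsupported token ", sQuote(p),
           call. = FALSE)
    }
    m <- gregexpr("[CHNO][0-9]*", p)[[1]]
    for (tok in regmatches(p, list(m))[[1]]) {
      el <- substr(tok, 1, 1)
      k <- substr(tok, 2, nchar(tok))
      counts[el] <- counts[el] + if (nzchar(k)) as.integer(k) else 1L
    }
  }
  chem_formula(counts[["C"]], counts[["H"]], counts[["N"]], counts[["O"]],
               charge = charge, radical = radical)
}

#' Format a formula as a string
#'
#' Hill-order element string (C, H, then remaining elements alphabetically)
#' with optional radical marker `*` and a trailing `-` for anions. With
#' `style = "adduct"` an NO3 unit is split out as a `.NO3-` suffix when the
#' composition contains at least one N and three O.
#'
#' @param x A `chem_formula`.
#' @param style `"combined"` (default) or `"adduct"`.
#' @param ... Unused.
#' @return A character string.
#' @export
format.chem_formula <- function(x, style = c("combined", "adduct"), ...) {
  style <- match.arg(style)
  fmt1 <- function(counts) {
    out <- ""
    for (el in ELEMENTS) {
      k <- counts[[el]]
      if (k > 0L) out <- paste0(out, el, if (k > 1L) k else "")
    }
    out
  }
  counts <- stats::setNames(as.integer(x), ELEMENTS)
  suffix <- paste0(if (formula_radical(x)) "*" else "",
                   if (formula_charge(x) == -1L) "-" else "")
  if (style == "adduct" && counts[["N"]] >= 1L && counts[["O"]] >= 3L) {
    core <- counts - base::c(C = 0L, H = 0L, N = 1L, O = 3L)
    return(paste0(fmt1(core), ".NO3", suffix))
  }
  if (all(counts == 0L)) return(paste0("(empty)", suffix))
  paste0(fmt1(counts), suffix)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x),
      "  charge=", formula_charge(x),
      if (formula_radical(x)) "  radical" else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.chem_formula <- function(x, ...) format(x, ...)

#' @export
`==.chem_formula` <- function(e1, e2) {
  all(unclass(e1) == unclass(e2)) &&
    formula_charge(e1) == formula_charge(e2) &&
    formula_radical(e1) == formula_radical(e2)
}

#' Add two formulas
#'
#' Element-wise sum; used for adduct formation and dimer accretion
#' arithmetic (RO2 + RO2 -> ROOR + O2). Charges add; the radical flag is
#' the exclusive-or of the inputs (two odd-electron species combine to a
#' closed shell).
#'
#' @param a,b `chem_formula` objects.
#' @return A `chem_formula`.
#' @export
formula_add <- function(a, b) {
  stopifnot(is_chem_formula(a), is_chem_formula(b))
  counts <- unclass(a) + unclass(b)
  chem_formula(counts[["C"]], counts[["H"]], counts[["N"]], counts[["O"]],
               charge = max(-1L, formula_charge(a) + formula_charge(b)),
               radical = xor(formula_radical(a), formula_radical(b)))
}

#' Subtract a fragment formula (neutral loss)
#'
#' Element-wise difference between a parent ion composition and a product
#' ion composition. The result is the neutral loss: charge 0, closed
#' shell. Errors if the fragment is not an element-wise sub-formula of the
#' parent.
#'
#' @param parent,fragment `chem_formula` objects.
#' @return A neutral `chem_formula`.
#' @export
#' @examples
#' o2 <- formula_subtract(parse_formula("C10H15NO11-"), parse_formula("C10H15NO9-"))
#' format(o2)  # "O2"
formula_subtract <- function(parent, fragment) {
  stopifnot(is_chem_formula(parent), is_chem_formula(fragment))
  counts <- unclass(parent) - unclass(fragment)
  if (any(counts < 0L)) {
    bad <- ELEMENTS[counts < 0L]
    stop("fragment ", format(fragment), " is not a sub-formula of ",
         format(parent), " (negative ", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  }
  chem_formula(counts[["C"]], counts[["H"]], counts[["N"]], counts[["O"]],
               charge = 0L, radical = FALSE)
}

#' @export
`+.chem_formula` <- function(e1, e2) formula_add(e1, e2)

#' @export
`-.chem_formula` <- function(e1, e2) formula_subtract(e1, e2)

#' Monoisotopic mass
#'
#' Sum of element monoisotopic masses, plus one electron mass for an anion
#' when `include_electron` is `TRUE` (the default, physically correct
#' convention for measured m/z).
#'
#' @param f A `chem_formula`.
#' @param include_electron Logical; include the electron mass for charged
#'   species.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("NO3-"))  # 61.98837
monoisotopic_mass <- function(f, include_electron = TRUE) {
  stopifnot(is_chem_formula(f))
  m <- sum(as.numeric(f) * ATOMIC_MASS)
  if (include_electron && formula_charge(f) != 0L) {
    m <- m - formula_charge(f) * ELECTRON_MASS
  }
  m
}

#' Mass-to-charge ratio of an ion
#'
#' @param f A singly charged `chem_formula`.
#' @param include_electron Passed to [monoisotopic_mass()].
#' @return m/z value.
#' @export
mz <- function(f, include_electron = TRUE) {
  stopifnot(is_chem_formula(f))
  if (formula_charge(f) == 0L) {
    stop("neutral species ", format(f), " has no m/z", call. = FALSE)
  }
  monoisotopic_mass(f, include_electron = include_electron) / abs(formula_charge(f))
}

#' Signed mass error in parts per million
#'
#' Computed relative to the theoretical value, the standard convention:
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param theoretical,observed m/z values (vectorized).
#' @return Signed ppm error.
#' @export
ppm_error <- function(theoretical, observed) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' Ring-plus-double-bond equivalents
#'
#' `C - H/2 + N/2 + 1`; half-integer values are legitimate for radicals
#' and adduct ions and are not rejected.
#'
#' @param f A `chem_formula`.
#' @return RDBE value (possibly half-integer).
#' @export
rdbe <- function(f) {
  stopifnot(is_chem_formula(f))
  unname(f[["C"]] - f[["H"]] / 2 + f[["N"]] / 2 + 1)
}

#' Enumeration bounds for formula assignment
#'
#' Element-count windows, an RDBE window and a ppm tolerance constraining
#' the formula search. Nitrogen is capped at 2 by default: ions are
#' assumed to contain only C, H and O plus at most two nitrogens brought in
#' by the NO3- / HNO3.NO3- reagent ions. The default windows cover C10
#' monomers, C20 accretion dimers and their nitrate adducts.
#'
#' @param c,h,n,o Length-2 integer vectors `c(min, max)`.
#' @param rdbe Length-2 numeric RDBE window.
#' @param tol_ppm Matching tolerance in ppm (> 0), default 5.
#' @return An object of class `enumeration_bounds`.
#' @export
enumeration_bounds <- function(c = base::c(0L, 25L), h = base::c(0L, 45L),
                               n = base::c(0L, 2L), o = base::c(0L, 20L),
                               rdbe = base::c(-0.5, 20), tol_ppm = 5) {
  stopifnot(tol_ppm > 0, length(rdbe) == 2L)
  chk <- function(x) {
    stopifnot(length(x) == 2L, x[1] >= 0, x[1] <= x[2])
    as.integer(x)
  }
  structure(
    list(c = chk(c), h = chk(h), n = chk(n), o = chk(o),
         rdbe = as.numeric(rdbe), tol_ppm = as.numeric(tol_ppm)),
    class = "enumeration_bounds"
  )
}

#' Enumerate candidate formulas for an observed m/z
#'
#' Finds every C/H/N/O composition within `bounds` whose singly charged
#' anion m/z (electron-inclusive by default) lies within `tol_ppm` of the
#' observed value, ordered by absolute ppm error and then by ascending
#' nitrogen count. The search iterates over the C/N/O grid and solves for
#' the hydrogen count analytically, so it is exact over the bounded space.
#'
#' @param observed_mz Observed m/z (> 0).
#' @param bounds An [enumeration_bounds()] object.
#' @param include_electron Electron-mass convention for the anion m/z.
#' @return A data frame with columns `formula`, `C`, `H`, `N`, `O`, `mz`,
#'   `ppm`, `rdbe`, ordered best match first. Zero rows when nothing
#'   matches.
#' @export
#' @examples
#' enumerate_formulas(61.9884)$formula[1]  # "NO3-"
enumerate_formulas <- function(observed_mz, bounds = enumeration_bounds(),
                               include_electron = TRUE) {
  stopifnot(observed_mz > 0)
  target <- observed_mz - if (include_electron) ELECTRON_MASS else 0
  tol_da <- observed_mz * bounds$tol_ppm * 1e-6
  grid <- expand.grid(C = bounds$c[1]:bounds$c[2],
                      N = bounds$n[1]:bounds$n[2],
                      O = bounds$o[1]:bounds$o[2])
  base_mass <- grid$C * ATOMIC_MASS[["C"]] + grid$N * ATOMIC_MASS[["N"]] +
    grid$O * ATOMIC_MASS[["O"]]
  h_exact <- (target - base_mass) / ATOMIC_MASS[["H"]]
  h <- round(h_exact)
  ok <- h >= bounds$h[1] & h <= bounds$h[2] &
    abs(h * ATOMIC_MASS[["H"]] + base_mass - target) <= tol_da
  if (!any(ok)) {
    return(data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), mz = numeric(),
                      ppm = numeric(), rdbe = numeric()))
  }
  grid <- grid[ok, , drop = FALSE]
  grid$H <- as.integer(h[ok])
  grid$rdbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  grid <- grid[grid$rdbe >= bounds$rdbe[1] & grid$rdbe <= bounds$rdbe[2], ,
               drop = FALSE]
  if (nrow(grid) == 0L) {
    return(data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), mz = numeric(),
                      ppm = numeric(), rdbe = numeric()))
  }
  grid$mz <- grid$C * ATOMIC_MASS[["C"]] + grid$H * ATOMIC_MASS[["H"]] +
    grid$N * ATOMIC_MASS[["N"]] + grid$O * ATOMIC_MASS[["O"]] +
    if (include_electron) ELECTRON_MASS else 0
  grid$ppm <- ppm_error(grid$mz, observed_mz)
  grid <- grid[order(abs(grid$ppm), grid$N), , drop = FALSE]
  grid$formula <- vapply(seq_len(nrow(grid)), function(i) {
    format(chem_formula(grid$C[i], grid$H[i], grid$N[i], grid$O[i],
                        charge = -1L))
  }, character(1))
  rownames(grid) <- NULL
  grid[, base::c("formula", "C", "H", "N", "O", "mz", "ppm", "rdbe")]
}
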