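# ROOR accretion-product (dimer) arithmetic: RO2 + RO2 -> ROOR + O2,
# RO-OR peroxide-bond cleavage with H-exchange, and ranking of candidate
# RO2 precursor pairs from observed cleavage product ions.

O2_FORMULA <- function() chem_formula(o = 2)
H_FORMULA <- function() chem_formula(h = 1)
O_FORMULA <- function() chem_formula(o = 1)

#' Accretion dimer formula from two RO2 precursors
#'
#' `dimer = a + b - O2`, the composition of the ROOR product of an
#' RO2 + RO2 accretion reaction.
#'
#' @param a,b RO2 `structure_record` objects.
#' @return A neutral `chem_formula`.
#' @export
dimer_formula <- function(a, b) {
  stopifnot(inherits(a, "structure_record"), inherits(b, "structure_record"))
  if (a$species != "RO2_radical" || b$species != "RO2_radical") {
    stop("dimer precursors must be RO2 radical records", call. = FALSE)
  }
  formula_subtract(formula_add(a$formula, b$formula), O2_FORMULA())
}

# Neutral monomer-side fragments of RO-OR cleavage with H-exchange: the
# H-donor side ends up one H short with a new carbonyl ("ketone side"),
# the H-acceptor side gains one H ("alcohol side"). Side formulas are the
# RO2 compositions; the alkoxy RO is the side minus one O.
ketone_side <- function(s) {
  formula_subtract(s$formula, formula_add(O_FORMULA(), H_FORMULA()))
}
alcohol_side <- function(s) {
  formula_add(formula_subtract(s$formula, O_FORMULA()), H_FORMULA())
}
as_no3_adduct <- function(neutral) {
  f <- formula_add(neutral, chem_formula(n = 1, o = 3))
  chem_formula(f[["C"]], f[["H"]], f[["N"]], f[["O"]], charge = -1L)
}
as_deprotonated <- function(neutral) {
  f <- formula_subtract(neutral, H_FORMULA())
  chem_formula(f[["C"]], f[["H"]], f[["N"]], f[["O"]], charge = -1L)
}

#' Expected product ions of dimer RO-OR cleavage
#'
#' Cleavage of the peroxide RO-OR bond gives two alkoxy radicals which
#' exchange a hydrogen: the donor side loses H (carbonyl product) and the
#' acceptor side gains H (alcohol/acid product); both are detected as
#' NO3- adducts. When neither side is an acylperoxy radical, both
#' donor/acceptor assignments are open and both sides' H-loss and H-gain
#' adducts are expected. An acylperoxy side has no abstractable hydrogen
#' on its acyloxy radical and cannot act as H-donor, so only one pathway
#' remains: the alkyl side donates (its H-gain product is suppressed) and
#' the acyl side accepts.
#'
#' @param a,b RO2 `structure_record` objects.
#' @return Character vector of expected product-ion formulas (NO3- adduct
#'   anions), unique and sorted, with attribute `pathways`: a list of
#'   `(donor, acceptor)` id pairs with their neutral products.
#' @export
dimer_cleavage_products <- function(a, b) {
  stopifnot(inherits(a, "structure_record"), inherits(b, "structure_record"))
  if (a$species != "RO2_radical" || b$species != "RO2_radical") {
    stop("dimer cleavage is defined for RO2 radical records", call. = FALSE)
  }
  sides <- list(a, b)
  is_acyl <- vapply(sides, function(s) s$ro2_site_class == "acylperoxy",
                    logical(1))
  if (all(is_acyl)) {
    warning("both sides acylperoxy: no H-exchange pathway available",
            call. = FALSE)
    return(structure(character(0), pathways = list()))
  }
  pathways <- list()
  for (donor_idx in 1:2) {
    if (is_acyl[donor_idx]) next  # acyloxy radical cannot donate H
    acceptor_idx <- 3L - donor_idx
    donor <- sides[[donor_idx]]
    acceptor <- sides[[acceptor_idx]]
    pathways[[length(pathways) + 1L]] <- list(
      donor = donor$id, acceptor = acceptor$id,
      neutrals = list(ketone = ketone_side(donor),
                      alcohol = alcohol_side(acceptor)))
  }
  products <- unlist(lapply(pathways, function(p) {
    c(format(as_no3_adduct(p$neutrals$ketone)),
      format(as_no3_adduct(p$neutrals$alcohol)))
  }))
  structure(sort(unique(products)), pathways = pathways)
}

#' Rank candidate RO2 precursor pairs of an observed dimer
#'
#' Every pool pair whose accretion arithmetic matches the dimer
#' composition (`a + b - O2`) is scored by the evidence its predicted
#' RO-OR cleavage products find in the observed product ions. NO3- adduct
#' matches count with weight 1; matches to the deprotonated `[M - H]-`
#' forms of the neutral cleavage products count with
#' `deprotonated_weight` (default 0.5), since such ions can also arise
#' from secondary fragmentation. Ties are broken by oxygen symmetry
#' (smaller difference in oxygen counts first), then by label.
#'
#' @param dimer_formula Neutral `chem_formula` (or string) of the dimer.
#' @param observed_products Character vector (or list of `chem_formula`)
#'   of observed product-ion anion formulas.
#' @param ro2_pool List of RO2 `structure_record` objects.
#' @param deprotonated_weight Evidence weight for `[M - H]-` matches.
#' @return A data frame ranked best first with columns `a`, `b`, `score`,
#'   `o_asymmetry`, `evidence`; zero rows (with a `diagnostic` attribute)
#'   when no pool pair is arithmetically consistent.
#' @export
infer_dimer_precursors <- function(dimer_formula, observed_products, ro2_pool,
                                   deprotonated_weight = 0.5) {
  if (is.character(dimer_formula)) dimer_formula <- parse_formula(dimer_formula)
  stopifnot(is_chem_formula(dimer_formula))
  obs <- vapply(observed_products,
                function(x) if (is_chem_formula(x)) format(x) else
                  format(parse_formula(x)),
                character(1))
  counts_equal <- function(f, g) all(unclass(f)[ELEMENTS] == unclass(g)[ELEMENTS])
  n <- length(ro2_pool)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- ro2_pool[[i]]; b <- ro2_pool[[j]]
      pred_dimer <- formula_subtract(formula_add(a$formula, b$formula),
                                     O2_FORMULA())
      if (!counts_equal(pred_dimer, dimer_formula)) next
      prods <- tryCatch(dimer_cleavage_products(a, b),
                        warning = function(w) structure(character(0),
                                                        pathways = list()))
      deprot <- unlist(lapply(attr(prods, "pathways"), function(p) {
        c(format(as_deprotonated(p$neutrals$ketone)),
          format(as_deprotonated(p$neutrals$alcohol)))
      }))
      deprot <- unique(deprot)
      hit_add <- intersect(obs, as.character(prods))
      hit_dep <- intersect(obs, deprot)
      rows[[length(rows) + 1L]] <- data.frame(
        a = a$id, b = b$id,
        score = length(hit_add) + deprotonated_weight * length(hit_dep),
        o_asymmetry = abs(a$formula[["O"]] - b$formula[["O"]]),
        evidence = paste(c(hit_add, if (length(hit_dep))
          paste0(hit_dep, " (deprotonated)")), collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(a = character(), b = character(), score = numeric(),
                      o_asymmetry = numeric(), evidence = character(),
                      stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- paste0(
      "no pool pair satisfies a + b - O2 = ", format(dimer_formula))
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$o_asymmetry, out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
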