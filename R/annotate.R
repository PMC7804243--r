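# Precursor and product ion formula assignment and the neutral-loss table.
# Product compositions are constrained to sub-formulas of the precursor
# composition; losses are single-step precursor-minus-product differences
# (multi-step cascades are reconstructed downstream by the rule engine).

#' Assign the precursor formula of a spectrum
#'
#' Enumerates candidate anion compositions at the precursor m/z within the
#' bounds and stores the best-ranked one (smallest absolute ppm error,
#' then fewest nitrogens) on the spectrum.
#'
#' @param s An `msms_spectrum`.
#' @param bounds An [enumeration_bounds()].
#' @return The spectrum with `precursor_formula` set.
#' @export
#' @examples
#' s <- msms_spectrum("limonene O8 radical", 325.0644, "NO3", 2,
#'                    data.frame(mz = 61.9884, intensity = 1))
#' format(assign_precursor(s)$precursor_formula)  # "C10H15NO11-"
assign_precursor <- function(s, bounds = enumeration_bounds()) {
  stopifnot(inherits(s, "msms_spectrum"))
  cand <- enumerate_formulas(s$precursor_mz, bounds)
  if (nrow(cand) == 0L) {
    wide <- bounds
    wide$tol_ppm <- bounds$tol_ppm * 20
    near <- enumerate_formulas(s$precursor_mz, wide)
    diag <- if (nrow(near)) {
      paste0("; nearest candidate ", near$formula[1], " at ",
             formatC(near$ppm[1], format = "f", digits = 1), " ppm")
    } else "; no composition anywhere near within bounds"
    stop("no precursor formula within ", bounds$tol_ppm, " ppm of m/z ",
         s$precursor_mz, diag, call. = FALSE)
  }
  s$precursor_formula <- parse_formula(cand$formula[1])
  s
}

# All element-wise sub-formulas of `parent`, as a data frame with anion
# m/z (electron-inclusive). Computed once per spectrum and matched against
# every peak.
subformula_grid <- function(parent) {
  grid <- expand.grid(C = 0:parent[["C"]], H = 0:parent[["H"]],
                      N = 0:parent[["N"]], O = 0:parent[["O"]])
  grid$mz <- grid$C * ATOMIC_MASS[["C"]] + grid$H * ATOMIC_MASS[["H"]] +
    grid$N * ATOMIC_MASS[["N"]] + grid$O * ATOMIC_MASS[["O"]] + ELECTRON_MASS
  grid
}

#' Annotate product ions against a precursor composition
#'
#' Each peak is assigned the best sub-formula of the parent composition
#' within the ppm tolerance (anion convention, electron included). Ties
#' are broken by smaller absolute ppm error, then fewer nitrogens, then
#' fewer oxygens. The peak matching NO3- is tagged `reagent_ion`, the peak
#' matching the parent is tagged `precursor`; all other assigned peaks are
#' `product` and carry their neutral loss (parent minus product). Peaks
#' with no sub-formula in the window are kept and tagged `unassigned`.
#'
#' @param s A normalized (and typically floored) `msms_spectrum`.
#' @param parent Parent `chem_formula`; defaults to `s$precursor_formula`.
#' @param tol_ppm Matching tolerance in ppm.
#' @return An object of class `annotated_spectrum`: the spectrum, the
#'   parent formula, and a peak table with columns `mz`, `rel_intensity`,
#'   `formula`, `ppm`, `role`, `neutral_loss`.
#' @export
annotate_products <- function(s, parent = s$precursor_formula, tol_ppm = 5) {
  stopifnot(inherits(s, "msms_spectrum"))
  if (is.null(parent)) {
    stop("no parent formula: run assign_precursor() first or pass `parent`",
         call. = FALSE)
  }
  if (anyNA(s$peaks$rel_intensity)) {
    stop("spectrum must be normalized before annotation", call. = FALSE)
  }
  grid <- subformula_grid(parent)
  no3 <- NO3_ANION()
  n <- nrow(s$peaks)
  res <- data.frame(mz = s$peaks$mz, rel_intensity = s$peaks$rel_intensity,
                    formula = NA_character_, ppm = NA_real_,
                    role = "unassigned", neutral_loss = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    obs <- s$peaks$mz[i]
    ppm <- ppm_error(grid$mz, obs)
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) next
    ord <- hit[order(abs(ppm[hit]), grid$N[hit], grid$O[hit])]
    best <- ord[1]
    f <- chem_formula(grid$C[best], grid$H[best], grid$N[best], grid$O[best],
                      charge = -1L)
    res$formula[i] <- format(f)
    res$ppm[i] <- ppm[best]
    same_counts <- function(a, b) all(unclass(a)[ELEMENTS] == unclass(b)[ELEMENTS])
    if (same_counts(f, no3)) {
      res$role[i] <- "reagent_ion"
    } else if (same_counts(f, parent)) {
      res$role[i] <- "precursor"
    } else {
      res$role[i] <- "product"
      res$neutral_loss[i] <- format(formula_subtract(parent, f))
    }
  }
  structure(
    list(spectrum = s, parent = parent, tol_ppm = tol_ppm, peaks = res),
    class = "annotated_spectrum"
  )
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat("<annotated_spectrum> ", x$spectrum$label,
      "  parent ", format(x$parent), "\n", sep = "")
  print(x$peaks, digits = 7)
  invisible(x)
}

#' @export
summary.annotated_spectrum <- function(object, ...) {
  tab <- table(object$peaks$role)
  cat("Annotated spectrum:", object$spectrum$label, "\n")
  cat("Parent:", format(object$parent), "\n")
  print(tab)
  invisible(tab)
}

#' Aggregate the neutral-loss table of an annotated spectrum
#'
#' One row per distinct loss composition: single-step differences relative
#' to the precursor only, with product relative intensities summed and the
#' contributing product formulas listed. Reagent-ion and precursor rows
#' are excluded.
#'
#' @param annotated An `annotated_spectrum`.
#' @return Data frame with columns `loss`, `rel_intensity`, `products`,
#'   ordered by decreasing summed intensity.
#' @export
loss_table <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_spectrum"))
  p <- annotated$peaks
  p <- p[p$role == "product" & !is.na(p$neutral_loss), , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(loss = character(), rel_intensity = numeric(),
                      products = character(), stringsAsFactors = FALSE))
  }
  agg_i <- tapply(p$rel_intensity, p$neutral_loss, sum)
  agg_f <- tapply(p$formula, p$neutral_loss,
                  function(x) paste(sort(unique(x)), collapse = ";"))
  out <- data.frame(loss = names(agg_i),
                    rel_intensity = as.numeric(agg_i),
                    products = as.character(agg_f[names(agg_i)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rel_intensity, out$loss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an annotated peak table (with config sidecar)
#'
#' CSV with columns `mz, rel_intensity, formula, ppm, role, neutral_loss`;
#' a sidecar JSON next to it records the tolerance and parent used.
#'
#' @param annotated An `annotated_spectrum`.
#' @param path Output CSV path.
#' @export
write_annotation_csv <- function(annotated, path) {
  stopifnot(inherits(annotated, "annotated_spectrum"))
  utils::write.csv(annotated$peaks, path, row.names = FALSE)
  sidecar <- paste0(path, ".config.json")
  jsonlite::write_json(
    list(parent = format(annotated$parent), tol_ppm = annotated$tol_ppm,
         label = annotated$spectrum$label),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
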