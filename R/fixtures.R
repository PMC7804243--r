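# Loaders for the shipped candidate-structure fixtures. The candidate
# trees themselves (which isomers exist for each composition, and their
# structural features) are figure-derived information and therefore enter
# the package as versioned JSON data, not as code.

record_from_list <- function(x) {
  members <- if (!is.null(x$members)) lapply(x$members, record_from_list)
  structure_record(
    id = x$id,
    species = x$species,
    formula = x$formula,
    ro2_site_class = if (is.null(x$ro2_site_class)) "none" else x$ro2_site_class,
    alpha_carbon_quaternary = isTRUE(x$alpha_carbon_quaternary),
    has_hydroperoxide = isTRUE(x$has_hydroperoxide),
    has_peroxy_acid = isTRUE(x$has_peroxy_acid),
    has_carbonyl = isTRUE(x$has_carbonyl),
    radical_near_peroxy = isTRUE(x$radical_near_peroxy),
    gem_dimethyl_quaternary = isTRUE(x$gem_dimethyl_quaternary),
    scramble_sites = if (is.null(x$scramble_sites)) 0L else x$scramble_sites,
    channels = if (is.null(x$channels)) NULL else unlist(x$channels),
    scrb_overrides = x$scrb_overrides,
    members = members,
    note = x$note
  )
}

#' Read candidate structures from a JSON fixture file
#'
#' @param path Path to a structures JSON file (see the files under
#'   `system.file("extdata", package = "homsms")` for the schema).
#' @return A named list of `structure_record` objects.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("cannot read structures file: ", path,
                               call. = FALSE)
  obj <- jsonlite::read_json(path)
  recs <- lapply(obj$structures, record_from_list)
  stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
}

#' Shipped candidate-structure sets
#'
#' Versioned fixture sets installed with the package:
#' * `"limonene_o8"` — the fourteen candidate C10H15O8 radicals (A1-A7,
#'   B1-B7) from the two limonene ozonolysis routes;
#' * `"limonene_o10"` — the named C10H15O10 derivatives of the surviving
#'   O8 structures;
#' * `"limonene_ro2_pool"` — one representative limonene RO2 per oxygen
#'   number (O4, O6, O8, O10) for dimer precursor inference;
#' * `"apinene_ro2_pool"` — the a-pinene analogues.
#'
#' @param name Fixture set name.
#' @return A named list of `structure_record` objects.
#' @export
#' @examples
#' names(hom_structures("limonene_o8"))
hom_structures <- function(name = c("limonene_o8", "limonene_o10",
                                    "limonene_ro2_pool", "apinene_ro2_pool")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("structures_", name, ".json"),
                      package = "homsms")
  read_structures(path)
}

#' Demonstration spectrum set for similarity and clustering
#'
#' Builds, in code, the mixed monomer/dimer structure set whose simulated
#' spectra exercise the clustering stage: the closed-shell C10H16O8
#' termination product of the O8 peroxy radical, the two limonene
#' accretion dimers C20H30O12 (acylperoxy-O6 + O8) and C20H30O14
#' (O8 + O8), and two structurally unrelated spectra (the O4 and O10
#' peroxy radicals, whose product-ion formulas are disjoint from the
#' others). The termination product and both dimers share the
#' C10H14O7.NO3- product-ion channel (water loss from the hydroperoxide
#' vs. RO-OR cleavage), which is what groups them in the clustering.
#'
#' @return A named list of `structure_record` objects.
#' @export
clustering_demo_structures <- function() {
  pool <- hom_structures("limonene_ro2_pool")
  o8 <- pool[["lim-O8"]]
  o6 <- pool[["lim-O6"]]
  recs <- list(
    structure_record("C10H16O8", "closed_shell", "C10H16O8",
                     has_hydroperoxide = TRUE, has_peroxy_acid = TRUE,
                     has_carbonyl = TRUE,
                     note = "termination product of the O8 peroxy radical"),
    structure_record("C20H30O14", "dimer",
                     dimer_formula(o8, o8), members = list(o8, o8),
                     has_hydroperoxide = TRUE,
                     note = "O8 + O8 accretion dimer"),
    structure_record("C20H30O12", "dimer",
                     dimer_formula(o6, o8), members = list(o6, o8),
                     has_hydroperoxide = TRUE,
                     note = "acylperoxy-O6 + O8 accretion dimer"),
    pool[["lim-O4"]],
    pool[["lim-O10"]]
  )
  stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
}
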