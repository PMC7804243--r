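# Declarative fragmentation-feasibility rules and the candidate-elimination
# engine. Candidate isomers are encoded as feature records (radical-site
# class, quaternary flags, functional groups) rather than molecular graphs:
# the discriminating fragmentation logic for NO3- adducts of peroxy
# radicals depends on exactly these features.

#' Create a candidate-structure feature record
#'
#' @param id Candidate label, e.g. `"A2"` or `"B2-1"`.
#' @param species One of `"RO2_radical"`, `"closed_shell"`, `"dimer"`.
#' @param formula `chem_formula` of the neutral species (radical flag set
#'   for RO2 radicals), or a formula string.
#' @param ro2_site_class Carbon class bearing the peroxy radical:
#'   `"primary"`, `"secondary"`, `"tertiary"`, `"acylperoxy"` or `"none"`.
#'   Must not be `"none"` for an RO2 radical.
#' @param alpha_carbon_quaternary Is the carbon adjacent to the radical
#'   carbon (after O2 loss) quaternary? Gates H-transfer eliminations.
#' @param has_hydroperoxide Carries an -OOH group (enables H2O loss).
#' @param has_peroxy_acid Carries a peroxy-acid / carboxyl moiety (enables
#'   charge-migration CO2 loss).
#' @param has_carbonyl Carries a C=O group.
#' @param radical_near_peroxy Radical site adjacent to a peroxy group
#'   (enables CHO3 radical-recombination loss).
#' @param gem_dimethyl_quaternary Quaternary carbon bonded to two methyl
#'   groups (the a-pinene motif; enables CH3O2 and C3H6O losses).
#' @param scramble_sites Number of exchangeable -OOH/-OO* hydrogen
#'   positions available for H-shift scrambling.
#' @param channels Optional character vector of fragmentation-rule ids:
#'   the channels this structure's spectra actually exhibit. The forward
#'   simulator emits the intersection of these channels with the feasible
#'   rules; `NULL` means all feasible rules. The elimination engine
#'   ignores this field.
#' @param scrb_overrides Optional list (length `scramble_sites`) of named
#'   flag overrides describing each scrambling variant.
#' @param members For dimers: list of the two member RO2 records.
#' @param note Optional free-text provenance note.
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(id,
                             species = c("RO2_radical", "closed_shell", "dimer"),
                             formula,
                             ro2_site_class = c("none", "primary", "secondary",
                                                "tertiary", "acylperoxy"),
                             alpha_carbon_quaternary = FALSE,
                             has_hydroperoxide = FALSE,
                             has_peroxy_acid = FALSE,
                             has_carbonyl = FALSE,
                             radical_near_peroxy = FALSE,
                             gem_dimethyl_quaternary = FALSE,
                             scramble_sites = 0L,
                             channels = NULL,
                             scrb_overrides = NULL,
                             members = NULL,
                             note = NULL) {
  species <- match.arg(species)
  ro2_site_class <- match.arg(ro2_site_class)
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(is_chem_formula(formula))
  if (species == "RO2_radical" && ro2_site_class == "none") {
    stop("an RO2 radical record must have a peroxy site class", call. = FALSE)
  }
  if (species == "dimer") {
    if (is.null(members) || length(members) != 2L) {
      stop("a dimer record carries exactly two member records", call. = FALSE)
    }
  }
  structure(
    list(id = as.character(id), species = species, formula = formula,
         ro2_site_class = ro2_site_class,
         alpha_carbon_quaternary = isTRUE(alpha_carbon_quaternary),
         has_hydroperoxide = isTRUE(has_hydroperoxide),
         has_peroxy_acid = isTRUE(has_peroxy_acid),
         has_carbonyl = isTRUE(has_carbonyl),
         radical_near_peroxy = isTRUE(radical_near_peroxy),
         gem_dimethyl_quaternary = isTRUE(gem_dimethyl_quaternary),
         scramble_sites = as.integer(scramble_sites),
         channels = channels, scrb_overrides = scrb_overrides,
         members = members, note = note),
    class = "structure_record"
  )
}

#' @export
print.structure_record <- function(x, ...) {
  flags <- c("alpha_carbon_quaternary", "has_hydroperoxide", "has_peroxy_acid",
             "has_carbonyl", "radical_near_peroxy", "gem_dimethyl_quaternary")
  on <- flags[vapply(flags, function(f) isTRUE(x[[f]]), logical(1))]
  cat("<structure_record> ", x$id, "  ", x$species, "  ",
      format(x$formula), "  site=", x$ro2_site_class,
      if (length(on)) paste0("  [", paste(on, collapse = ", "), "]") else "",
      "\n", sep = "")
  invisible(x)
}

# Named predicate registry: predicates are pure functions of the feature
# record, referenced by name so the rule set serializes to JSON and back.
RULE_PREDICATES <- list(
  always = function(s) TRUE,
  has_peroxy_site = function(s) s$ro2_site_class != "none",
  alpha_not_quaternary = function(s) !s$alpha_carbon_quaternary,
  has_hydroperoxide = function(s) s$has_hydroperoxide,
  has_peroxy_acid = function(s) s$has_peroxy_acid,
  not_tertiary_ro2 = function(s) s$ro2_site_class != "tertiary",
  radical_near_peroxy = function(s) s$radical_near_peroxy,
  gem_dimethyl = function(s) s$gem_dimethyl_quaternary
)

new_rule <- function(id, loss, applies_to, predicate, anchor) {
  stopifnot(predicate %in% names(RULE_PREDICATES))
  structure(list(id = id, loss = loss, applies_to = applies_to,
                 predicate = predicate, anchor = anchor),
            class = "fragmentation_rule")
}

#' The fragmentation-feasibility rule set
#'
#' One declarative rule per observed neutral-loss channel, each pairing a
#' loss composition with a structural precondition. The default set covers
#' the channels diagnostic for NO3--CI spectra of monoterpene oxidation
#' products: O2 loss of the peroxy group, HNO3 declustering of closed-shell
#' adducts, combined HNO3+OH loss, H2O loss from hydroperoxides, CO2 loss
#' from peroxy-acid/carboxyl moieties, OH elimination with ketone
#' formation, HO2 elimination, CHO3 loss via radical recombination, and
#' the a-pinene-specific CH3O2 and C3H6O losses.
#'
#' @return A named list of `fragmentation_rule` objects.
#' @export
fragmentation_rules <- function() {
  r <- list(
    new_rule("R-O2", "O2", "RO2_radical", "has_peroxy_site",
             "loss of the peroxy functional group as O2; available to every peroxy radical"),
    new_rule("R-HNO3", "HNO3", c("closed_shell", "dimer"), "always",
             "declustering of the nitrate adduct as nitric acid; characteristic of closed-shell molecules and rare for RO2 radicals"),
    new_rule("R-HNO3-OH", "H2NO4", "RO2_radical", "alpha_not_quaternary",
             "combined HNO3 and OH loss after O2 elimination; needs an abstractable hydrogen, so the carbon adjacent to the alkyl radical must not be quaternary"),
    new_rule("R-H2O", "H2O", c("RO2_radical", "closed_shell", "dimer"),
             "has_hydroperoxide",
             "water loss from a hydroperoxide group, a standard negative-ion fragmentation channel"),
    new_rule("R-CO2", "CO2", c("RO2_radical", "closed_shell"),
             "has_peroxy_acid",
             "charge-migration elimination of CO2, diagnostic of a carboxylic/peroxy-acid moiety"),
    new_rule("R-OHelim", "OH", "RO2_radical", "not_tertiary_ro2",
             "intramolecular H-abstraction at the peroxy radical followed by OH elimination and ketone formation; impossible for tertiary alkylperoxy radicals"),
    new_rule("R-HO2", "HO2", "RO2_radical", "alpha_not_quaternary",
             "HO2 elimination; needs a hydrogen on the carbon next to the peroxy radical, so that carbon must not be quaternary"),
    new_rule("R-CHO3", "CHO3", "RO2_radical", "radical_near_peroxy",
             "CHO3 loss by radical recombination, possible when the radical sits near a peroxy group"),
    new_rule("R-CH3O2", "CH3O2", "RO2_radical", "gem_dimethyl",
             "methylperoxy loss, indicative of the gem-dimethyl quaternary carbon of the a-pinene skeleton"),
    new_rule("R-C3H6O", "C3H6O", "RO2_radical", "gem_dimethyl",
             "C3H6O loss, indicative of the gem-dimethyl quaternary carbon of the a-pinene skeleton")
  )
  stats::setNames(r, vapply(r, `[[`, character(1), "id"))
}

#' Test whether a loss channel is feasible for a structure
#'
#' @param s A `structure_record`.
#' @param r A `fragmentation_rule`.
#' @return A list with `status` (`"feasible"`, `"infeasible"` or
#'   `"inapplicable"` when the rule's species set does not include the
#'   record's species), `feasible` (logical, `NA` when inapplicable) and
#'   the rule's anchored `explanation`.
#' @export
loss_feasible <- function(s, r) {
  stopifnot(inherits(s, "structure_record"), inherits(r, "fragmentation_rule"))
  if (!s$species %in% r$applies_to) {
    return(list(status = "inapplicable", feasible = NA,
                explanation = paste0(r$id, " does not apply to species ",
                                     s$species)))
  }
  ok <- isTRUE(RULE_PREDICATES[[r$predicate]](s))
  list(status = if (ok) "feasible" else "infeasible", feasible = ok,
       explanation = paste0(r$id, " (", r$loss, "): ", r$anchor))
}

#' Feasible losses of a structure under a rule set
#'
#' @param s A `structure_record`.
#' @param rules Rule set (default [fragmentation_rules()]).
#' @param restrict_channels If `TRUE` (default), intersect with the
#'   record's `channels` field when present.
#' @return Named character vector of loss compositions, named by rule id.
#' @export
feasible_losses <- function(s, rules = fragmentation_rules(),
                            restrict_channels = TRUE) {
  keep <- vapply(rules, function(r) isTRUE(loss_feasible(s, r)$feasible),
                 logical(1))
  r <- rules[keep]
  if (restrict_channels && !is.null(s$channels)) {
    r <- r[names(r) %in% s$channels]
  }
  vapply(r, `[[`, character(1), "loss")
}

#' Eliminate candidate structures against observed neutral losses
#'
#' A candidate survives iff every observed loss has at least one feasible
#' rule for it. Losses for which no rule exists at all are ignored with a
#' warning. Elimination is monotone: adding observed losses can only
#' shrink the survivor set.
#'
#' @param candidates List of `structure_record` objects (non-empty).
#' @param observed_losses Character vector (or list of `chem_formula`) of
#'   loss compositions.
#' @param rules Rule set.
#' @return An object of class `elimination_report` with components
#'   `surviving` (ids), `eliminated` (named list; per candidate a data
#'   frame of the failing `(loss, rule, explanation)` rows), `ignored_losses`
#'   and a full per-candidate `trace`.
#' @export
eliminate <- function(candidates, observed_losses,
                      rules = fragmentation_rules()) {
  stopifnot(length(candidates) >= 1L)
  if (inherits(candidates, "structure_record")) candidates <- list(candidates)
  norm_loss <- function(l) {
    if (is_chem_formula(l)) format(l) else format(parse_formula(l))
  }
  losses <- unique(vapply(observed_losses, norm_loss, character(1)))
  rule_loss <- vapply(rules, function(r) format(parse_formula(r$loss)),
                      character(1))
  known <- losses %in% rule_loss
  if (any(!known)) {
    warning("no fragmentation rule for loss(es) ",
            paste(losses[!known], collapse = ", "), "; ignored",
            call. = FALSE)
  }
  ignored <- losses[!known]
  losses <- losses[known]
  surviving <- character(0)
  eliminated <- list()
  trace <- list()
  for (cand in candidates) {
    fail_rows <- list()
    ok_all <- TRUE
    for (l in losses) {
      rl <- rules[rule_loss == l]
      verdicts <- lapply(rl, loss_feasible, s = cand)
      feas <- vapply(verdicts, function(v) isTRUE(v$feasible), logical(1))
      if (!any(feas)) {
        ok_all <- FALSE
        fail_rows[[l]] <- data.frame(
          loss = l,
          rule = vapply(rl, `[[`, character(1), "id"),
          status = vapply(verdicts, `[[`, character(1), "status"),
          explanation = vapply(verdicts, `[[`, character(1), "explanation"),
          stringsAsFactors = FALSE)
      }
    }
    trace[[cand$id]] <- list(losses = losses, failed = names(fail_rows))
    if (ok_all) {
      surviving <- c(surviving, cand$id)
    } else {
      eliminated[[cand$id]] <- do.call(rbind, unname(fail_rows))
    }
  }
  structure(
    list(surviving = surviving, eliminated = eliminated,
         ignored_losses = ignored, observed_losses = losses, trace = trace),
    class = "elimination_report"
  )
}

#' @export
print.elimination_report <- function(x, ...) {
  cat("<elimination_report>\n")
  cat("  observed losses: ", paste(x$observed_losses, collapse = ", "), "\n",
      sep = "")
  cat("  surviving: ", paste(x$surviving, collapse = ", "), "\n", sep = "")
  for (id in names(x$eliminated)) {
    df <- x$eliminated[[id]]
    cat("  eliminated ", id, ": ",
        paste(unique(paste0(df$loss, " [", df$rule, "]")), collapse = "; "),
        "\n", sep = "")
  }
  if (length(x$ignored_losses)) {
    cat("  ignored losses: ", paste(x$ignored_losses, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Expand H-shift scrambling variants of a structure
#'
#' Rapid hydrogen exchange between -OOH and -OO* sites can interconvert
#' isomers; each exchangeable site yields one variant record, with ids
#' suffixed `-scrb`. Variant feature flags come from the record's
#' `scrb_overrides` when provided (figure-derived information is data, not
#' code); without overrides the variant copies the parent's features.
#' The output always contains the original record, so its size is at most
#' `scramble_sites + 1`.
#'
#' @param s A `structure_record`.
#' @return A list of `structure_record` objects.
#' @export
expand_scrambling <- function(s) {
  stopifnot(inherits(s, "structure_record"))
  if (s$scramble_sites < 1L) return(list(s))
  out <- list(s)
  for (i in seq_len(s$scramble_sites)) {
    v <- s
    v$id <- paste0(s$id, "-scrb", if (s$scramble_sites > 1L) i else "")
    v$scramble_sites <- 0L
    v$scrb_overrides <- NULL
    ov <- if (!is.null(s$scrb_overrides) && length(s$scrb_overrides) >= i) {
      s$scrb_overrides[[i]]
    } else NULL
    for (field in names(ov)) v[[field]] <- ov[[field]]
    out[[i + 1L]] <- v
  }
  out
}

# ---- rule-set JSON serialization -------------------------------------------

#' Serialize / load the rule set as JSON
#'
#' Rules are versioned data: losses by composition string and predicates
#' by registry name, so the set round-trips losslessly.
#'
#' @param rules A rule set from [fragmentation_rules()].
#' @param path JSON file path.
#' @export
write_rules_json <- function(rules, path) {
  payload <- lapply(unname(rules), function(r) {
    list(id = r$id, loss = r$loss, applies_to = as.list(r$applies_to),
         predicate = r$predicate, anchor = r$anchor)
  })
  jsonlite::write_json(list(version = 1L, rules = payload), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(path) {
  obj <- jsonlite::read_json(path)
  r <- lapply(obj$rules, function(x) {
    new_rule(x$id, x$loss, unlist(x$applies_to), x$predicate, x$anchor)
  })
  stats::setNames(r, vapply(r, `[[`, character(1), "id"))
}
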