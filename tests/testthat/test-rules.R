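# Fragmentation-feasibility rules, candidate elimination and scrambling.

test_that("individual rules gate on the encoded structural features", {
  rules <- fragmentation_rules()
  o8 <- hom_structures("limonene_o8")

  # tertiary alkylperoxy radical cannot eliminate OH with ketone formation
  expect_false(loss_feasible(o8[["A3"]], rules[["R-OHelim"]])$feasible)
  expect_true(loss_feasible(o8[["A2"]], rules[["R-OHelim"]])$feasible)

  # quaternary alpha carbon blocks the combined HNO3 + OH loss
  expect_false(loss_feasible(o8[["A4"]], rules[["R-HNO3-OH"]])$feasible)
  expect_true(loss_feasible(o8[["A1"]], rules[["R-HNO3-OH"]])$feasible)

  # every peroxy radical can shed O2
  expect_true(all(vapply(o8, function(s)
    loss_feasible(s, rules[["R-O2"]])$feasible, logical(1))))

  # species mismatch is inapplicable, not infeasible
  closed <- structure_record("m", "closed_shell", "C10H16O8",
                             has_hydroperoxide = TRUE)
  v <- loss_feasible(closed, rules[["R-O2"]])
  expect_identical(v$status, "inapplicable")
  expect_true(is.na(v$feasible))
  expect_true(loss_feasible(closed, rules[["R-HNO3"]])$feasible)

  # every verdict carries a non-empty explanation
  for (r in rules) {
    expect_gt(nchar(loss_feasible(o8[["A1"]], r)$explanation), 0)
  }
})

test_that("elimination reproduces the O8 and O10 candidate narrowing", {
  o8 <- hom_structures("limonene_o8")
  rep8 <- eliminate(o8, c("O2", "H2NO4", "H2O", "CO2", "OH"))
  expect_setequal(rep8$surviving, c("A1", "A2", "B1", "B2", "A7"))
  # eliminated candidates carry the rule that blocked them
  expect_true("R-OHelim" %in% rep8$eliminated[["A3"]]$rule)
  expect_true("R-HNO3-OH" %in% rep8$eliminated[["A4"]]$rule)

  o10 <- hom_structures("limonene_o10")
  rep10 <- eliminate(o10, c("O2", "OH", "HO2", "CHO3"))
  expect_setequal(rep10$surviving, c("A1-1", "B1-1", "A2-1", "B2-1", "A7-2"))
  expect_true("R-CHO3" %in% rep10$eliminated[["A1-2"]]$rule)
  expect_true("R-OHelim" %in% rep10$eliminated[["B2-6"]]$rule)

  # surviving and eliminated partition the candidate set
  expect_setequal(c(rep10$surviving, names(rep10$eliminated)),
                  vapply(o10, `[[`, character(1), "id"))
})

test_that("elimination is vacuous without losses, monotone with them", {
  o8 <- hom_structures("limonene_o8")
  all_ids <- vapply(o8, `[[`, character(1), "id")
  expect_setequal(eliminate(o8, character(0))$surviving, all_ids)

  expect_warning(rep <- eliminate(o8, c("O2", "C5H5N5")), "no fragmentation rule")
  expect_identical(rep$ignored_losses, loss_key("C5H5N5"))

  losses <- c("O2", "H2NO4", "H2O", "CO2", "OH", "HO2")
  set.seed(9)
  for (i in 1:10) {
    sub <- sample(losses, sample(length(losses), 1))
    sub_surv <- eliminate(o8, sub)$surviving
    full_surv <- eliminate(o8, losses)$surviving
    expect_true(all(full_surv %in% sub_surv))
  }
})

test_that("the rule set round-trips through JSON and ships with the package", {
  rules <- fragmentation_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_rules_json(rules, path)
  back <- read_rules_json(path)
  expect_identical(lapply(back, unclass), lapply(rules, unclass))

  shipped <- read_rules_json(system.file("extdata",
                                         "fragmentation_rules.json",
                                         package = "homsms"))
  expect_identical(lapply(shipped, unclass), lapply(rules, unclass))
})

test_that("scrambling expansion is bounded and maps B7 onto A7", {
  o8 <- hom_structures("limonene_o8")
  expect_identical(expand_scrambling(o8[["A1"]]), list(o8[["A1"]]))

  b7 <- expand_scrambling(o8[["B7"]])
  expect_lte(length(b7), o8[["B7"]]$scramble_sites + 1L)
  ids <- vapply(b7, `[[`, character(1), "id")
  expect_true("B7-scrb" %in% ids)
  variant <- b7[[which(ids == "B7-scrb")]]
  a7 <- o8[["A7"]]
  feat <- c("species", "ro2_site_class", "alpha_carbon_quaternary",
            "has_hydroperoxide", "has_peroxy_acid", "radical_near_peroxy",
            "gem_dimethyl_quaternary")
  expect_identical(variant[feat], a7[feat])

  # a scrambled B7 survives the O8 loss set that eliminates plain B7
  rep <- eliminate(b7, c("O2", "H2NO4", "H2O", "CO2", "OH"))
  expect_identical(rep$surviving, "B7-scrb")
})

test_that("structure records validate their invariants", {
  expect_error(structure_record("bad", "RO2_radical", "C10H15O8*",
                                ro2_site_class = "none"),
               "peroxy site class")
  expect_error(structure_record("d", "dimer", "C20H30O14"),
               "two member records")
})
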