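# Shared helpers: canonical loss spellings, a brute-force formula
# enumerator and a naive complete-linkage agglomerator. The oracles here
# are deliberately independent of the package internals they check.

# canonical composition string (e.g. "OH" -> "HO")
loss_key <- function(x) vapply(x, function(l) format(parse_formula(l)),
                               character(1), USE.NAMES = FALSE)

# Exhaustive nested-loop formula enumeration over the full element grid;
# no analytic hydrogen solve, no shortcuts.
brute_force_formulas <- function(observed_mz, bounds = enumeration_bounds()) {
  masses <- mass_constants()$elements
  e <- mass_constants()$electron
  hits <- character(0)
  for (C in bounds$c[1]:bounds$c[2]) {
    for (H in bounds$h[1]:bounds$h[2]) {
      for (N in bounds$n[1]:bounds$n[2]) {
        for (O in bounds$o[1]:bounds$o[2]) {
          m <- C * masses[["C"]] + H * masses[["H"]] + N * masses[["N"]] +
            O * masses[["O"]] + e
          if (abs(1e6 * (observed_mz - m) / m) > bounds$tol_ppm) next
          r <- C - H / 2 + N / 2 + 1
          if (r < bounds$rdbe[1] || r > bounds$rdbe[2]) next
          hits <- c(hits, format(chem_formula(C, H, N, O, charge = -1L)))
        }
      }
    }
  }
  sort(hits)
}

# Naive O(n^3) complete-linkage agglomeration; returns sorted merge heights.
naive_complete_linkage_heights <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_d <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# A small Fig. 3a-style spectrum built peak by peak from measured-style
# values (precursor O8-radical adduct plus its reported product ions).
fig3a_style_spectrum <- function() {
  peaks <- data.frame(
    mz = c(325.0644, 293.0748, 213.0766, 195.0667, 151.0764, 61.9884),
    intensity = c(1000, 400, 120, 60, 30, 500))
  msms_spectrum("limonene C10H15O8 radical", 325.0644, "NO3", 5, peaks)
}

random_formula <- function() {
  chem_formula(sample(0:20, 1), sample(0:40, 1), sample(0:2, 1),
               sample(0:20, 1))
}
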