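# Spectrum vectors, cosine similarity, the pairwise matrix and
# complete-linkage clustering (checked against a naive agglomerator).

vec <- function(x, mode = "product_ions") {
  structure(x, mode = mode, class = "spectrum_vector")
}

annotated_from_peaks <- function(label, precursor_mz, peaks) {
  s <- normalize_spectrum(msms_spectrum(label, precursor_mz, "NO3", 5, peaks))
  s <- assign_precursor(s)
  annotate_products(s)
}

test_that("spectrum vectors hold sqrt intensities and exclude key peaks", {
  th <- mz(parse_formula("C10H15NO9-"))
  ann <- annotated_from_peaks("one product", 325.0644,
                              data.frame(mz = c(61.9884, th, 325.0644),
                                         intensity = c(50, 25, 100)))
  v <- build_vector(ann, "product_ions")
  expect_equal(length(v), 1L)
  expect_identical(names(v), "C10H15NO9-")
  expect_equal(as.numeric(v), sqrt(0.25))
  # reagent ion and precursor excluded from the vector space
  expect_false(any(c("NO3-", "C10H15NO11-") %in% names(v)))

  l <- build_vector(ann, "neutral_losses")
  expect_identical(names(l), "O2")

  bare <- annotated_from_peaks("bare", 325.0644,
                               data.frame(mz = c(61.9884, 325.0644),
                                          intensity = c(1, 10)))
  expect_length(build_vector(bare, "product_ions"), 0L)
})

test_that("cosine similarity is bounded, symmetric and handles edge cases", {
  a <- vec(c(F1 = 1))
  b <- vec(c(F1 = 1, F2 = 1))
  expect_equal(cosine_similarity(a, b), 1 / sqrt(2))
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(vec(c(F1 = 1)), vec(c(F2 = 1))), 0)
  expect_equal(cosine_similarity(vec(numeric(0)), a), 0)
  expect_error(cosine_similarity(a, vec(c(F1 = 1), mode = "neutral_losses")),
               "different modes")
  set.seed(7)
  for (i in 1:20) {
    x <- vec(stats::setNames(stats::runif(4), paste0("k", sample(10, 4))))
    y <- vec(stats::setNames(stats::runif(4), paste0("k", sample(10, 4))))
    s <- cosine_similarity(x, y)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, cosine_similarity(y, x))
  }
})

test_that("the pairwise matrix is symmetric with unit diagonal; masking is display-only", {
  th1 <- mz(parse_formula("C10H15NO9-"))
  th2 <- mz(parse_formula("C10H13NO10-"))
  a1 <- annotated_from_peaks("s1", 325.0644,
                             data.frame(mz = c(61.9884, th1, 325.0644),
                                        intensity = c(5, 25, 100)))
  a2 <- annotated_from_peaks("s2", 325.0644,
                             data.frame(mz = c(61.9884, th1, th2, 325.0644),
                                        intensity = c(5, 25, 50, 100)))
  m <- pairwise_similarity(list(a1, a2, a1), "product_ions")
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_equal(diag(unclass(m)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(m[1, 3], 1)  # identical spectra

  masked <- mask_similarity(m, threshold = 0.2)
  expect_true(all(is.na(masked) | masked >= 0.2))
  # boundary: 0.20 kept, 0.19 hidden
  mm <- m
  mm[1, 2] <- mm[2, 1] <- 0.19
  mm[1, 3] <- mm[3, 1] <- 0.20
  mk <- mask_similarity(mm, 0.2)
  expect_true(is.na(mk[1, 2]))
  expect_equal(mk[1, 3], 0.20)
})

test_that("complete-linkage heights match the naive agglomerator", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 8
    sim <- matrix(stats::runif(n * n), n)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
    dimnames(sim) <- list(letters[1:n], letters[1:n])
    m <- structure(sim, mode = "product_ions",
                   class = c("similarity_matrix", "matrix"))
    cl <- cluster_spectra(m)
    expect_equal(sort(cl$hclust$height),
                 naive_complete_linkage_heights(1 - sim),
                 tolerance = 1e-10)
  }
})

test_that("clustering output is deterministic and well-formed", {
  sim <- matrix(c(1, 1, 0.2,
                  1, 1, 0.2,
                  0.2, 0.2, 1), 3, byrow = TRUE,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m <- structure(sim, mode = "product_ions",
                 class = c("similarity_matrix", "matrix"))
  cl <- cluster_spectra(m)
  # the identical pair merges first, at height 0
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(cut_clusters(cl, 0.5), c(x = 1, y = 1, z = 2))

  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, c("x", "y", "z"))
  expect_equal(length(tree$tip.label), 3L)

  # invariant to input label order (tie-break: lexicographic sort first)
  perm <- c(3, 1, 2)
  m2 <- structure(sim[perm, perm], mode = "product_ions",
                  class = c("similarity_matrix", "matrix"))
  expect_identical(cluster_spectra(m2)$newick, cl$newick)

  one <- structure(matrix(1, 1, 1, dimnames = list("a", "a")),
                   mode = "product_ions",
                   class = c("similarity_matrix", "matrix"))
  expect_error(cluster_spectra(one), "at least 2")
})
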