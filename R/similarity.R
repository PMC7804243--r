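# Cosine similarity over formula-keyed product-ion / neutral-loss vectors
# and complete-linkage hierarchical clustering of the resulting distance
# matrix. Vectors are keyed by assigned formula (post-annotation), not by
# binned m/z; intensities are square-root transformed; the NO3- reagent
# ion and the precursor peak are excluded.

#' Build a formula-keyed spectrum vector
#'
#' In `product_ions` mode the entries are keyed by assigned product
#' formulas; in `neutral_losses` mode by the loss compositions. Values are
#' square roots of relative intensities. The NO3- reagent ion, the
#' precursor peak and unassigned peaks are excluded.
#'
#' @param annotated An `annotated_spectrum`.
#' @param mode `"product_ions"` or `"neutral_losses"`.
#' @return A named numeric vector of class `spectrum_vector` (possibly
#'   empty) with a `mode` attribute.
#' @export
build_vector <- function(annotated, mode = c("product_ions", "neutral_losses")) {
  stopifnot(inherits(annotated, "annotated_spectrum"))
  mode <- match.arg(mode)
  p <- annotated$peaks
  p <- p[p$role == "product", , drop = FALSE]
  key <- if (mode == "product_ions") p$formula else p$neutral_loss
  keep <- !is.na(key)
  v <- tapply(sqrt(p$rel_intensity[keep]), key[keep], sum)
  out <- if (length(v)) stats::setNames(as.numeric(v), names(v)) else
    stats::setNames(numeric(0), character(0))
  structure(out, mode = mode, class = "spectrum_vector")
}

#' Cosine similarity between two spectrum vectors
#'
#' Dot product over the union key set divided by the product of norms;
#' defined as 0 when either vector is empty. Both vectors must have the
#' same mode.
#'
#' @param a,b `spectrum_vector` objects.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(inherits(a, "spectrum_vector"), inherits(b, "spectrum_vector"))
  if (!identical(attr(a, "mode"), attr(b, "mode"))) {
    stop("cannot compare vectors of different modes (",
         attr(a, "mode"), " vs ", attr(b, "mode"), ")", call. = FALSE)
  }
  if (length(a) == 0L || length(b) == 0L) return(0)
  keys <- union(names(a), names(b))
  x <- stats::setNames(numeric(length(keys)), keys)
  y <- x
  x[names(a)] <- as.numeric(a)
  y[names(b)] <- as.numeric(b)
  denom <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  if (denom == 0) return(0)
  min(1, sum(x * y) / denom)
}

#' Pairwise similarity matrix over annotated spectra
#'
#' @param annotated_list List of `annotated_spectrum` objects (length >= 2);
#'   labels are taken from the underlying spectra.
#' @param mode Vector mode, see [build_vector()].
#' @return A labeled symmetric matrix of class `similarity_matrix` with
#'   unit diagonal and a `mode` attribute.
#' @export
pairwise_similarity <- function(annotated_list,
                                mode = c("product_ions", "neutral_losses")) {
  mode <- match.arg(mode)
  stopifnot(length(annotated_list) >= 2L)
  labels <- vapply(annotated_list, function(a) a$spectrum$label, character(1))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  vecs <- lapply(annotated_list, build_vector, mode = mode)
  n <- length(vecs)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- cosine_similarity(vecs[[i]], vecs[[j]])
    }
  }
  dimnames(m) <- list(labels, labels)
  structure(m, mode = mode, class = c("similarity_matrix", "matrix"))
}

#' Mask a similarity matrix for display
#'
#' Replaces entries below the threshold with `NA`. Display only: the
#' clustering always runs on the unmasked matrix.
#'
#' @param m A `similarity_matrix`.
#' @param threshold Display threshold (default 0.2); the comparison is
#'   inclusive (`>=` survives).
#' @return The masked matrix (diagonal kept).
#' @export
mask_similarity <- function(m, threshold = 0.2) {
  stopifnot(inherits(m, "similarity_matrix"))
  out <- unclass(m)
  out[out < threshold] <- NA_real_
  diag(out) <- 1
  structure(out, mode = attr(m, "mode"), class = class(m))
}

#' Complete-linkage clustering of a similarity matrix
#'
#' Agglomerative hierarchical clustering with complete linkage on the
#' cosine distance `1 - similarity`. Labels are sorted lexicographically
#' before clustering so tie merges are resolved deterministically and the
#' result is invariant to input order.
#'
#' @param m A `similarity_matrix` over at least 2 items.
#' @return An object of class `spectral_clustering`: a list with the
#'   `hclust` object, the labels, and a Newick string of the dendrogram.
#' @export
cluster_spectra <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (nrow(m) < 2L) {
    stop("clustering needs at least 2 spectra, got ", nrow(m), call. = FALSE)
  }
  ord <- order(rownames(m))
  vals <- unclass(m)[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - vals)
  hc <- stats::hclust(d, method = "complete")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, labels = hc$labels, newick = newick,
                 mode = attr(m, "mode")),
            class = "spectral_clustering")
}

#' @export
print.spectral_clustering <- function(x, ...) {
  cat("<spectral_clustering> complete linkage, cosine distance, ",
      length(x$labels), " spectra (", x$mode, ")\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

#' Cut a spectral clustering into groups
#'
#' @param x A `spectral_clustering`.
#' @param h Distance height at which to cut.
#' @return Named integer vector of group memberships.
#' @export
cut_clusters <- function(x, h) {
  stopifnot(inherits(x, "spectral_clustering"))
  stats::cutree(x$hclust, h = h)
}

#' Write a similarity matrix as labeled CSV
#'
#' @param m A `similarity_matrix`.
#' @param path Output path.
#' @export
write_similarity_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
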