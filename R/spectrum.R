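# MS/MS spectrum container and peak-list I/O (MGF and two-column CSV),
# intensity normalization and the relative-intensity floor filter.

NO3_ANION <- function() chem_formula(n = 1, o = 3, charge = -1)

#' Create an MS/MS spectrum
#'
#' @param label Free-text label, e.g. `"limonene C10H15O8"`.
#' @param precursor_mz Precursor m/z (> 0).
#' @param adduct Reagent-ion adduct, `"NO3"` or `"HNO3NO3"`.
#' @param nce Normalized collision energy (dimensionless, instrument range
#'   2-10 in the data this package models).
#' @param peaks Data frame with columns `mz` and `intensity` (absolute,
#'   non-negative); an optional `rel_intensity` column is preserved.
#'   Peaks are stored sorted by ascending m/z; peaks closer than 1e-5 m/z
#'   are merged with summed intensity (duplicate-centroid guard).
#' @param precursor_formula Optional `chem_formula` of the precursor ion.
#' @return An object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(label, precursor_mz, adduct = c("NO3", "HNO3NO3"),
                          nce, peaks, precursor_formula = NULL) {
  adduct <- match.arg(adduct)
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0, is.numeric(nce), nce >= 0)
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("negative peak intensity", call. = FALSE)
  if (is.null(peaks$rel_intensity)) peaks$rel_intensity <- NA_real_
  peaks <- peaks[order(peaks$mz), c("mz", "intensity", "rel_intensity")]
  peaks <- merge_close_peaks(peaks)
  rownames(peaks) <- NULL
  structure(
    list(label = as.character(label), precursor_mz = precursor_mz,
         adduct = adduct, nce = as.numeric(nce), peaks = peaks,
         precursor_formula = precursor_formula),
    class = "msms_spectrum"
  )
}

# Sum intensities of centroids closer than `tol` in m/z (spectra arrive
# sorted). rel_intensity is invalidated by merging and must be recomputed.
merge_close_peaks <- function(peaks, tol = 1e-5) {
  if (nrow(peaks) < 2L) return(peaks)
  grp <- cumsum(c(TRUE, diff(peaks$mz) > tol))
  if (max(grp) == nrow(peaks)) return(peaks)
  merged <- do.call(rbind, lapply(split(peaks, grp), function(p) {
    data.frame(mz = stats::weighted.mean(p$mz, pmax(p$intensity, 1e-12)),
               intensity = sum(p$intensity),
               rel_intensity = if (nrow(p) == 1L) p$rel_intensity else NA_real_)
  }))
  rownames(merged) <- NULL
  merged
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<msms_spectrum> ", x$label, "\n", sep = "")
  cat("  precursor m/z ", format(x$precursor_mz, nsmall = 4),
      "  adduct ", x$adduct, "  NCE ", x$nce,
      "  peaks ", nrow(x$peaks), "\n", sep = "")
  if (!is.null(x$precursor_formula)) {
    cat("  precursor formula ", format(x$precursor_formula), "\n", sep = "")
  }
  invisible(x)
}

#' Normalize peak intensities to the base peak
#'
#' Sets `rel_intensity = intensity / max(intensity)`; the base peak gets
#' relative intensity 1 (ties leave several peaks at 1, which is
#' tolerated). The base peak is chosen over all peaks, including the
#' precursor.
#'
#' @param s An `msms_spectrum` with at least one positive-intensity peak.
#' @return The spectrum with `rel_intensity` filled in. Idempotent.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "msms_spectrum"))
  if (nrow(s$peaks) == 0L || all(s$peaks$intensity <= 0)) {
    stop("cannot normalize a spectrum with no positive-intensity peaks",
         call. = FALSE)
  }
  s$peaks$rel_intensity <- s$peaks$intensity / max(s$peaks$intensity)
  s
}

#' Apply the relative-intensity floor
#'
#' Drops peaks with relative intensity below `floor` (default 0.1%, the
#' refinement threshold used for NO3--CI product ion lists). The
#' comparison is inclusive: a peak exactly at the floor survives. The
#' precursor peak and the NO3- reagent-ion peak are never removed,
#' whatever their intensity.
#'
#' @param s A normalized `msms_spectrum`.
#' @param floor Relative-intensity threshold in `[0, 1]`.
#' @param tol_ppm Tolerance used to recognize the precursor and NO3-
#'   peaks.
#' @return The filtered spectrum. Idempotent.
#' @export
filter_floor <- function(s, floor = 0.001, tol_ppm = 5) {
  stopifnot(inherits(s, "msms_spectrum"), floor >= 0, floor <= 1)
  if (anyNA(s$peaks$rel_intensity)) {
    stop("spectrum must be normalized before filtering", call. = FALSE)
  }
  protected <- abs(ppm_error(s$precursor_mz, s$peaks$mz)) <= tol_ppm |
    abs(ppm_error(mz(NO3_ANION()), s$peaks$mz)) <= tol_ppm
  keep <- s$peaks$rel_intensity >= floor | protected
  s$peaks <- s$peaks[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Read / write spectra in MGF format
#'
#' A standard MGF dialect with one `BEGIN IONS`/`END IONS` block per
#' spectrum. `PEPMASS` carries the precursor m/z and `CHARGE=1-` the anion
#' charge; the collision energy, adduct and optional precursor formula are
#' carried on `NCE=`, `ADDUCT=` and `FORMULA=` lines. m/z values are
#' written with six decimals so a write/read round trip is lossless at the
#' precision the annotation works with.
#'
#' @param path File path.
#' @return `read_mgf()` returns a list of `msms_spectrum`; `write_mgf()`
#'   returns `path` invisibly.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  }
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(trimws(block))]
    kv_idx <- grepl("^[A-Z]+=", block)
    kv <- block[kv_idx]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[A-Z]+=", "", kv)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("scan_", i)
    if (!"PEPMASS" %in% keys) {
      stop("malformed MGF block ", i, " (", title, "): missing PEPMASS",
           call. = FALSE)
    }
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1])
    if (is.na(pepmass)) {
      stop("malformed MGF block ", i, " (", title, "): unreadable PEPMASS",
           call. = FALSE)
    }
    nce <- if ("NCE" %in% keys) as.numeric(vals[match("NCE", keys)]) else 0
    adduct <- if ("ADDUCT" %in% keys) vals[match("ADDUCT", keys)] else "NO3"
    pform <- if ("FORMULA" %in% keys) parse_formula(vals[match("FORMULA", keys)])
    else NULL
    peak_lines <- block[!kv_idx]
    if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
                                   function(x) as.numeric(x[1:2])))
      if (anyNA(mat)) {
        stop("malformed MGF block ", i, " (", title, "): unreadable peak line",
             call. = FALSE)
      }
      peaks <- data.frame(mz = mat[, 1], intensity = mat[, 2])
    } else {
      peaks <- data.frame(mz = numeric(), intensity = numeric())
    }
    out[[i]] <- msms_spectrum(title, pepmass, adduct, nce, peaks,
                              precursor_formula = pform)
  }
  out
}

#' @rdname read_mgf
#' @param spectra A list of `msms_spectrum` objects.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "msms_spectrum")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$label),
      paste0("PEPMASS=", formatC(s$precursor_mz, format = "f", digits = 6)),
      "CHARGE=1-",
      paste0("NCE=", s$nce),
      paste0("ADDUCT=", s$adduct),
      if (!is.null(s$precursor_formula))
        paste0("FORMULA=", format(s$precursor_formula))
    ), con)
    if (nrow(s$peaks)) {
      writeLines(paste(formatC(s$peaks$mz, format = "f", digits = 6),
                       formatC(s$peaks$intensity, format = "f", digits = 4)),
                 con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read / write a two-column CSV peak list
#'
#' Columns `mz,intensity`, header required, `.` decimal separator, UTF-8.
#'
#' @param path File path.
#' @param label,precursor_mz,adduct,nce Spectrum metadata supplied by the
#'   caller (a bare peak list carries none).
#' @return `read_peaks_csv()` returns an `msms_spectrum`.
#' @export
read_peaks_csv <- function(path, label = basename(path), precursor_mz,
                           adduct = "NO3", nce = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak-list CSV must have columns mz,intensity: ", path, call. = FALSE)
  }
  msms_spectrum(label, precursor_mz, adduct, nce,
                df[, c("mz", "intensity")])
}

#' @rdname read_peaks_csv
#' @param s An `msms_spectrum`.
#' @export
write_peaks_csv <- function(s, path) {
  utils::write.csv(s$peaks[, c("mz", "intensity")], path, row.names = FALSE)
  invisible(path)
}
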