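#' Optical-density transform of an 8-bit RGB image
#'
#' `OD_c = -log10((value_c + eps) / I0)` per pixel and colour channel; the
#' small `eps` (1/255) avoids `log(0)` at fully absorbed pixels. Pure white
#' maps to an OD slightly below zero, which downstream clipping treats as
#' zero concentration.
#'
#' @param rgb Integer array `rows x cols x 3` in \[0, 255\].
#' @param I0 Incident intensity (default 255).
#' @param eps Offset added before the log (default `1/255`).
#' @return Numeric array `rows x cols x 3` of optical densities.
#' @export
od_transform <- function(rgb, I0 = 255, eps = 1 / 255) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  -log10((rgb + eps) / I0)
}

#' Colour deconvolution: unmix an RGB image into per-stain OD maps
#'
#' Projects each pixel's optical-density vector through the inverse of the
#' stain basis (Ruifrok–Johnston linear unmixing). Negative ODs (possible
#' only through the `eps` offset at saturated-white pixels) and negative
#' concentrations (noise/quantization artefacts) are clipped to zero, so
#' pure white unmixes to exactly zero for every stain.
#'
#' @param rgb Integer array `rows x cols x 3` in \[0, 255\].
#' @param basis A [stain_basis()].
#' @inheritParams od_transform
#' @return Named list of per-stain concentration matrices (OD units).
#' @export
unmix <- function(rgb, basis = stain_basis(), I0 = 255, eps = 1 / 255) {
  stopifnot(inherits(basis, "stain_basis"))
  od <- od_transform(rgb, I0 = I0, eps = eps)
  od[od < 0] <- 0
  d <- dim(od)[1:2]
  odm <- matrix(od, ncol = 3L)               # pixels x RGB
  conc <- odm %*% solve(unclass(basis))      # pixels x stains
  conc[conc < 0] <- 0
  out <- lapply(seq_len(ncol(conc)), function(j) matrix(conc[, j], d[1], d[2]))
  names(out) <- rownames(basis)
  out
}

#' Triangle-method threshold on an OD map
#'
#' Standard geometric triangle threshold on a 256-bin histogram: the
#' threshold is the bin maximizing the distance to the line joining the
#' histogram peak and the far tail. Used as the default when no fixed OD
#' threshold is supplied (the study's own thresholds are unpublished).
#'
#' @param x Numeric matrix/vector of OD values.
#' @param n_bins Number of histogram bins.
#' @return Scalar threshold on the OD scale.
#' @export
triangle_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  counts <- h$counts
  peak <- which.max(counts)
  # tail on the longer side of the peak
  tail_idx <- if ((n_bins - peak) >= (peak - 1L)) max(which(counts > 0)) else
    min(which(counts > 0))
  x1 <- peak; y1 <- counts[peak]; x2 <- tail_idx; y2 <- counts[tail_idx]
  span <- if (x1 <= x2) x1:x2 else x2:x1
  # perpendicular distance of each histogram point to the peak-tail chord
  num <- abs((y2 - y1) * span - (x2 - x1) * counts[span] + x2 * y1 - y2 * x1)
  best <- span[which.max(num)]
  h$mids[best]
}

#' Tissue mask from thresholded Eosin and DAB maps
#'
#' The overlay of the thresholded Eosin and DAB channels defines "tissue":
#' a pixel is tissue if either stain exceeds its OD threshold.
#'
#' @param eosin,dab Per-stain OD matrices of one shape.
#' @param eosin_threshold,dab_threshold Scalar OD thresholds (strict `>`).
#' @return Logical matrix mask.
#' @export
tissue_mask <- function(eosin, dab, eosin_threshold, dab_threshold) {
  if (!identical(dim(eosin), dim(dab))) {
    stop("maps must share one shape", call. = FALSE)
  }
  (eosin > eosin_threshold) | (dab > dab_threshold)
}

#' DAB quantification over a tissue mask
#'
#' Reports the two study statistics: `percent_surface_area` (DAB-positive
#' pixels as a percentage of tissue pixels) and `density` (mean DAB OD over
#' all tissue pixels, i.e. "the whole tissue", not only DAB-positive
#' pixels).
#'
#' @param dab DAB OD matrix.
#' @param dab_threshold Scalar OD threshold (strict `>`).
#' @param mask Logical tissue mask from [tissue_mask()].
#' @return An object of class `ihc_quant`: list with `dab_area`,
#'   `tissue_area`, `percent_surface_area`, `density`.
#' @export
quantify_dab <- function(dab, dab_threshold, mask) {
  if (!identical(dim(dab), dim(mask))) {
    stop("map and mask must share one shape", call. = FALSE)
  }
  tissue_area <- sum(mask)
  if (tissue_area == 0L) stop("zero tissue area", call. = FALSE)
  dab_area <- sum(mask & (dab > dab_threshold))
  structure(list(dab_area = dab_area, tissue_area = tissue_area,
                 percent_surface_area = 100 * dab_area / tissue_area,
                 density = mean(dab[mask])),
            class = "ihc_quant")
}

#' Per-subject ratios of lysyl-oxidase staining statistics
#'
#' From a long table of per-subject, per-target quantification results,
#' forms pairwise ratios (e.g. LOX/LOXL1) of densities and of percentage
#' surface areas, ready for cohort statistics. Zero denominators yield `NA`
#' with a warning naming the subject.
#'
#' @param quants Data frame with columns `subject`, `target`,
#'   `percent_surface_area`, `density`.
#' @param pairs List of 2-vectors `c(numerator, denominator)` of target
#'   names; default the three study ratios.
#' @return Data frame with one row per subject and columns
#'   `<num>_<den>_density_ratio`, `<num>_<den>_area_ratio`.
#' @export
ratio_table <- function(quants,
                        pairs = list(c("LOX", "LOXL1"), c("LOX", "LOXL2"))) {
  need <- c("subject", "target", "percent_surface_area", "density")
  if (!all(need %in% names(quants))) {
    stop("`quants` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  subjects <- unique(quants$subject)
  out <- data.frame(subject = subjects)
  for (p in pairs) {
    num <- quants[quants$target == p[1], ]
    den <- quants[quants$target == p[2], ]
    if (!all(subjects %in% num$subject) || !all(subjects %in% den$subject)) {
      stop(sprintf("missing %s or %s rows for some subjects", p[1], p[2]),
           call. = FALSE)
    }
    num <- num[match(subjects, num$subject), ]
    den <- den[match(subjects, den$subject), ]
    dr <- num$density / den$density
    ar <- num$percent_surface_area / den$percent_surface_area
    zero_d <- den$density == 0
    zero_a <- den$percent_surface_area == 0
    if (any(zero_d | zero_a)) {
      warning(sprintf("zero %s denominator for subject(s) %s; ratio set to NA",
                      p[2],
                      paste(subjects[zero_d | zero_a], collapse = ", ")),
              call. = FALSE)
      dr[zero_d] <- NA_real_
      ar[zero_a] <- NA_real_
    }
    out[[paste0(p[1], "_", p[2], "_density_ratio")]] <- dr
    out[[paste0(p[1], "_", p[2], "_area_ratio")]] <- ar
  }
  out
}
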