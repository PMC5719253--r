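#' Stain optical-density basis for colour deconvolution
#'
#' A 3 x 3 matrix of unit-length optical-density vectors (rows = stains,
#' columns = R, G, B). The default is the published Ruifrok–Johnston
#' Haematoxylin / Eosin / DAB set used by ImageJ's colour deconvolution;
#' studies typically re-optimize these per batch, so custom vectors can be
#' supplied. Rows are normalized to unit Euclidean norm and must be
#' linearly independent.
#'
#' @param vectors Optional 3 x 3 numeric matrix (stains x RGB). Rows are
#'   renormalized to unit norm.
#' @return A `stain_basis` matrix with rownames `H`, `E`, `DAB` (or the
#'   supplied rownames).
#' @references Ruifrok AC, Johnston DA. Quantification of histochemical
#'   staining by color deconvolution. Anal Quant Cytol Histol 2001.
#' @export
stain_basis <- function(vectors = NULL) {
  if (is.null(vectors)) {
    vectors <- rbind(H   = c(0.650, 0.704, 0.286),
                     E   = c(0.072, 0.990, 0.105),
                     DAB = c(0.268, 0.570, 0.776))
  }
  vectors <- as.matrix(vectors)
  if (!all(dim(vectors) == c(3L, 3L)) || !is.numeric(vectors)) {
    stop("`vectors` must be a numeric 3x3 matrix (stains x RGB)", call. = FALSE)
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero stain vector", call. = FALSE)
  vectors <- vectors / nrm
  if (abs(det(vectors)) < 1e-6) {
    stop("stain vectors are not linearly independent", call. = FALSE)
  }
  if (is.null(rownames(vectors))) rownames(vectors) <- c("H", "E", "DAB")
  colnames(vectors) <- c("R", "G", "B")
  structure(vectors, class = c("stain_basis", "matrix"))
}

#' Ground truth for a synthetic IHC brightfield image
#'
#' @param concentration_maps Named list of three nonnegative matrices of one
#'   common shape, in optical-density units, named as the basis rows
#'   (default `H`, `E`, `DAB`).
#' @param basis A [stain_basis()].
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `ihc_truth`.
#' @export
ihc_truth <- function(concentration_maps, basis = stain_basis(), seed = 1L) {
  stopifnot(inherits(basis, "stain_basis"))
  if (!is.list(concentration_maps) || length(concentration_maps) != 3L) {
    stop("`concentration_maps` must be a list of three matrices", call. = FALSE)
  }
  if (is.null(names(concentration_maps))) {
    names(concentration_maps) <- rownames(basis)
  }
  if (!setequal(names(concentration_maps), rownames(basis))) {
    stop("map names must match basis stains", call. = FALSE)
  }
  concentration_maps <- concentration_maps[rownames(basis)]
  dims <- lapply(concentration_maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all concentration maps must share one shape", call. = FALSE)
  }
  if (any(vapply(concentration_maps, function(m) any(m < 0), logical(1)))) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  structure(list(concentration_maps = concentration_maps, basis = basis,
                 seed = as.integer(seed)),
            class = "ihc_truth")
}

# smooth nonnegative blob field: sum of Gaussian bumps
blob_map <- function(shape, n_blobs, peak, sigma_range = c(2, 6)) {
  m <- matrix(0, shape[1], shape[2])
  if (n_blobs == 0L) return(m)
  cx <- stats::runif(n_blobs, 1, shape[1])
  cy <- stats::runif(n_blobs, 1, shape[2])
  s <- stats::runif(n_blobs, sigma_range[1], sigma_range[2])
  h <- stats::runif(n_blobs, 0.3, 1) * peak
  xs <- seq_len(shape[1]); ys <- seq_len(shape[2])
  for (i in seq_len(n_blobs)) {
    m <- m + h[i] * exp(-(outer((xs - cx[i])^2, (ys - cy[i])^2, "+")) /
                          (2 * s[i]^2))
  }
  m
}

#' Random IHC ground truth with blob-shaped stain deposits
#'
#' Generates smooth nonnegative concentration maps (Gaussian blobs) for the
#' three stains. The default per-stain peak of 0.25 OD keeps transmitted
#' light in the regime where 8-bit quantization perturbs unmixed
#' concentrations by less than 2/255 OD, so mix/unmix round trips are exact
#' up to quantization.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param n_blobs Blobs per stain.
#' @param peak_od Per-stain peak concentration in OD units.
#' @param basis A [stain_basis()].
#' @param seed Integer seed.
#' @return An `ihc_truth`.
#' @export
random_ihc_truth <- function(shape = c(64, 64), n_blobs = 4, peak_od = 0.25,
                             basis = stain_basis(), seed = 1L) {
  maps <- with_local_seed(seed, {
    out <- lapply(rownames(basis), function(s) blob_map(shape, n_blobs, peak_od))
    names(out) <- rownames(basis)
    out
  })
  ihc_truth(maps, basis = basis, seed = seed)
}

#' Render a synthetic brightfield RGB image from stain concentrations
#'
#' Beer–Lambert transmission: for colour channel `c`, transmitted light is
#' `I0 * 10^(-sum_s concentration_s * basis[s, c])`, quantized to 8 bits.
#' Background (zero-concentration) pixels are white (`I0 = 255`).
#'
#' @param truth An [ihc_truth()].
#' @param I0 Incident light intensity (255 for 8-bit brightfield).
#' @return Integer array `rows x cols x 3` (R, G, B) in \[0, 255\].
#' @export
gen_ihc_image <- function(truth, I0 = 255) {
  stopifnot(inherits(truth, "ihc_truth"))
  d <- dim(truth$concentration_maps[[1]])
  conc <- vapply(truth$concentration_maps, as.vector,
                 numeric(prod(d)))           # pixels x stains
  od <- conc %*% unclass(truth$basis)        # pixels x RGB
  transmitted <- round(I0 * 10^(-od))
  transmitted <- pmin(pmax(transmitted, 0), 255)
  array(as.integer(transmitted), c(d, 3L))
}

#' Write / read an 8-bit RGB image as PNG
#'
#' @param img Integer array `rows x cols x 3` in \[0, 255\].
#' @param path File path.
#' @return `path` (write) or the integer array (read).
#' @export
write_ihc_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_ihc_png
#' @export
read_ihc_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  array(as.integer(round(a[, , 1:3] * 255)), c(dim(a)[1:2], 3L))
}
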