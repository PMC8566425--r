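# Optical-density color deconvolution of brightfield IHC chromogens.
#
# Stains mix approximately linearly in optical-density (OD) space
# (Beer-Lambert), so per-stain concentrations are recovered by inverting a
# matrix of unit stain vectors. Each deconvolution pass handles at most three
# stains because OD space is three-dimensional; multiplex panels with more
# stains are unmixed with one pass per chromogen, pairing the chromogen with
# the hematoxylin counterstain and a residual vector orthogonal to both.

unit3 <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero stain vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a stain matrix
#'
#' A stain matrix holds up to three unit optical-density vectors, one per
#' stain, and defines a single deconvolution pass. Two-stain matrices are
#' padded with a residual vector orthogonal to both stains so the matrix is
#' invertible.
#'
#' @param vectors named list of numeric length-3 OD vectors (normalized
#'   internally), at most 3 stains.
#' @param max_condition error if the condition number of the (padded) matrix
#'   exceeds this bound; collinear stains cannot be unmixed.
#' @return object of class `stain_matrix` with elements `names`, `M`
#'   (3 x 3 matrix, columns are stains), `n_stains` (before padding).
#' @export
stain_matrix <- function(vectors, max_condition = 50) {
  if (!is.list(vectors) || is.null(names(vectors)) || any(names(vectors) == ""))
    stop("vectors must be a named list")
  k <- length(vectors)
  if (k < 1L || k > 3L) stop("a deconvolution pass supports 1 to 3 stains")
  V <- vapply(vectors, unit3, numeric(3))
  nm <- names(vectors)
  if (k == 1L) {
    # complete with any two orthogonal residuals
    r1 <- unit3(cross3(V[, 1], if (abs(V[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    r2 <- unit3(cross3(V[, 1], r1))
    V <- cbind(V, r1, r2); nm <- c(nm, "residual1", "residual2")
  } else if (k == 2L) {
    r <- cross3(V[, 1], V[, 2])
    if (sqrt(sum(r^2)) < 1e-8) stop("collinear stains")
    V <- cbind(V, unit3(r)); nm <- c(nm, "residual")
  }
  colnames(V) <- nm
  if (kappa(V, exact = TRUE) > max_condition) stop("collinear stains")
  structure(list(names = nm, M = V, n_stains = k,
                 id = paste(nm[seq_len(k)], collapse = "+")),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("stain_matrix:", x$id, "\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Built-in stain vector registry
#'
#' Unit OD vectors for the chromogens used by the two IHC panels
#' (purple = CD3, teal = CD20/CD163, yellow = CD68) plus the hematoxylin
#' counterstain and a neutral background vector. Vectors are fixed
#' configuration shared by the scene generator and the deconvolution step,
#' which makes stain recovery well-posed. They can be overridden from a YAML
#' registry via [read_stain_registry()].
#'
#' @return named list of unit numeric length-3 vectors.
#' @export
default_stain_vectors <- function() {
  lapply(list(
    hematoxylin = c(0.651, 0.701, 0.290),
    purple      = c(0.180, 0.940, 0.290),
    teal        = c(0.950, 0.150, 0.270),
    yellow      = c(0.100, 0.210, 0.970),
    background  = c(1, 1, 1)
  ), unit3)
}

#' Read a stain vector registry from YAML
#'
#' @param path YAML file mapping stain name -> numeric length-3 vector.
#' @return named list of unit vectors.
#' @export
read_stain_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, unit3)
}

#' Deconvolution passes for a staining panel
#'
#' The triple panel (CD3 purple / CD20 teal / CD68 yellow + hematoxylin) has
#' four stains in three-dimensional OD space, so it is unmixed with one pass
#' per chromogen: `[hematoxylin, chromogen, residual]`. Within such a pass the
#' counterstain contributes exactly zero to the chromogen channel and the
#' chromogen contributes exactly zero to the hematoxylin channel. The double
#' panel (CD68 yellow / CD163 teal + hematoxylin) fits in a single pass.
#'
#' @param panel `"triple"` or `"double"`.
#' @param vectors stain vector registry (default [default_stain_vectors()]).
#' @return named list: per marker, a list with `pass` (a [stain_matrix()]),
#'   `marker_channel` and `hema_channel` (column names inside the pass).
#' @export
panel_passes <- function(panel = c("triple", "double"),
                         vectors = default_stain_vectors()) {
  panel <- match.arg(panel)
  h <- vectors$hematoxylin
  if (panel == "triple") {
    markers <- c(CD3 = "purple", CD20 = "teal", CD68 = "yellow")
    out <- lapply(markers, function(chrom) {
      sm <- stain_matrix(stats::setNames(list(h, vectors[[chrom]]),
                                         c("hematoxylin", chrom)))
      list(pass = sm, marker_channel = chrom, hema_channel = "hematoxylin")
    })
  } else {
    sm <- stain_matrix(list(hematoxylin = h, yellow = vectors$yellow,
                            teal = vectors$teal))
    out <- list(
      CD68  = list(pass = sm, marker_channel = "yellow", hema_channel = "hematoxylin"),
      CD163 = list(pass = sm, marker_channel = "teal",   hema_channel = "hematoxylin"))
  }
  out
}

#' Convert an RGB image to optical density
#'
#' `OD = -log10((I + 1) / 256)` per channel, so white (255) maps to 0 and
#' black (0) to `log10(256)`.
#'
#' @param image numeric array `rows x cols x 3` with values in 0..255.
#' @return array of the same shape with OD values.
#' @export
rgb_to_od <- function(image) {
  if (any(!is.finite(image))) stop("non-finite pixels")
  if (min(image) < 0 || max(image) > 255) stop("image channels must be in [0, 255]")
  -log10((image + 1) / 256)
}

#' Convert optical density back to 0..255 intensities
#'
#' Inverse of [rgb_to_od()] before rounding.
#'
#' @param od numeric array of optical densities (>= 0).
#' @return numeric array in 0..255.
#' @export
od_to_rgb <- function(od) {
  pmax(pmin(256 * 10^(-od) - 1, 255), 0)
}

#' Deconvolve an OD image into per-stain concentration channels
#'
#' Applies the inverse of the stain matrix to every pixel's OD vector.
#'
#' @param od_image array `rows x cols x 3` of optical densities.
#' @param matrix a [stain_matrix()].
#' @return object of class `channel_stack`: list with `channels` (named list
#'   of `rows x cols` concentration matrices), `matrix_id`, and
#'   `max_residual` (maximum absolute reconstruction residual,
#'   `|OD - M %*% c|`; ~0 when all stains present are in the matrix).
#' @export
deconvolve <- function(od_image, matrix) {
  stopifnot(inherits(matrix, "stain_matrix"))
  d <- dim(od_image)
  if (length(d) != 3L || d[3] != 3L) stop("od_image must be rows x cols x 3")
  n <- d[1] * d[2]
  odm <- matrix(od_image, nrow = n, ncol = 3L)     # pixels x 3
  conc <- odm %*% t(solve(matrix$M))               # pixels x 3 (M^-1 od)
  recon <- conc %*% t(matrix$M)
  ch <- lapply(seq_len(3L), function(j) matrix(conc[, j], d[1], d[2]))
  names(ch) <- matrix$names
  structure(list(channels = ch, matrix_id = matrix$id,
                 max_residual = max(abs(recon - odm))),
            class = "channel_stack")
}

#' Map a concentration channel to a 0..255 intensity image
#'
#' Uses the monotone map `I = 255 * 10^(-c / scale)`, so zero concentration is
#' white (255) and strong stain is dark (0). This is the representation in
#' which per-object positivity thresholds (e.g. mean intensity < 50) are
#' applied.
#'
#' @param channel numeric matrix of concentrations.
#' @param scale positive scale; concentration == `scale` maps to 25.5.
#' @return numeric matrix in 0..255.
#' @export
channel_to_intensity <- function(channel, scale = 1) {
  stopifnot_scalar(scale, "scale", lo = .Machine$double.eps)
  pmax(pmin(255 * 10^(-pmax(channel, 0) / scale), 255), 0)
}
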