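# Synthetic multiplex-IHC scene generation with ground truth.
#
# A scene is a brightfield RGB image of an FFPE-like breast tissue section:
# a fat/stroma background (FSR), smooth epithelium-enriched regions (EER)
# subdivided into a peri-epithelial band (PE) and intralobular stroma (ILS),
# and planted immune cells rendered as a hematoxylin nucleus disk plus a
# chromogen halo, composed in optical-density space (Beer-Lambert) using the
# same stain vectors the deconvolution step uses.

COMPARTMENT_LEVELS <- c("FSR", "PE", "ILS")

#' Scene specification
#'
#' Parameters for one synthetic tissue image. Densities are cells per square
#' millimeter in the target compartment. Planted cells carry a hematoxylin
#' nucleus (default equivalent diameter 8 +/- 1.5 um) under a chromogen halo
#' whose diameter is drawn at 18 +/- 1.5 um and truncated at 16 um so that
#' genuine cells survive the 15 um detection floor; an optional sub-15 um
#' "debris" population and nucleus-free CD68 "speckle" population exercise
#' the size and nucleus-association filters.
#'
#' @param image_size_px integer length-2 (rows, cols).
#' @param pixel_size_um microns per pixel (default 0.465, the scan resolution
#'   of a 20x whole-slide scanner).
#' @param eer_fraction fraction of image area in epithelium-enriched regions.
#' @param pe_fraction_of_eer fraction of EER that is peri-epithelium.
#' @param panel `"triple"` (CD3/CD20/CD68: classes T, B, Mac) or `"double"`
#'   (CD68/CD163: classes M1, M2).
#' @param planted_density data.frame with columns `class`, `compartment`
#'   (`"PE"` or `"ILS"`), `density` (cells/mm^2), or NULL for none.
#' @param cell_diameter_um c(mean, sd) of nucleus equivalent diameter.
#' @param halo_diameter_um c(mean, sd, min) of chromogen halo diameter.
#' @param chromogen_conc OD concentration amplitude of a halo (maps to
#'   intensity 25.5 at the default intensity scale, i.e. well below the
#'   positivity threshold of 50).
#' @param nucleus_conc hematoxylin amplitude of planted nuclei.
#' @param speckle_fraction nucleus-free CD68 speckles planted at this
#'   fraction of the CD68-class density (classes Mac and M1).
#' @param dp_fraction fraction of M2 cells rendered CD68/CD163 double
#'   positive (green), double panel only.
#' @param debris_per_mm2 sub-15-um chromogen debris objects per mm^2 of EER.
#' @param background_od_noise sd of Gaussian OD noise added per RGB channel.
#' @param stain_vectors stain registry; default [default_stain_vectors()].
#' @param seed integer seed; identical spec + seed gives identical scenes.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = c(1024, 1024),
                       pixel_size_um = 0.465,
                       eer_fraction = 0.6,
                       pe_fraction_of_eer = 0.3,
                       panel = c("triple", "double"),
                       planted_density = NULL,
                       cell_diameter_um = c(8, 1.5),
                       halo_diameter_um = c(18, 1.5, 16),
                       chromogen_conc = 1.2,
                       nucleus_conc = 1.3,
                       speckle_fraction = 0,
                       dp_fraction = 0.5,
                       debris_per_mm2 = 0,
                       background_od_noise = 0.02,
                       stain_vectors = default_stain_vectors(),
                       seed = 1L) {
  panel <- match.arg(panel)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", lo = 1e-6)
  stopifnot_scalar(eer_fraction, "eer_fraction", 0, 1)
  stopifnot_scalar(pe_fraction_of_eer, "pe_fraction_of_eer", 0, 1)
  stopifnot_scalar(background_od_noise, "background_od_noise", 0)
  stopifnot_scalar(speckle_fraction, "speckle_fraction", 0)
  stopifnot_scalar(debris_per_mm2, "debris_per_mm2", 0)
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 64L))
    stop("image_size_px must be two integers >= 64")
  classes <- if (panel == "triple") c("T", "B", "Mac") else c("M1", "M2")
  if (is.null(planted_density)) {
    planted_density <- expand.grid(class = classes,
                                   compartment = c("PE", "ILS"),
                                   stringsAsFactors = FALSE)
    planted_density$density <- 0
  }
  stopifnot(is.data.frame(planted_density),
            all(c("class", "compartment", "density") %in% names(planted_density)))
  if (any(planted_density$density < 0)) stop("densities must be >= 0")
  if (!all(planted_density$class %in% classes))
    stop("planted_density classes must match the panel (", paste(classes, collapse = ", "), ")")
  if (!all(planted_density$compartment %in% c("PE", "ILS")))
    stop("planted_density compartment must be PE or ILS")
  structure(list(
    image_size_px = image_size_px, pixel_size_um = pixel_size_um,
    eer_fraction = eer_fraction, pe_fraction_of_eer = pe_fraction_of_eer,
    panel = panel, planted_density = planted_density,
    cell_diameter_um = cell_diameter_um, halo_diameter_um = halo_diameter_um,
    chromogen_conc = chromogen_conc, nucleus_conc = nucleus_conc,
    speckle_fraction = speckle_fraction, dp_fraction = dp_fraction,
    debris_per_mm2 = debris_per_mm2,
    background_od_noise = background_od_noise,
    stain_vectors = stain_vectors, seed = as.integer(seed)),
    class = "scene_spec")
}

# smooth random field from a small sum of low-frequency cosine waves;
# feature_px sets the characteristic feature size in pixels. Each plane wave
# cos(u(col) + v(row)) is expanded as outer products of 1-D cosines/sines so
# transcendentals are only evaluated on vectors.
smooth_field <- function(nr, nc, feature_px, n_waves = 8L) {
  # fields are band-limited well below 1/(4 px), so synthesize on a coarse
  # grid and upscale bilinearly when the feature size allows it
  fac <- max(1L, min(4L, floor(feature_px / 16)))
  nr2 <- ceiling(nr / fac); nc2 <- ceiling(nc / fac)
  x <- seq_len(nc2) * fac; y <- seq_len(nr2) * fac
  f <- matrix(0, nr2, nc2)
  for (k in seq_len(n_waves)) {
    freq <- stats::runif(1, 0.5, 1.5) / feature_px
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::runif(1, 0.5, 1)
    u <- 2 * pi * freq * cos(th) * x + ph     # column part (carries phase)
    v <- 2 * pi * freq * sin(th) * y          # row part
    f <- f + a * (outer(cos(v), cos(u)) - outer(sin(v), sin(u)))
  }
  if (fac > 1L) {
    f <- EBImage::resize(EBImage::Image(f), w = nr, h = nc, filter = "bilinear")
    f <- matrix(EBImage::imageData(f), nr, nc)
  }
  f
}

#' Construct a compartment mask
#'
#' @param labels integer matrix, 0 = FSR, 1 = PE, 2 = ILS.
#' @param pixel_size_um microns per pixel.
#' @return object of class `compartment_mask` with per-label pixel counts and
#'   areas in mm^2 (`area_mm2 = pixels * (pixel_size_um / 1000)^2`).
#' @export
compartment_mask <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  px <- c(FSR = sum(labels == 0L), PE = sum(labels == 1L), ILS = sum(labels == 2L))
  area <- px * (pixel_size_um / 1000)^2
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 pixel_counts = px, area_mm2 = area),
            class = "compartment_mask")
}

#' @export
print.compartment_mask <- function(x, ...) {
  cat("compartment_mask", paste(dim(x$labels), collapse = " x "),
      sprintf("px @ %.3f um/px\n", x$pixel_size_um))
  print(round(x$area_mm2, 4))
  invisible(x)
}

# quantile-thresholded smooth fields give exact area fractions with
# blob/band morphology: EER = top eer_fraction of a coarse field; PE = a
# high band of a finer "duct" field within EER (band around duct cores).
generate_compartments <- function(spec) {
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  labels <- matrix(0L, nr, nc)
  if (spec$eer_fraction > 0) {
    f_eer <- smooth_field(nr, nc, feature_px = max(nr, nc) / 2.5)
    thr <- stats::quantile(f_eer, 1 - spec$eer_fraction, names = FALSE)
    eer <- f_eer >= thr
    labels[eer] <- 2L
    if (spec$pe_fraction_of_eer > 0) {
      f_duct <- smooth_field(nr, nc, feature_px = 350 / spec$pixel_size_um)
      v <- f_duct[eer]
      lumen_frac <- min(0.05, (1 - spec$pe_fraction_of_eer) / 2)
      q_hi <- stats::quantile(v, 1 - lumen_frac, names = FALSE)
      q_lo <- stats::quantile(v, 1 - lumen_frac - spec$pe_fraction_of_eer,
                              names = FALSE)
      pe <- eer & f_duct >= q_lo & f_duct < q_hi
      labels[pe] <- 1L
    }
  }
  compartment_mask(labels, spec$pixel_size_um)
}

# hard-core placement of n points uniformly on the pixels where allowed==TRUE,
# min separation min_sep_px; errors after bounded retries
place_points <- function(allowed, n, min_sep_px, existing = NULL,
                         max_tries_per_point = 200L) {
  if (n == 0L) return(cbind(row = integer(0), col = integer(0)))
  idx <- which(allowed)
  if (length(idx) == 0L) stop("overcrowded scene: no room in target compartment")
  nr <- nrow(allowed)
  cell <- max(1, ceiling(min_sep_px))
  hash <- new.env(hash = TRUE, parent = emptyenv())
  keyof <- function(r, c) paste(r %/% cell, c %/% cell)
  addpt <- function(r, c) {
    k <- keyof(r, c)
    assign(k, rbind(get0(k, envir = hash, ifnotfound = NULL), c(r, c)), envir = hash)
  }
  okpt <- function(r, c) {
    gr <- r %/% cell; gc <- c %/% cell
    for (dr in -1:1) for (dc in -1:1) {
      pts <- get0(paste(gr + dr, gc + dc), envir = hash, ifnotfound = NULL)
      if (!is.null(pts) &&
          any((pts[, 1] - r)^2 + (pts[, 2] - c)^2 < min_sep_px^2)) return(FALSE)
    }
    TRUE
  }
  if (!is.null(existing) && nrow(existing))
    for (i in seq_len(nrow(existing))) addpt(existing[i, 1], existing[i, 2])
  out <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tr in seq_len(max_tries_per_point)) {
      j <- idx[sample.int(length(idx), 1L)]
      r <- ((j - 1L) %% nr) + 1L; c <- ((j - 1L) %/% nr) + 1L
      if (okpt(r, c)) { addpt(r, c); out[i, ] <- c(r, c); placed <- TRUE; break }
    }
    if (!placed) stop("overcrowded scene: hard-core placement failed")
  }
  colnames(out) <- c("row", "col")
  out
}

# linear indices of the pixels of a disk centered at (r0, c0)
disk_indices <- function(r0, c0, radius_px, nr, nc) {
  R <- ceiling(radius_px)
  rows <- max(1L, r0 - R):min(nr, r0 + R)
  cols <- max(1L, c0 - R):min(nc, c0 + R)
  dr <- rows - r0
  dc <- cols - c0
  inside <- outer(dr^2, dc^2, `+`) <= radius_px^2
  idx <- (rep(cols, each = length(rows)) - 1L) * nr +
    rep(rows, times = length(cols))
  idx[as.vector(inside)]
}

# stamp a disk of given radius (px) into field by pmax with amplitude
stamp_disk <- function(field, r0, c0, radius_px, amplitude) {
  idx <- disk_indices(r0, c0, radius_px, nrow(field), ncol(field))
  field[idx] <- pmax(field[idx], amplitude)
  field
}

# chromogens used to render each cell class
class_chromogens <- function(class, panel, dp) {
  switch(paste(panel, class, sep = "."),
    triple.T = "purple", triple.B = "teal", triple.Mac = "yellow",
    double.M1 = "yellow",
    double.M2 = if (dp) c("teal", "yellow") else "teal",
    stop("unknown class ", class))
}

#' Generate a synthetic IHC scene
#'
#' Renders compartments, planted cells, speckles and debris into an RGB
#' brightfield image via Beer-Lambert composition of per-stain optical
#' densities, and returns the image together with the exact ground truth.
#'
#' @param spec a [scene_spec()].
#' @return object of class `ihc_scene`: list with `image` (rows x cols x 3,
#'   0..255), `truth` (list: `compartment_mask`, `cells` data.frame,
#'   `speckles` data.frame, `debris` data.frame, `planted_density_realized`
#'   data.frame with exact count/area/density per class x compartment), and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    mask <- generate_compartments(spec)
    lab <- mask$labels
    um2px <- 1 / spec$pixel_size_um

    # background concentration fields
    hema <- matrix(0.04, nr, nc)
    hema[lab == 2L] <- 0.15
    hema[lab == 1L] <- 0.55
    tex <- smooth_field(nr, nc, feature_px = 60 * um2px, n_waves = 6L)
    tex <- tex / max(abs(tex) , 1e-9)
    hema <- pmax(hema + 0.06 * tex * (0.5 + 0.5 * (lab == 1L)), 0)
    bg <- matrix(0.05, nr, nc)
    bg[lab != 0L] <- 0.02

    chrom_names <- if (spec$panel == "triple") c("purple", "teal", "yellow")
                   else c("teal", "yellow")
    # disk stamps are collected as linear pixel indices and applied in one
    # vectorized pass per stain (per-pixel max at the stamp amplitude)
    chrom_idx <- stats::setNames(lapply(chrom_names, function(i) list()),
                                 chrom_names)
    nuc_idx <- list()
    add_stamp <- function(store, r0, c0, radius_px) {
      store[[length(store) + 1L]] <- disk_indices(r0, c0, radius_px, nr, nc)
      store
    }

    pd <- spec$planted_density
    pd <- pd[order(pd$class, pd$compartment), , drop = FALSE]
    # separation floor above the halo-diameter tail so halos of adjacent
    # cells do not fuse into one binary object
    min_sep_px <- (spec$halo_diameter_um[1] + 4 * spec$halo_diameter_um[2]) * um2px
    cells <- list(); speckles <- list(); debris <- list()
    placed <- NULL
    cell_id <- 0L

    draw_halo_diam <- function(n) {
      pmax(spec$halo_diameter_um[3],
           stats::rnorm(n, spec$halo_diameter_um[1], spec$halo_diameter_um[2]))
    }
    draw_nuc_diam <- function(n) {
      pmax(3, stats::rnorm(n, spec$cell_diameter_um[1], spec$cell_diameter_um[2]))
    }

    for (i in seq_len(nrow(pd))) {
      cls <- pd$class[i]; comp <- pd$compartment[i]; dens <- pd$density[i]
      if (dens <= 0) next
      area <- mask$area_mm2[[comp]]
      if (area <= 0) next
      n <- stats::rpois(1L, dens * area)
      if (n == 0L) next
      allowed <- lab == (if (comp == "PE") 1L else 2L)
      pts <- place_points(allowed, n, min_sep_px, existing = placed)
      placed <- rbind(placed, pts)
      hd <- draw_halo_diam(n); nd <- draw_nuc_diam(n)
      dp <- stats::runif(n) < spec$dp_fraction
      for (j in seq_len(n)) {
        cell_id <- cell_id + 1L
        for (ch in class_chromogens(cls, spec$panel, dp[j]))
          chrom_idx[[ch]] <- add_stamp(chrom_idx[[ch]], pts[j, 1], pts[j, 2],
                                       hd[j] / 2 * um2px)
        nuc_idx <- add_stamp(nuc_idx, pts[j, 1], pts[j, 2], nd[j] / 2 * um2px)
        cells[[cell_id]] <- data.frame(
          id = cell_id, row_px = pts[j, 1], col_px = pts[j, 2],
          diameter_um = hd[j], nucleus_diameter_um = nd[j],
          class = cls, compartment = comp, double_positive = dp[j] && cls == "M2")
      }
      # nucleus-free speckles for CD68-marked classes
      if (spec$speckle_fraction > 0 && cls %in% c("Mac", "M1")) {
        ns <- stats::rpois(1L, dens * spec$speckle_fraction * area)
        if (ns > 0L) {
          sp <- place_points(allowed, ns, min_sep_px, existing = placed)
          placed <- rbind(placed, sp)
          shd <- draw_halo_diam(ns)
          for (j in seq_len(ns)) {
            chrom_idx$yellow <- add_stamp(chrom_idx$yellow, sp[j, 1], sp[j, 2],
                                          shd[j] / 2 * um2px)
            speckles[[length(speckles) + 1L]] <- data.frame(
              row_px = sp[j, 1], col_px = sp[j, 2], diameter_um = shd[j],
              class = cls, compartment = comp)
          }
        }
      }
    }

    # sub-15-um debris to exercise the size filter
    if (spec$debris_per_mm2 > 0) {
      eer_area <- mask$area_mm2[["PE"]] + mask$area_mm2[["ILS"]]
      ndeb <- stats::rpois(1L, spec$debris_per_mm2 * eer_area)
      if (ndeb > 0L) {
        dpn <- place_points(lab != 0L, ndeb, min_sep_px, existing = placed)
        ddiam <- stats::runif(ndeb, 5, 10)
        for (j in seq_len(ndeb)) {
          ch <- sample(chrom_names, 1L)
          chrom_idx[[ch]] <- add_stamp(chrom_idx[[ch]], dpn[j, 1], dpn[j, 2],
                                       ddiam[j] / 2 * um2px)
          debris[[j]] <- data.frame(row_px = dpn[j, 1], col_px = dpn[j, 2],
                                    diameter_um = ddiam[j], chromogen = ch)
        }
      }
    }

    if (length(nuc_idx)) {
      idx <- unique(unlist(nuc_idx))
      hema[idx] <- pmax(hema[idx], spec$nucleus_conc)
    }

    # Beer-Lambert composition; chromogen fields are sparse (disk stamps),
    # so they are added at their pixel indices rather than as full planes
    vecs <- spec$stain_vectors
    od <- array(0, c(nr, nc, 3))
    plane_px <- as.double(nr) * nc
    for (k in 1:3)
      od[, , k] <- hema * vecs$hematoxylin[k] + bg * vecs$background[k]
    for (ch in chrom_names) {
      if (!length(chrom_idx[[ch]])) next
      idx <- unique(unlist(chrom_idx[[ch]]))
      for (k in 1:3) {
        off <- idx + (k - 1) * plane_px
        od[off] <- od[off] + spec$chromogen_conc * vecs[[ch]][k]
      }
    }
    if (spec$background_od_noise > 0)
      od <- pmax(od + stats::rnorm(length(od), 0, spec$background_od_noise), 0)
    image <- round(od_to_rgb(od))

    cells <- if (length(cells)) do.call(rbind, cells) else
      data.frame(id = integer(0), row_px = integer(0), col_px = integer(0),
                 diameter_um = numeric(0), nucleus_diameter_um = numeric(0),
                 class = character(0), compartment = character(0),
                 double_positive = logical(0))
    speckles <- if (length(speckles)) do.call(rbind, speckles) else
      data.frame(row_px = integer(0), col_px = integer(0),
                 diameter_um = numeric(0), class = character(0),
                 compartment = character(0))
    debris <- if (length(debris)) do.call(rbind, debris) else
      data.frame(row_px = integer(0), col_px = integer(0),
                 diameter_um = numeric(0), chromogen = character(0))

    realized <- pd
    realized$count <- vapply(seq_len(nrow(pd)), function(i)
      sum(cells$class == pd$class[i] & cells$compartment == pd$compartment[i]),
      integer(1))
    realized$area_mm2 <- mask$area_mm2[realized$compartment]
    realized$realized_density <- ifelse(realized$area_mm2 > 0,
                                        realized$count / realized$area_mm2, 0)

    structure(list(image = image,
                   truth = list(compartment_mask = mask, cells = cells,
                                speckles = speckles, debris = debris,
                                planted_density_realized = realized),
                   spec = spec),
              class = "ihc_scene")
  })
}

#' @export
print.ihc_scene <- function(x, ...) {
  cat(sprintf("ihc_scene %d x %d px (%s panel), %d cells, %d speckles\n",
              nrow(x$image), ncol(x$image), x$spec$panel,
              nrow(x$truth$cells), nrow(x$truth$speckles)))
  invisible(x)
}

#' Write a scene to disk as plain image + truth files
#'
#' Writes the RGB image as TIFF, the compartment label map as TIFF
#' (0 = FSR, 1 = PE, 2 = ILS) and the planted cells as CSV.
#'
#' @param scene an `ihc_scene`.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".tiff"))
  mask_path <- file.path(dir, paste0(name, "_mask.tiff"))
  cells_path <- file.path(dir, paste0(name, "_cells.csv"))
  tiff::writeTIFF(scene$image / 255, img_path, bits.per.sample = 8L)
  tiff::writeTIFF(scene$truth$compartment_mask$labels / 255, mask_path,
                  bits.per.sample = 8L)
  utils::write.csv(scene$truth$cells, cells_path, row.names = FALSE)
  invisible(c(img_path, mask_path, cells_path))
}

#' Read a scene image written by [write_scene()]
#'
#' @param path TIFF path.
#' @return numeric array rows x cols x 3 in 0..255.
#' @export
read_scene_image <- function(path) {
  img <- tiff::readTIFF(path)
  round(img * 255)
}
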