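# Cell detection, filtering and classification from deconvolved channels.
#
# The detection chain per marker channel: mean-filter smoothing, dark-object
# binarization, connected components, watershed splitting of objects larger
# than the characteristic blob scale (33 um), removal of objects with
# equivalent diameter < 15 um, and removal of objects whose mean channel
# intensity is >= 50 (0 = strongest stain). CD68 objects must additionally
# overlap a hematoxylin nucleus object, which removes nucleus-free "speckle"
# staining from sliced macrophage fragments.

#' Detection parameters
#'
#' Lengths are in microns so the same configuration applies across
#' magnifications; they are converted to pixels with the image's pixel size.
#'
#' @param mean_filter_radius_um radius of the circular mean filter.
#' @param blob_scale_um characteristic single-blob size; objects with larger
#'   equivalent diameter are watershed-split into touching cells.
#' @param min_object_um objects with equivalent-circle diameter strictly less
#'   than this are removed (15.0 um is kept).
#' @param positivity_intensity_threshold objects with per-object mean channel
#'   intensity strictly below this are positive (a mean of exactly 50 is not).
#' @param binarize_intensity pixels darker than this form candidate objects.
#' @param nucleus_overlap_min fraction of a CD68 object's area that must
#'   overlap a nucleus object for the cell to be kept.
#' @param overlap_merge_min objects from different marker channels sharing at
#'   least this fraction of the smaller object's area are merged into one cell.
#' @param intensity_scale scale of [channel_to_intensity()].
#' @param nucleus_binarize_intensity binarization threshold for the
#'   hematoxylin channel (darker than tissue background, lighter than nuclei).
#' @param nucleus_min_um minimum equivalent diameter of nucleus objects.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(mean_filter_radius_um = 2,
                             blob_scale_um = 33,
                             min_object_um = 15,
                             positivity_intensity_threshold = 50,
                             binarize_intensity = 100,
                             nucleus_overlap_min = 0.01,
                             overlap_merge_min = 0.3,
                             intensity_scale = 1,
                             nucleus_binarize_intensity = 32,
                             nucleus_min_um = 3) {
  stopifnot_scalar(mean_filter_radius_um, "mean_filter_radius_um", lo = 1e-6)
  stopifnot_scalar(blob_scale_um, "blob_scale_um", lo = 1e-6)
  stopifnot_scalar(min_object_um, "min_object_um", lo = 0)
  stopifnot_scalar(positivity_intensity_threshold,
                   "positivity_intensity_threshold", lo = 0, hi = 255)
  stopifnot_scalar(binarize_intensity, "binarize_intensity", lo = 0, hi = 255)
  stopifnot_scalar(nucleus_overlap_min, "nucleus_overlap_min", lo = 0, hi = 1)
  structure(list(mean_filter_radius_um = mean_filter_radius_um,
                 blob_scale_um = blob_scale_um,
                 min_object_um = min_object_um,
                 positivity_intensity_threshold = positivity_intensity_threshold,
                 binarize_intensity = binarize_intensity,
                 nucleus_overlap_min = nucleus_overlap_min,
                 overlap_merge_min = overlap_merge_min,
                 intensity_scale = intensity_scale,
                 nucleus_binarize_intensity = nucleus_binarize_intensity,
                 nucleus_min_um = nucleus_min_um),
            class = "detection_params")
}

# square mean filter of side 2r+1 via integral images (replicate boundary);
# linear time, which matters on whole-scene channels
mean_filter <- function(x, radius_px) {
  r <- max(1L, round(radius_px))
  nr <- nrow(x); nc <- ncol(x)
  pad <- x[c(rep(1L, r), seq_len(nr), rep(nr, r)),
           c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  S <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed integral image
  S <- rbind(0, cbind(0, S))                      # (nc+2r+1) x (nr+2r+1)
  w <- 2L * r + 1L
  # window sums via the inclusion-exclusion corners (S is transposed)
  ci <- seq_len(nc) + w - 1L; ri <- seq_len(nr) + w - 1L
  sums <- S[ci + 1L, ri + 1L, drop = FALSE] -
    S[ci + 1L - w, ri + 1L, drop = FALSE] -
    S[ci + 1L, ri + 1L - w, drop = FALSE] +
    S[ci + 1L - w, ri + 1L - w, drop = FALSE]
  t(sums) / (w * w)
}

# per-label features from a smoothed concentration map; the per-object mean
# intensity is computed on the 0..255 scale from object pixels only
label_features_conc <- function(labels, smc, pixel_size_um, intensity_scale) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      row_px = numeric(0), col_px = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      mean_intensity = numeric(0)))
  pos <- which(labels > 0L)
  lab <- labels[pos]
  nr <- nrow(labels)
  rows <- ((pos - 1L) %% nr) + 1L
  cols <- ((pos - 1L) %/% nr) + 1L
  inten <- channel_to_intensity(smc[pos], intensity_scale)
  area <- tabulate(lab, nbins = n)
  rsum <- rowsum(cbind(rows, cols, inten), lab)
  keep <- area > 0L
  labs <- which(keep)
  data.frame(label = labs,
             area_px = area[keep],
             row_px = rsum[, 1] / area[keep],
             col_px = rsum[, 2] / area[keep],
             equivalent_diameter_um =
               2 * sqrt(area[keep] / pi) * pixel_size_um,
             mean_intensity = rsum[, 3] / area[keep])
}

#' Detect candidate stained objects in one channel intensity map
#'
#' @param intensity_map matrix in the 0..255 convention (0 = strongest stain).
#' @param params a [detection_params()].
#' @param pixel_size_um microns per pixel (required; size filters are metric).
#' @param min_object_um size floor; defaults to `params$min_object_um`
#'   (the nucleus channel uses its own, smaller floor).
#' @param binarize_intensity binarization threshold; defaults to
#'   `params$binarize_intensity`.
#' @param apply_positivity apply the mean-intensity positivity filter.
#' @return list with `objects` (data.frame: label, area_px, row_px, col_px,
#'   equivalent_diameter_um, mean_intensity) and `labels` (integer matrix of
#'   retained objects, relabeled 1..n).
#' @export
detect_candidates <- function(intensity_map, params, pixel_size_um,
                              min_object_um = params$min_object_um,
                              binarize_intensity = params$binarize_intensity,
                              apply_positivity = TRUE) {
  if (missing(pixel_size_um) || is.null(pixel_size_um))
    stop("pixel_size_um is required: size thresholds are in microns")
  # smoothing is linear in stain concentration, not in the 0..255 intensity
  # map (which is convex in concentration and would erode dark objects), so
  # invert the intensity map, mean-filter, and map back
  conc <- -params$intensity_scale * log10(pmax(intensity_map, 0.5) / 255)
  detect_candidates_conc(conc, params, pixel_size_um,
                         min_object_um = min_object_um,
                         binarize_intensity = binarize_intensity,
                         apply_positivity = apply_positivity)
}

# detection core working directly on a deconvolved concentration channel
# (avoids the intensity round-trip when the caller already has
# concentrations); thresholds are still expressed on the intensity scale
detect_candidates_conc <- function(conc, params, pixel_size_um,
                                   min_object_um = params$min_object_um,
                                   binarize_intensity = params$binarize_intensity,
                                   apply_positivity = TRUE) {
  smc <- mean_filter(conc, params$mean_filter_radius_um / pixel_size_um)
  # intensity < thr  <=>  concentration > scale * log10(255 / thr)
  conc_thr <- params$intensity_scale * log10(255 / binarize_intensity)
  bin <- smc > conc_thr
  labels <- EBImage::bwlabel(EBImage::Image(bin))
  labels <- matrix(as.integer(EBImage::imageData(labels)), nrow(bin), ncol(bin))
  labels <- split_oversized(labels, bin, params$blob_scale_um, pixel_size_um)
  feats <- label_features_conc(labels, smc, pixel_size_um,
                               params$intensity_scale)
  keep <- feats$equivalent_diameter_um >= min_object_um
  if (apply_positivity)
    keep <- keep & feats$mean_intensity < params$positivity_intensity_threshold
  feats <- feats[keep, , drop = FALSE]
  relab <- integer(max(labels, 1L))
  relab[feats$label] <- seq_len(nrow(feats))
  out_labels <- matrix(0L, nrow(labels), ncol(labels))
  pos <- which(labels > 0L)
  out_labels[pos] <- relab[labels[pos]]
  feats$label <- seq_len(nrow(feats))
  rownames(feats) <- NULL
  list(objects = feats, labels = out_labels)
}

# watershed-split connected components whose equivalent diameter exceeds the
# characteristic blob scale; smaller components keep their single label
split_oversized <- function(labels, bin, blob_scale_um, pixel_size_um) {
  n <- max(labels)
  if (n == 0L) return(labels)
  area <- tabulate(labels[labels > 0L], nbins = n)
  max_area_px <- pi * (blob_scale_um / 2 / pixel_size_um)^2
  big <- which(area > max_area_px)
  if (!length(big)) return(labels)
  nr <- nrow(labels)
  next_label <- n
  for (b in big) {
    pos <- which(labels == b)
    rows <- range(((pos - 1L) %% nr) + 1L)
    cols <- range(((pos - 1L) %/% nr) + 1L)
    sub <- labels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE] == b
    dm <- EBImage::distmap(EBImage::Image(sub))
    ws <- EBImage::watershed(dm, tolerance = 1)
    wsm <- matrix(as.integer(EBImage::imageData(ws)), nrow(sub), ncol(sub))
    k <- max(wsm)
    if (k <= 1L) next
    subidx <- which(sub)
    # map sub-window coordinates back to full-image linear indices
    sr <- ((subidx - 1L) %% nrow(sub)) + rows[1]
    sc <- ((subidx - 1L) %/% nrow(sub)) + cols[1]
    fidx <- (sc - 1L) * nr + sr
    w <- wsm[subidx]
    labels[fidx] <- ifelse(w == 1L, b, next_label + w - 1L)
    next_label <- next_label + k - 1L
  }
  labels
}

#' Drop CD68 objects without an associated nucleus
#'
#' @param cd68 detection result (from [detect_candidates()]) for the CD68
#'   channel.
#' @param nuclei detection result for the hematoxylin channel.
#' @param params a [detection_params()]; `nucleus_overlap_min` is the minimum
#'   fraction of the CD68 object's area overlapping any nucleus object.
#' @return filtered detection result (objects relabeled 1..n).
#' @export
associate_nucleus <- function(cd68, nuclei, params) {
  if (nrow(cd68$objects) == 0L) return(cd68)
  nucmask <- nuclei$labels > 0L
  pos <- which(cd68$labels > 0L)
  lab <- cd68$labels[pos]
  ov <- rowsum(as.numeric(nucmask[pos]), lab)
  ovfrac <- numeric(nrow(cd68$objects))
  ovfrac[as.integer(rownames(ov))] <- ov[, 1]
  ovfrac <- ovfrac / cd68$objects$area_px
  keep <- ovfrac >= pmax(params$nucleus_overlap_min, .Machine$double.eps)
  objects <- cd68$objects[keep, , drop = FALSE]
  relab <- integer(nrow(cd68$objects))
  relab[objects$label] <- seq_len(nrow(objects))
  labels <- matrix(0L, nrow(cd68$labels), ncol(cd68$labels))
  labels[pos] <- relab[lab]
  objects$label <- seq_len(nrow(objects))
  rownames(objects) <- NULL
  list(objects = objects, labels = labels)
}

#' Merge per-marker objects into classified cells
#'
#' Objects from different marker channels are merged into one cell when they
#' share at least `overlap_merge_min` of the smaller object's area. Triple
#' panel: cells positive for exactly one of CD3/CD20/CD68 are classed T, B,
#' Mac; multi-positive collisions are `unclassified` and excluded from
#' counts. Double panel: CD163-positive cells are M2 whether or not they are
#' also CD68-positive; CD68-positive/CD163-negative cells are M1.
#'
#' @param detections named list of detection results, names are marker names
#'   (`CD3`, `CD20`, `CD68` or `CD68`, `CD163`).
#' @param panel `"triple"` or `"double"`.
#' @param params a [detection_params()].
#' @return data.frame of cells: `cell_id`, `row_px`, `col_px`,
#'   `equivalent_diameter_um`, one logical `<marker>_pos` and numeric
#'   `<marker>_mean_intensity` column per marker, and `class`.
#' @export
classify_cells <- function(detections, panel = c("triple", "double"), params) {
  panel <- match.arg(panel)
  markers <- names(detections)
  expected <- if (panel == "triple") c("CD3", "CD20", "CD68") else c("CD68", "CD163")
  if (!setequal(markers, expected))
    stop("detections must be named ", paste(expected, collapse = ", "))
  markers <- expected

  # global object table
  objs <- do.call(rbind, lapply(markers, function(m) {
    o <- detections[[m]]$objects
    if (nrow(o) == 0L) return(NULL)
    o$marker <- m
    o
  }))
  if (is.null(objs) || nrow(objs) == 0L) {
    out <- data.frame(cell_id = integer(0), row_px = numeric(0),
                      col_px = numeric(0), equivalent_diameter_um = numeric(0))
    for (m in markers) {
      out[[paste0(m, "_pos")]] <- logical(0)
      out[[paste0(m, "_mean_intensity")]] <- numeric(0)
    }
    out$class <- character(0)
    return(out)
  }
  objs$gid <- seq_len(nrow(objs))

  # union-find over spatially overlapping objects of different markers
  parent <- seq_len(nrow(objs))
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unio <- function(i, j) { ri <- findp(i); rj <- findp(j); if (ri != rj) parent[rj] <<- ri }
  gid_of <- lapply(markers, function(m) {
    o <- detections[[m]]$objects
    ids <- integer(max(c(0L, o$label)))
    ids[o$label] <- objs$gid[objs$marker == m]
    ids
  })
  names(gid_of) <- markers
  for (a in seq_along(markers)) for (b in seq_along(markers)) {
    if (a >= b) next
    la <- detections[[markers[a]]]$labels
    lb <- detections[[markers[b]]]$labels
    both <- which(la > 0L & lb > 0L)
    if (!length(both)) next
    pair <- paste(la[both], lb[both])
    cnt <- table(pair)
    ids <- strsplit(names(cnt), " ", fixed = TRUE)
    for (k in seq_along(cnt)) {
      ia <- as.integer(ids[[k]][1]); ib <- as.integer(ids[[k]][2])
      ga <- gid_of[[markers[a]]][ia]; gb <- gid_of[[markers[b]]][ib]
      minarea <- min(objs$area_px[ga], objs$area_px[gb])
      if (cnt[[k]] / minarea >= params$overlap_merge_min) unio(ga, gb)
    }
  }
  objs$cell <- vapply(objs$gid, findp, integer(1))

  f <- match(objs$cell, sort(unique(objs$cell)))
  n_cells <- max(f)
  area_sum <- rowsum(objs$area_px, f)[, 1]
  cells <- data.frame(
    row_px = rowsum(objs$row_px * objs$area_px, f)[, 1] / area_sum,
    col_px = rowsum(objs$col_px * objs$area_px, f)[, 1] / area_sum,
    equivalent_diameter_um =
      as.numeric(tapply(objs$equivalent_diameter_um, f, max)))
  for (m in markers) {
    hit <- objs$marker == m
    pos <- logical(n_cells)
    pos[unique(f[hit])] <- TRUE
    mi <- rep(NA_real_, n_cells)
    if (any(hit))
      mi[as.integer(names(tapply(objs$mean_intensity[hit], f[hit], min)))] <-
        as.numeric(tapply(objs$mean_intensity[hit], f[hit], min))
    cells[[paste0(m, "_pos")]] <- pos
    cells[[paste0(m, "_mean_intensity")]] <- mi
  }
  cells$cell_id <- seq_len(nrow(cells))
  rownames(cells) <- NULL

  if (panel == "triple") {
    npos <- cells$CD3_pos + cells$CD20_pos + cells$CD68_pos
    cells$class <- ifelse(npos != 1L, "unclassified",
                   ifelse(cells$CD3_pos, "T",
                   ifelse(cells$CD20_pos, "B", "Mac")))
  } else {
    cells$class <- ifelse(cells$CD163_pos, "M2",
                   ifelse(cells$CD68_pos, "M1", "unclassified"))
  }
  cells[, c("cell_id", setdiff(names(cells), "cell_id"))]
}

#' Assign each cell to a tissue compartment
#'
#' The compartment is the mask label under the cell centroid; centroids in
#' FSR are `"outside"` and excluded from compartment densities.
#'
#' @param cells data.frame with `row_px`, `col_px` (e.g. [classify_cells()]).
#' @param mask a [compartment_mask()] in the same coordinate frame.
#' @return `cells` with a `compartment` column (`"PE"`, `"ILS"`, `"outside"`).
#' @export
assign_compartment <- function(cells, mask) {
  stopifnot(inherits(mask, "compartment_mask"))
  if (nrow(cells) == 0L) { cells$compartment <- character(0); return(cells) }
  r <- round(cells$row_px); c <- round(cells$col_px)
  if (any(r < 1 | r > nrow(mask$labels) | c < 1 | c > ncol(mask$labels)))
    stop("cell centroid outside image")
  lab <- mask$labels[cbind(r, c)]
  cells$compartment <- c("outside", "PE", "ILS")[lab + 1L]
  cells
}

#' Detect and classify all cells in an image
#'
#' Full per-image detection driver: RGB to OD, per-marker deconvolution
#' passes, candidate detection per marker channel, nucleus association for
#' CD68, and cross-marker classification.
#'
#' @param image RGB array rows x cols x 3 in 0..255.
#' @param panel `"triple"` or `"double"`.
#' @param params a [detection_params()].
#' @param pixel_size_um microns per pixel.
#' @param stain_vectors stain registry shared with the renderer/deconvolver.
#' @return data.frame of classified cells (see [classify_cells()]).
#' @export
detect_cells <- function(image, panel = c("triple", "double"),
                         params = detection_params(),
                         pixel_size_um = 0.465,
                         stain_vectors = default_stain_vectors()) {
  panel <- match.arg(panel)
  d <- dim(image)
  od <- rgb_to_od(image)
  odm <- matrix(od, d[1] * d[2], 3L)
  passes <- panel_passes(panel, stain_vectors)
  detections <- list()
  for (marker in names(passes)) {
    p <- passes[[marker]]
    inv <- solve(p$pass$M)
    chan_row <- inv[match(p$marker_channel, p$pass$names), ]
    conc <- matrix(odm %*% chan_row, d[1], d[2])
    det <- detect_candidates_conc(conc, params, pixel_size_um)
    if (marker == "CD68") {
      hema_row <- inv[match(p$hema_channel, p$pass$names), ]
      hema_conc <- matrix(odm %*% hema_row, d[1], d[2])
      nuc <- detect_candidates_conc(hema_conc, params, pixel_size_um,
                                    min_object_um = params$nucleus_min_um,
                                    binarize_intensity = params$nucleus_binarize_intensity,
                                    apply_positivity = FALSE)
      det <- associate_nucleus(det, nuc, params)
    }
    detections[[marker]] <- det
  }
  classify_cells(detections, panel, params)
}
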