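# Two-stage tissue segmentation with a desk-scale encoder-decoder network.
#
# Stage A separates epithelium-enriched regions (EER) from fat/stroma (FSR);
# stage B runs only inside EER and separates the peri-epithelial band (PE)
# from intralobular stroma (ILS). The network is a classic encoder-decoder
# with skip connections and ReLU activations (f(x) = max(0, x)), trained on
# annotated tiles with flip/rotation/intensity augmentation until the
# validation pixel error drops below a target (default 10%) or the epoch
# budget is exhausted. Inference tiles the image with 50% overlap and
# averages class scores before the argmax.

#' Segmenter training parameters
#'
#' @param tile_px square input tile size (divisible by 2^depth).
#' @param depth number of pooling levels.
#' @param base_channels channels of the first encoder level (doubled per
#'   level); the desk-scale default is narrow by design.
#' @param epochs maximum training epochs (one pass over the training tiles).
#' @param lr Adam learning rate.
#' @param target_validation_error stop early when the validation pixel
#'   misclassification fraction drops below this.
#' @param val_fraction fraction of tiles held out for validation.
#' @param augment apply random flips/rotations and intensity jitter.
#' @param check_every validate every this many epochs.
#' @return list of class `segmenter_params`.
#' @export
segmenter_params <- function(tile_px = 64L, depth = 2L, base_channels = 8L,
                             epochs = 60L, lr = 2e-3,
                             target_validation_error = 0.10,
                             val_fraction = 0.25, augment = TRUE,
                             check_every = 5L) {
  if (tile_px %% 2^depth != 0L) stop("tile_px must be divisible by 2^depth")
  structure(list(tile_px = as.integer(tile_px), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), lr = lr,
                 target_validation_error = target_validation_error,
                 val_fraction = val_fraction, augment = augment,
                 check_every = as.integer(check_every)),
            class = "segmenter_params")
}

# normalize an RGB tile (0..255) into network input features (OD per channel,
# roughly unit scale)
tile_features <- function(rgb_tile) {
  rgb_to_od(rgb_tile)
}

augment_tile <- function(x, y) {
  if (stats::runif(1) < 0.5) { x <- x[rev(seq_len(nrow(y))), , , drop = FALSE]; y <- y[rev(seq_len(nrow(y))), , drop = FALSE] }
  if (stats::runif(1) < 0.5) { x <- x[, rev(seq_len(ncol(y))), , drop = FALSE]; y <- y[, rev(seq_len(ncol(y))), drop = FALSE] }
  if (stats::runif(1) < 0.5) { x <- aperm(x, c(2, 1, 3)); y <- t(y) }
  x <- x * stats::runif(1, 0.9, 1.1)       # stain-intensity jitter in OD
  list(x = x, y = y)
}

validation_pixel_error <- function(p, depth, xs, ys) {
  wrong <- 0; total <- 0
  for (i in seq_along(xs)) {
    logits <- unet_forward(p, xs[[i]], depth)$logits
    pred <- max.col(matrix(logits, length(ys[[i]]), dim(logits)[3]))
    use <- as.vector(ys[[i]]) > 0L
    wrong <- wrong + sum(pred[use] != as.vector(ys[[i]])[use])
    total <- total + sum(use)
  }
  if (total == 0L) stop("no labeled validation pixels")
  wrong / total
}

#' Train a tissue segmenter
#'
#' @param tiles list of RGB tiles (`tile_px x tile_px x 3`, 0..255).
#' @param label_masks list of integer matrices: 0 = ignore, 1..2 = class
#'   (stage A: 1 = FSR, 2 = EER; stage B: 1 = PE, 2 = ILS; stage-B masks
#'   mark non-EER pixels 0 so they do not contribute to the loss).
#' @param stage `"A"` or `"B"`.
#' @param params a [segmenter_params()].
#' @param seed RNG seed; same data + seed reproduces the model exactly.
#' @return object of class `segmenter_model`: weights, `stage`,
#'   `architecture`, `validation_error`, `converged` (FALSE, with a warning,
#'   when the epoch budget ran out above the target error).
#' @export
train_segmenter <- function(tiles, label_masks, stage = c("A", "B"),
                            params = segmenter_params(), seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(length(tiles) == length(label_masks), length(tiles) >= 2L)
  present <- sort(unique(unlist(lapply(label_masks, function(m) unique(m[m > 0L])))))
  if (length(present) < 2L)
    stop("training data contains a single class; need examples of both")
  with_seed(seed, {
    xs <- lapply(tiles, tile_features)
    ys <- label_masks
    n <- length(xs)
    n_val <- max(1L, round(params$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(tr_idx)) stop("no training tiles left after validation split")

    p <- unet_init(3L, params$base_channels, params$depth, 2L)
    st <- list(t = 0L,
               m = lapply(p, function(w) w * 0),
               v = lapply(p, function(w) w * 0))
    best_err <- Inf
    converged <- FALSE
    for (epoch in seq_len(params$epochs)) {
      for (i in sample(tr_idx)) {
        xy <- if (params$augment) augment_tile(xs[[i]], ys[[i]])
              else list(x = xs[[i]], y = ys[[i]])
        fw <- unet_forward(p, xy$x, params$depth)
        sx <- softmax_xent(fw$logits, xy$y)
        g <- unet_backward(p, fw$cache, sx$dlogits, params$depth)
        upd <- adam_step(st, p, g, params$lr)
        st <- upd$state; p <- upd$params
      }
      if (epoch %% params$check_every == 0L || epoch == params$epochs) {
        err <- validation_pixel_error(p, params$depth, xs[val_idx], ys[val_idx])
        best_err <- min(best_err, err)
        if (err < params$target_validation_error) { converged <- TRUE; break }
      }
    }
    if (!converged)
      warning(sprintf("segmenter did not reach target validation error (%.3f > %.3f)",
                      best_err, params$target_validation_error))
    structure(list(weights = p, stage = stage,
                   architecture = list(
                     family = "encoder-decoder with skip connections",
                     activation = "ReLU f(x) = max(0, x)",
                     tile_px = params$tile_px, depth = params$depth,
                     base_channels = params$base_channels),
                   params = params,
                   validation_error = if (is.finite(best_err)) best_err else NA_real_,
                   converged = converged, seed = seed),
              class = "segmenter_model")
  })
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("segmenter_model stage %s: %s, depth %d, %d base channels\n",
              x$stage, x$architecture$family, x$architecture$depth,
              x$architecture$base_channels))
  cat(sprintf("  validation pixel error: %.4f (%s)\n", x$validation_error,
              if (x$converged) "converged" else "budget exhausted"))
  invisible(x)
}

#' Predict per-pixel class scores for a full image
#'
#' Tile-and-stitch inference: tiles of the training size with 50% overlap,
#' softmax class scores averaged over overlapping tiles. Images smaller than
#' one tile are padded by edge replication and cropped back.
#'
#' @param object a `segmenter_model`.
#' @param image RGB array (0..255).
#' @param ... unused.
#' @return integer matrix of predicted classes (1 or 2) the size of `image`.
#' @export
predict.segmenter_model <- function(object, image, ...) {
  tp <- object$architecture$tile_px
  d <- dim(image)
  nr0 <- d[1]; nc0 <- d[2]
  nr <- max(tp, ceiling(nr0 / tp) * tp)
  nc <- max(tp, ceiling(nc0 / tp) * tp)
  padded <- array(0, c(nr, nc, 3))
  padded[seq_len(nr0), seq_len(nc0), ] <- image
  if (nr > nr0) padded[(nr0 + 1):nr, seq_len(nc0), ] <-
    image[rep(nr0, nr - nr0), , , drop = FALSE]
  if (nc > nc0) padded[, (nc0 + 1):nc, ] <-
    padded[, rep(nc0, nc - nc0), , drop = FALSE]
  x <- tile_features(padded)
  score <- array(0, c(nr, nc, 2L))
  weight <- matrix(0, nr, nc)
  step <- tp %/% 2L
  row_starts <- unique(pmin(seq(1L, nr, step), nr - tp + 1L))
  col_starts <- unique(pmin(seq(1L, nc, step), nc - tp + 1L))
  for (r0 in row_starts) for (c0 in col_starts) {
    rows <- r0:(r0 + tp - 1L); cols <- c0:(c0 + tp - 1L)
    logits <- unet_forward(object$weights, x[rows, cols, , drop = FALSE],
                           object$architecture$depth)$logits
    L <- matrix(logits, tp * tp, 2L)
    L <- L - apply(L, 1L, max)
    P <- exp(L); P <- P / rowSums(P)
    score[rows, cols, 1L] <- score[rows, cols, 1L] + matrix(P[, 1L], tp, tp)
    score[rows, cols, 2L] <- score[rows, cols, 2L] + matrix(P[, 2L], tp, tp)
    weight[rows, cols] <- weight[rows, cols] + 1
  }
  pred <- 1L + (score[, , 2L] > score[, , 1L])
  pred[seq_len(nr0), seq_len(nc0), drop = FALSE]
}

#' Segment epithelium-enriched regions (stage A)
#'
#' @param image RGB array (0..255).
#' @param model_A stage-A `segmenter_model`.
#' @param min_region_px connected EER regions smaller than this are removed.
#' @param fill_holes fill enclosed FSR holes inside EER regions.
#' @return logical matrix, TRUE = EER.
#' @export
segment_eer <- function(image, model_A, min_region_px = 256L, fill_holes = TRUE) {
  stopifnot(inherits(model_A, "segmenter_model"))
  if (model_A$stage != "A") stop("model_A must be a stage-A model")
  eer <- predict(model_A, image) == 2L
  if (fill_holes) {
    lab <- EBImage::bwlabel(EBImage::Image(eer))
    eer <- matrix(as.integer(EBImage::imageData(EBImage::fillHull(lab))) > 0L,
                  nrow(eer), ncol(eer))
  }
  if (min_region_px > 0L) {
    lab <- EBImage::bwlabel(EBImage::Image(eer))
    labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(eer), ncol(eer))
    if (max(labm) > 0L) {
      area <- tabulate(labm[labm > 0L], nbins = max(labm))
      drop <- which(area < min_region_px)
      if (length(drop)) eer[labm %in% drop] <- FALSE
    }
  }
  eer
}

#' Segment PE versus ILS inside the EER mask (stage B)
#'
#' Pixels outside `eer_mask` stay FSR; classification happens only inside
#' EER, the two-stage design that keeps stage B from having to learn the
#' FSR boundary as well.
#'
#' @param image RGB array (0..255).
#' @param eer_mask logical matrix from [segment_eer()] (or truth).
#' @param model_B stage-B `segmenter_model`.
#' @return a [compartment_mask()].
#' @export
segment_pe_ils <- function(image, eer_mask, model_B,
                           pixel_size_um = 0.465) {
  stopifnot(inherits(model_B, "segmenter_model"))
  if (model_B$stage != "B") stop("model_B must be a stage-B model")
  labels <- matrix(0L, nrow(eer_mask), ncol(eer_mask))
  if (!any(eer_mask)) {
    warning("empty EER mask; returning all-FSR compartment mask")
    return(compartment_mask(labels, pixel_size_um))
  }
  pred <- predict(model_B, image)          # 1 = PE, 2 = ILS
  labels[eer_mask] <- pred[eer_mask]
  compartment_mask(labels, pixel_size_um)
}

#' Oracle segmenter: the generator's true compartment mask
#'
#' Decouples detection/density tests from segmentation quality by returning
#' the ground-truth mask verbatim.
#'
#' @param truth the `truth` element of an `ihc_scene` (or the scene itself).
#' @return the true [compartment_mask()].
#' @export
oracle_segmenter <- function(truth) {
  if (inherits(truth, "ihc_scene")) truth <- truth$truth
  truth$compartment_mask
}

#' Cut scenes into labeled training tiles for a segmentation stage
#'
#' Stage A tiles are labeled 1 = FSR, 2 = EER everywhere; stage B tiles are
#' labeled 1 = PE, 2 = ILS inside EER and 0 (ignore) elsewhere, and tiles
#' with fewer than 10% labeled pixels are skipped.
#'
#' @param scenes list of `ihc_scene` objects.
#' @param stage `"A"` or `"B"`.
#' @param tile_px tile size.
#' @param max_tiles optional cap on the number of tiles returned.
#' @return list with `tiles` and `labels` (parallel lists).
#' @export
segmentation_tiles <- function(scenes, stage = c("A", "B"), tile_px = 64L,
                               max_tiles = Inf) {
  stage <- match.arg(stage)
  tiles <- list(); labels <- list()
  for (sc in scenes) {
    lab <- sc$truth$compartment_mask$labels
    d <- dim(sc$image)
    for (r0 in seq(1L, d[1] - tile_px + 1L, tile_px)) {
      for (c0 in seq(1L, d[2] - tile_px + 1L, tile_px)) {
        if (length(tiles) >= max_tiles) break
        rows <- r0:(r0 + tile_px - 1L); cols <- c0:(c0 + tile_px - 1L)
        sub <- lab[rows, cols]
        y <- if (stage == "A") 1L + (sub > 0L) else {
          yy <- matrix(0L, tile_px, tile_px)
          yy[sub == 1L] <- 1L
          yy[sub == 2L] <- 2L
          yy
        }
        if (stage == "B" && mean(y > 0L) < 0.10) next
        tiles[[length(tiles) + 1L]] <- sc$image[rows, cols, , drop = FALSE]
        labels[[length(labels) + 1L]] <- y
      }
    }
  }
  list(tiles = tiles, labels = labels)
}
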