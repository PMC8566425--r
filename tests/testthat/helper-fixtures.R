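# fixtures built in code: single-stain disk images and small scenes

# render a white image with one uniform chromogen disk (and optionally a
# hematoxylin nucleus disk at the same center)
disk_image <- function(size_px = 256, diameter_um = 20, conc = 1.2,
                       chromogen = "purple", pixel_size_um = 0.465,
                       nucleus = FALSE, nucleus_conc = 1.3,
                       nucleus_diameter_um = 8,
                       center = c(size_px / 2, size_px / 2)) {
  vecs <- default_stain_vectors()
  field <- matrix(0, size_px, size_px)
  field <- mammilieu:::stamp_disk(field, center[1], center[2],
                                  diameter_um / 2 / pixel_size_um, conc)
  od <- array(0, c(size_px, size_px, 3))
  for (k in 1:3) od[, , k] <- field * vecs[[chromogen]][k]
  if (nucleus) {
    nuc <- matrix(0, size_px, size_px)
    nuc <- mammilieu:::stamp_disk(nuc, center[1], center[2],
                                  nucleus_diameter_um / 2 / pixel_size_um,
                                  nucleus_conc)
    for (k in 1:3) od[, , k] <- od[, , k] + nuc * vecs$hematoxylin[k]
  }
  round(od_to_rgb(od))
}

# detect candidates in a single marker channel of an RGB image
detect_in_channel <- function(image, marker = "CD3", panel = "triple",
                              params = detection_params(),
                              pixel_size_um = 0.465) {
  od <- rgb_to_od(image)
  p <- panel_passes(panel)[[marker]]
  stack <- deconvolve(od, p$pass)
  inten <- channel_to_intensity(stack$channels[[p$marker_channel]],
                                params$intensity_scale)
  detect_candidates(inten, params, pixel_size_um)
}

# small standard scene for reuse across tests
small_scene <- function(seed = 1, densities = NULL, ...) {
  if (is.null(densities))
    densities <- data.frame(class = c("T", "Mac"),
                            compartment = c("ILS", "PE"),
                            density = c(260, 310))
  generate_scene(scene_spec(image_size_px = c(512, 512), eer_fraction = 0.8,
                            pe_fraction_of_eer = 0.3,
                            planted_density = densities, seed = seed, ...))
}
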