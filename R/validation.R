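# Planted-density recovery experiments: generate scenes at a stated density,
# run oracle segmentation + detection + quantification, and compare the
# pooled recovered density against the planted value. This is the package's
# main validation surface, since cohort-level human results cannot be
# regenerated from synthetic data.

#' Recover planted densities over a required EER area
#'
#' Generates scenes (seeded) until the accumulated EER area reaches
#' `total_eer_mm2`, detects and classifies cells on each scene, assigns
#' compartments from the oracle (ground-truth) mask, and pools counts and
#' areas across scenes before dividing.
#'
#' @param planted_density data.frame `class`, `compartment`, `density`
#'   (cells/mm^2) passed to [scene_spec()].
#' @param total_eer_mm2 minimum total EER area to accumulate.
#' @param panel staining panel.
#' @param image_size_px per-scene size; larger scenes amortize fixed costs.
#' @param eer_fraction,pe_fraction_of_eer scene geometry.
#' @param speckle_fraction nucleus-free CD68 speckle load (fraction of the
#'   CD68-class density) that detection must exclude.
#' @param params a [detection_params()].
#' @param seed integer seed; scene s uses a child seed derived from it.
#' @return data.frame per class x compartment (PE, ILS): `planted`,
#'   `recovered` (pooled density), `count`, `area_mm2`, `n_scenes`.
#' @export
density_recovery_experiment <- function(planted_density,
                                        total_eer_mm2 = 10,
                                        panel = "triple",
                                        image_size_px = c(3072, 3072),
                                        eer_fraction = 0.9,
                                        pe_fraction_of_eer = 0.3,
                                        speckle_fraction = 0,
                                        params = detection_params(),
                                        seed = 1L) {
  records <- list()
  eer_done <- 0
  s <- 0L
  while (eer_done < total_eer_mm2) {
    s <- s + 1L
    sp <- scene_spec(image_size_px = image_size_px,
                     eer_fraction = eer_fraction,
                     pe_fraction_of_eer = pe_fraction_of_eer,
                     panel = panel, planted_density = planted_density,
                     speckle_fraction = speckle_fraction,
                     seed = child_seed(seed, s))
    scene <- generate_scene(sp)
    mask <- oracle_segmenter(scene)
    cells <- detect_cells(scene$image, panel, params,
                          pixel_size_um = sp$pixel_size_um)
    cells <- assign_compartment(cells, mask)
    records[[s]] <- compute_density(cells, mask, donor_id = "experiment",
                                    classes = unique(planted_density$class))
    eer_done <- eer_done + mask$area_mm2[["PE"]] + mask$area_mm2[["ILS"]]
  }
  pooled <- pool_density(do.call(rbind, records))
  out <- merge(planted_density, pooled,
               by.x = c("class", "compartment"),
               by.y = c("cell_class", "compartment"))
  data.frame(class = out$class, compartment = out$compartment,
             planted = out$density.x, recovered = out$density.y,
             count = out$count, area_mm2 = out$area_mm2, n_scenes = s)
}
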