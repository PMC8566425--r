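# detection thresholds, nucleus association, classification, compartments

test_that("stated size and intensity thresholds apply directly", {
  params <- detection_params()
  # dark disk of 20 um at concentration 1.2 (intensity ~16): retained
  img <- disk_image(diameter_um = 20, conc = 1.2)
  det <- detect_in_channel(img, "CD3", params = params)
  expect_equal(nrow(det$objects), 1L)
  # 10 um disk: removed by the < 15 um size filter
  img <- disk_image(diameter_um = 10, conc = 1.2)
  det <- detect_in_channel(img, "CD3", params = params)
  expect_equal(nrow(det$objects), 0L)
  # 20 um disk with mean intensity above 50 (conc 0.55 -> ~72): removed by
  # the positivity filter even though it binarizes
  img <- disk_image(diameter_um = 20, conc = 0.55)
  det <- detect_in_channel(img, "CD3", params = params)
  expect_equal(nrow(det$objects), 0L)
})

test_that("size filter is sharp at the 15 um boundary", {
  params <- detection_params(mean_filter_radius_um = 0.4)
  # construct objects straddling 15 um equivalent diameter; the convention
  # is exclusive: < 15 removed, >= 15 kept
  for (d in c(12, 14)) {
    det <- detect_in_channel(disk_image(diameter_um = d, conc = 1.2),
                             params = params)
    expect_equal(nrow(det$objects), 0L)
  }
  for (d in c(16.5, 18)) {
    det <- detect_in_channel(disk_image(diameter_um = d, conc = 1.2),
                             params = params)
    expect_equal(nrow(det$objects), 1L)
    expect_gte(det$objects$equivalent_diameter_um, 15)
  }
})

test_that("positivity filter is sharp at mean intensity 50", {
  params <- detection_params(mean_filter_radius_um = 0.4)
  # 255 * 10^(-c) = 50 at c = 0.70757; bracket it
  for (conc in c(0.65, 0.69)) {    # intensity 57..52 >= 50: not positive
    det <- detect_in_channel(disk_image(diameter_um = 24, conc = conc),
                             params = params)
    expect_equal(nrow(det$objects), 0L)
  }
  for (conc in c(0.76, 0.9)) {     # intensity < 50: positive
    det <- detect_in_channel(disk_image(diameter_um = 24, conc = conc),
                             params = params)
    expect_equal(nrow(det$objects), 1L)
    expect_lt(det$objects$mean_intensity, 50)
  }
})

test_that("touching blobs larger than the 33 um scale are watershed-split", {
  params <- detection_params()
  vecs <- default_stain_vectors()
  field <- matrix(0, 256, 256)
  # two 22 um disks with centers 24 um apart: merged area ~ 40 um object
  r_px <- 22 / 2 / 0.465; sep_px <- 24 / 0.465
  field <- mammilieu:::stamp_disk(field, 128, 128 - sep_px / 2, r_px, 1.2)
  field <- mammilieu:::stamp_disk(field, 128, 128 + sep_px / 2, r_px, 1.2)
  od <- array(0, c(256, 256, 3))
  for (k in 1:3) od[, , k] <- field * vecs$purple[k]
  det <- detect_in_channel(round(od_to_rgb(od)), params = params)
  expect_equal(nrow(det$objects), 2L)
})

test_that("pixel size is required for metric thresholds", {
  img <- disk_image()
  expect_error(detect_in_channel(img, pixel_size_um = NULL),
               "pixel_size_um")
})

test_that("CD68 objects without nuclei are dropped, with nuclei kept", {
  params <- detection_params()
  # nucleated CD68 cell
  img <- disk_image(diameter_um = 20, conc = 1.2, chromogen = "yellow",
                    nucleus = TRUE)
  cells <- detect_cells(img, "triple", params)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$class, "Mac")
  # nucleus-free speckle of the same size: excluded
  img <- disk_image(diameter_um = 20, conc = 1.2, chromogen = "yellow",
                    nucleus = FALSE)
  cells <- detect_cells(img, "triple", params)
  expect_equal(nrow(cells), 0L)
})

test_that("speckle exclusion recovers the nucleated count on scenes", {
  pd <- data.frame(class = "Mac", compartment = "ILS", density = 150)
  sc <- generate_scene(scene_spec(image_size_px = c(1024, 1024),
                                  eer_fraction = 0.85,
                                  pe_fraction_of_eer = 0.2,
                                  planted_density = pd,
                                  speckle_fraction = 0.2, seed = 21))
  cells <- detect_cells(sc$image, "triple")
  truth_n <- sum(sc$truth$cells$class == "Mac")
  expect_gt(nrow(sc$truth$speckles), 0)
  detected <- sum(cells$class == "Mac")
  expect_lt(abs(detected - truth_n) / truth_n, 0.05)
})

test_that("classification follows the exclusive marker rules", {
  params <- detection_params()
  # CD3 only -> T
  cells <- detect_cells(disk_image(diameter_um = 20, chromogen = "purple"),
                        "triple", params)
  expect_equal(cells$class, "T")
  expect_true(cells$CD3_pos && !cells$CD20_pos && !cells$CD68_pos)
  # CD20 only -> B
  cells <- detect_cells(disk_image(diameter_um = 20, chromogen = "teal"),
                        "triple", params)
  expect_equal(cells$class, "B")
  # CD3 + CD20 collision at the same location -> unclassified
  vecs <- default_stain_vectors()
  field <- matrix(0, 256, 256)
  field <- mammilieu:::stamp_disk(field, 128, 128, 20 / 2 / 0.465, 1.2)
  od <- array(0, c(256, 256, 3))
  for (k in 1:3) od[, , k] <- field * (1.2 * vecs$purple[k] + 1.2 * vecs$teal[k]) / 1.2
  cells <- detect_cells(round(od_to_rgb(od)), "triple", params)
  expect_true(all(cells$class == "unclassified"))
})

test_that("double panel: CD163+ is M2 regardless of CD68", {
  params <- detection_params()
  # teal only (CD163+/CD68-) -> M2
  img <- disk_image(diameter_um = 20, chromogen = "teal", nucleus = TRUE)
  cells <- detect_cells(img, "double", params)
  expect_equal(cells$class, "M2")
  # yellow only with nucleus (CD68+/CD163-) -> M1
  img <- disk_image(diameter_um = 20, chromogen = "yellow", nucleus = TRUE)
  cells <- detect_cells(img, "double", params)
  expect_equal(cells$class, "M1")
  # double positive: teal + yellow mixture -> M2
  vecs <- default_stain_vectors()
  field <- matrix(0, 256, 256)
  field <- mammilieu:::stamp_disk(field, 128, 128, 20 / 2 / 0.465, 1)
  nuc <- matrix(0, 256, 256)
  nuc <- mammilieu:::stamp_disk(nuc, 128, 128, 8 / 2 / 0.465, 1.3)
  od <- array(0, c(256, 256, 3))
  for (k in 1:3) od[, , k] <- field * (1.2 * vecs$teal[k] + 1.2 * vecs$yellow[k]) +
    nuc * vecs$hematoxylin[k]
  cells <- detect_cells(round(od_to_rgb(od)), "double", params)
  expect_equal(cells$class, "M2")
  expect_true(cells$CD68_pos && cells$CD163_pos)
})

test_that("compartment assignment uses the centroid label and partitions counts", {
  sc <- small_scene(seed = 22)
  cells <- detect_cells(sc$image, "triple")
  cells <- assign_compartment(cells, sc$truth$compartment_mask)
  lab <- sc$truth$compartment_mask$labels
  at <- lab[cbind(round(cells$row_px), round(cells$col_px))]
  expect_equal(cells$compartment,
               c("outside", "PE", "ILS")[at + 1L])
  # partition: PE + ILS counts equal total EER counts per class
  for (cl in unique(cells$class)) {
    n_pe <- sum(cells$class == cl & cells$compartment == "PE")
    n_ils <- sum(cells$class == cl & cells$compartment == "ILS")
    n_eer <- sum(cells$class == cl & cells$compartment != "outside")
    expect_equal(n_pe + n_ils, n_eer)
  }
  # centroid outside the image errors
  bad <- cells; bad$row_px[1] <- 1e6
  expect_error(assign_compartment(bad, sc$truth$compartment_mask), "outside image")
})

test_that("detection is invariant to whole-pixel translation", {
  img1 <- disk_image(size_px = 300, diameter_um = 20, center = c(120, 120))
  img2 <- disk_image(size_px = 300, diameter_um = 20, center = c(157, 183))
  d1 <- detect_in_channel(img1)
  d2 <- detect_in_channel(img2)
  expect_equal(nrow(d1$objects), 1L)
  expect_equal(d1$objects$area_px, d2$objects$area_px)
  expect_equal(d1$objects$mean_intensity, d2$objects$mean_intensity,
               tolerance = 1e-6)
  expect_equal(d2$objects$row_px - d1$objects$row_px, 37, tolerance = 0.1)
})

test_that("detection recall and precision reach 0.95 on paper-scale scenes", {
  pd <- data.frame(class = c("T", "B", "Mac", "Mac"),
                   compartment = c("ILS", "ILS", "ILS", "PE"),
                   density = c(259, 75, 101, 313))
  sc <- generate_scene(scene_spec(image_size_px = c(1024, 1024),
                                  eer_fraction = 0.85,
                                  pe_fraction_of_eer = 0.25,
                                  planted_density = pd,
                                  background_od_noise = 0, seed = 23))
  cells <- detect_cells(sc$image, "triple")
  tr <- sc$truth$cells
  for (cl in c("T", "B", "Mac")) {
    t2 <- tr[tr$class == cl, ]
    d2 <- cells[cells$class == cl, ]
    if (nrow(t2) < 10) next
    matched <- vapply(seq_len(nrow(t2)), function(i) {
      dd <- sqrt((d2$row_px - t2$row_px[i])^2 + (d2$col_px - t2$col_px[i])^2)
      any(dd < 15)
    }, logical(1))
    recall <- mean(matched)
    precision <- if (nrow(d2)) {
      hit <- vapply(seq_len(nrow(d2)), function(i) {
        dd <- sqrt((t2$row_px - d2$row_px[i])^2 + (t2$col_px - d2$col_px[i])^2)
        any(dd < 15)
      }, logical(1))
      mean(hit)
    } else 0
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})
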