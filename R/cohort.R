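# Synthetic donor cohorts with age/risk structure.
#
# Per-donor expected densities follow a linear age model (the analysis layer
# fits simple linear regressions, so the generator's truth is linear in age),
# with normal between-donor scatter and truncation at zero. High-risk (HR)
# donors can have steeper decline than average-risk (AR) donors.

#' Default linear age model for planted densities
#'
#' Intercepts and slopes (cells/mm^2 per year) are anchored to published
#' compartment means for breast tissue: intralobular-stromal (ILS) T cells
#' around 259 cells/mm^2, peri-epithelial (PE) T cells declining from ~849
#' (younger women) to ~477 (older), ILS B cells declining from ~75 to ~9,
#' PE B cells ~11, PE macrophages ~313 and ILS macrophages ~101 with no age
#' trend, and an M2-skewed intralobular macrophage population in the
#' double-stain panel. HR slopes are steeper for T and B cells.
#'
#' @return data.frame: `cell_class`, `compartment`, `intercept`, `slope_ar`,
#'   `slope_hr`, `sd` (between-donor).
#' @export
default_age_model <- function() {
  data.frame(
    cell_class  = c("T",   "T",   "B",   "B",   "Mac", "Mac", "M1",  "M1",  "M2",  "M2"),
    compartment = c("PE",  "ILS", "PE",  "ILS", "PE",  "ILS", "PE",  "ILS", "PE",  "ILS"),
    intercept   = c(1232,  406,   16,    143,   290,   101,   150,   140,   180,   600),
    slope_ar    = c(-11.6, -3.0,  -0.1,  -2.06,  0.5,   0.0,   0.0,   0.0,   0.0,   0.0),
    slope_hr    = c(-17.4, -4.5,  -0.15, -3.1,  -0.5,   0.0,   0.0,   0.0,   0.0,   0.0),
    sd          = c(250,   123,   12,    60,    152,   54,    60,    60,    70,    150))
}

#' Cohort specification
#'
#' @param n_donors total donors (default 102: 67 average-risk + 36 high-risk
#'   minus overlap is not modeled; defaults below give 67 + 35? no: 67 + 36
#'   must equal `n_donors`, enforced).
#' @param age_range_y min/max donor age in years.
#' @param n_ar,n_hr donors per genetic risk group; must sum to `n_donors`.
#' @param density_age_model see [default_age_model()].
#' @param eer_area_mm2 total EER area per donor (free design choice; the
#'   published work normalizes by per-donor EER area rather than fixing it).
#' @param pe_fraction_of_eer PE share of EER area per donor.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 103L, age_range_y = c(24, 74),
                        n_ar = 67L, n_hr = 36L,
                        density_age_model = default_age_model(),
                        eer_area_mm2 = 10, pe_fraction_of_eer = 0.3,
                        seed = 1L) {
  n_donors <- as.integer(n_donors); n_ar <- as.integer(n_ar); n_hr <- as.integer(n_hr)
  if (n_ar + n_hr != n_donors) stop("n_ar + n_hr must equal n_donors")
  if (age_range_y[1] >= age_range_y[2]) stop("invalid age range")
  stopifnot(all(c("cell_class", "compartment", "intercept", "slope_ar",
                  "slope_hr", "sd") %in% names(density_age_model)))
  structure(list(n_donors = n_donors, age_range_y = age_range_y,
                 n_ar = n_ar, n_hr = n_hr,
                 density_age_model = density_age_model,
                 eer_area_mm2 = eer_area_mm2,
                 pe_fraction_of_eer = pe_fraction_of_eer,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

bmi_class <- function(bmi) {
  ifelse(bmi < 18.5, "underweight",
  ifelse(bmi < 25, "normal", ifelse(bmi < 30, "overweight", "obese")))
}

#' Generate a synthetic donor cohort
#'
#' Draws donor metadata (age, risk, BMI, parity, menopause, tissue type,
#' tumor receptor status) and per-donor true densities from the linear age
#' model with truncation at zero (truncations are counted, not errors).
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort`: `donors` (one row per donor),
#'   `densities` (long: donor_id, cell_class, compartment in PE/ILS/EER_total,
#'   density), `n_truncated`, and `spec`. EER_total densities pool the two
#'   compartments by area.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_donors
    risk <- sample(c(rep("AR", spec$n_ar), rep("HR", spec$n_hr)))
    age <- stats::runif(n, spec$age_range_y[1], spec$age_range_y[2])
    bmi <- pmin(pmax(stats::rnorm(n, 27, 4.5), 18.6), 45)
    parity <- sample(c("0", "1", "2", "3", "4+"), n, TRUE,
                     prob = c(21, 17, 31, 20, 13))
    menopause <- ifelse(age >= 51, "post", ifelse(age < 45, "pre",
                        sample(c("pre", "post"), n, TRUE)))
    tissue <- sample(c("C", "P", "PM"), n, TRUE, prob = c(77, 15, 11))
    receptor <- ifelse(tissue == "PM", "none",
                       sample(c("ER+", "HER2+", "TNBC"), n, TRUE,
                              prob = c(56, 11, 15)))
    donors <- data.frame(
      donor_id = sprintf("D%03d", seq_len(n)), age_y = age, risk = risk,
      bmi = bmi, bmi_class = bmi_class(bmi), parity = parity,
      menopause = menopause, tissue_type = tissue, tumor_receptor = receptor)

    am <- spec$density_age_model
    n_trunc <- 0L
    dens <- list()
    a_pe <- spec$eer_area_mm2 * spec$pe_fraction_of_eer
    a_ils <- spec$eer_area_mm2 - a_pe
    for (i in seq_len(nrow(am))) {
      slope <- ifelse(risk == "HR", am$slope_hr[i], am$slope_ar[i])
      mu <- am$intercept[i] + slope * age
      d <- mu + stats::rnorm(n, 0, am$sd[i])
      n_trunc <- n_trunc + sum(d < 0)
      d <- pmax(d, 0)
      dens[[i]] <- data.frame(donor_id = donors$donor_id,
                              cell_class = am$cell_class[i],
                              compartment = am$compartment[i], density = d)
    }
    dens <- do.call(rbind, dens)
    # area-weighted EER_total per donor x class (a compartment absent from
    # the age model contributes zero)
    pe <- dens[dens$compartment == "PE", c("donor_id", "cell_class", "density")]
    ils <- dens[dens$compartment == "ILS", c("donor_id", "cell_class", "density")]
    wide <- merge(pe, ils, by = c("donor_id", "cell_class"), all = TRUE,
                  suffixes = c("_pe", "_ils"))
    wide$density_pe[is.na(wide$density_pe)] <- 0
    wide$density_ils[is.na(wide$density_ils)] <- 0
    tot <- data.frame(donor_id = wide$donor_id, cell_class = wide$cell_class,
                      compartment = "EER_total",
                      density = (wide$density_pe * a_pe +
                                 wide$density_ils * a_ils) / (a_pe + a_ils))
    densities <- rbind(dens, tot)
    rownames(densities) <- NULL
    structure(list(donors = donors, densities = densities,
                   n_truncated = n_trunc, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d donors (%d AR / %d HR), ages %.0f-%.0f\n",
              nrow(x$donors), sum(x$donors$risk == "AR"),
              sum(x$donors$risk == "HR"), min(x$donors$age_y),
              max(x$donors$age_y)))
  invisible(x)
}

#' Scene specifications for each donor of a cohort
#'
#' Turns each donor's true densities into a [scene_spec()] so the image
#' pipeline can be run per donor. Desk-scale image sizes keep full-cohort
#' runs tractable.
#'
#' @param cohort a [generate_cohort()] result.
#' @param classes cell classes to plant (default triple-panel classes).
#' @param image_size_px per-donor scene size.
#' @param eer_fraction EER fraction of each scene.
#' @param ... further arguments passed to [scene_spec()].
#' @return named list of `scene_spec`, one per donor.
#' @export
cohort_scene_specs <- function(cohort, classes = c("T", "B", "Mac"),
                               image_size_px = c(512, 512),
                               eer_fraction = 0.7, ...) {
  stopifnot(inherits(cohort, "cohort"))
  specs <- list()
  for (i in seq_len(nrow(cohort$donors))) {
    id <- cohort$donors$donor_id[i]
    dd <- cohort$densities
    pd <- dd[dd$donor_id == id & dd$cell_class %in% classes &
             dd$compartment %in% c("PE", "ILS"),
             c("cell_class", "compartment", "density")]
    names(pd)[1] <- "class"
    specs[[id]] <- scene_spec(
      image_size_px = image_size_px, eer_fraction = eer_fraction,
      pe_fraction_of_eer = cohort$spec$pe_fraction_of_eer,
      planted_density = pd,
      seed = child_seed(cohort$spec$seed, i), ...)
  }
  specs
}
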