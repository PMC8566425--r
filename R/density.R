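# Compartment-specific density records: cells per mm^2 of PE, ILS and total
# EER, normalizing counts by compartment area so donors with different EER
# extents are comparable.

#' Compute density records for one image or donor
#'
#' Produces one record per cell class and compartment (`PE`, `ILS`,
#' `EER_total`), with `density = count / area_mm2` exactly. `EER_total`
#' pools counts and areas (never averages the two densities). Unclassified
#' cells and cells outside EER are excluded.
#'
#' @param cells data.frame with `class` and `compartment` columns
#'   (see [assign_compartment()]).
#' @param mask a [compartment_mask()] carrying pixel size and areas.
#' @param donor_id identifier copied into the records.
#' @param classes classes to report; defaults to those present (excluding
#'   `"unclassified"`).
#' @return data.frame: `donor_id`, `cell_class`, `compartment`, `count`,
#'   `area_mm2`, `density`.
#' @export
compute_density <- function(cells, mask, donor_id = "donor1", classes = NULL) {
  stopifnot(inherits(mask, "compartment_mask"))
  if (is.null(classes)) {
    classes <- setdiff(unique(cells$class), "unclassified")
    if (!length(classes)) classes <- character(0)
  }
  area <- c(PE = unname(mask$area_mm2[["PE"]]),
            ILS = unname(mask$area_mm2[["ILS"]]))
  out <- list()
  for (cl in classes) {
    n_pe <- sum(cells$class == cl & cells$compartment == "PE")
    n_ils <- sum(cells$class == cl & cells$compartment == "ILS")
    counts <- c(PE = n_pe, ILS = n_ils, EER_total = n_pe + n_ils)
    areas <- c(PE = area[["PE"]], ILS = area[["ILS"]],
               EER_total = area[["PE"]] + area[["ILS"]])
    for (comp in names(counts)) {
      if (areas[[comp]] <= 0) {
        if (counts[[comp]] > 0)
          stop("compartment ", comp, " has zero area but nonzero count")
        warning("compartment ", comp, " has zero area; record omitted")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        donor_id = donor_id, cell_class = cl, compartment = comp,
        count = counts[[comp]], area_mm2 = areas[[comp]],
        density = counts[[comp]] / areas[[comp]])
    }
  }
  if (!length(out))
    return(data.frame(donor_id = character(0), cell_class = character(0),
                      compartment = character(0), count = integer(0),
                      area_mm2 = numeric(0), density = numeric(0)))
  do.call(rbind, out)
}

#' Pool density records across tiles of one donor
#'
#' Counts and areas are summed before dividing, matching the count/area
#' definition of density (robust to small tiles).
#'
#' @param records data.frame as returned by [compute_density()] for several
#'   tiles of the same donor.
#' @return pooled data.frame, one row per donor x class x compartment.
#' @export
pool_density <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- interaction(records$donor_id, records$cell_class,
                     records$compartment, drop = TRUE)
  pooled <- lapply(split(records, key), function(grp) {
    data.frame(donor_id = grp$donor_id[1], cell_class = grp$cell_class[1],
               compartment = grp$compartment[1],
               count = sum(grp$count), area_mm2 = sum(grp$area_mm2),
               density = sum(grp$count) / sum(grp$area_mm2))
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}
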