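# Cohort-level statistics over density tables: simple linear age
# regressions with Pearson correlation, one-way ANOVA with Tukey HSD
# post-hoc, paired (PE vs ILS) and unpaired (e.g. AR vs HR) t-tests, and
# Tukey boxplot summaries. All tests are two-sided at alpha = 0.05.

#' Significance symbol for a p-value
#'
#' `****` p <= 1e-4, `***` p <= 1e-3, `**` p <= 0.01, `*` p <= 0.05,
#' otherwise `NS`.
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
significance_symbol <- function(p) {
  ifelse(p <= 1e-4, "****",
  ifelse(p <= 1e-3, "***",
  ifelse(p <= 0.01, "**",
  ifelse(p <= 0.05, "*", "NS"))))
}

new_stat_result <- function(test, statistic, p_value, ...) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value,
                   symbol = significance_symbol(p_value)), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n",
              x$test, x$statistic, x$p_value, x$symbol))
  if (!is.null(x$r)) cat(sprintf("  r = %.3f\n", x$r))
  if (!is.null(x$slope)) cat(sprintf("  slope = %.4g (se %.3g) per year\n",
                                     x$slope, x$slope_se))
  if (!is.null(x$tukey)) { cat("  Tukey HSD adjusted p:\n"); print(x$tukey) }
  invisible(x)
}

# join donor metadata onto the long density table and filter
density_subset <- function(cohort_densities, donors, cell_class, compartment,
                           filter = NULL) {
  d <- cohort_densities[cohort_densities$cell_class == cell_class &
                        cohort_densities$compartment == compartment, ,
                        drop = FALSE]
  d <- merge(d, donors, by = "donor_id")
  if (!is.null(filter)) d <- d[filter(d), , drop = FALSE]
  d
}

#' Simple linear regression of density on age
#'
#' Ordinary least squares with two-sided slope p-value and Pearson r.
#'
#' @param cohort a `cohort` (or list with `donors` and `densities`).
#' @param cell_class cell class to analyze.
#' @param compartment `"PE"`, `"ILS"` or `"EER_total"`.
#' @param filter optional predicate over the merged donor rows, e.g.
#'   `function(d) d$risk == "HR"`.
#' @return `stat_result` with `slope`, `slope_se`, `r`, `n`.
#' @export
age_regression <- function(cohort, cell_class, compartment = "EER_total",
                           filter = NULL) {
  d <- density_subset(cohort$densities, cohort$donors, cell_class,
                      compartment, filter)
  if (nrow(d) < 3L) stop("need at least 3 donors")
  if (stats::var(d$age_y) == 0) stop("zero age variance")
  if (stats::var(d$density) == 0)
    return(new_stat_result("simple linear regression (density ~ age)",
                           statistic = 0, p_value = 1, slope = 0,
                           slope_se = 0, r = NA_real_, n = nrow(d),
                           cell_class = cell_class, compartment = compartment))
  fit <- stats::lm(density ~ age_y, data = d)
  sm <- summary(fit)
  new_stat_result("simple linear regression (density ~ age)",
                  statistic = sm$coefficients[2, 3],
                  p_value = sm$coefficients[2, 4],
                  slope = unname(stats::coef(fit)[2]),
                  slope_se = sm$coefficients[2, 2],
                  r = stats::cor(d$age_y, d$density),
                  n = nrow(d),
                  cell_class = cell_class, compartment = compartment)
}

#' Age-bin labels used for group comparisons
#'
#' Bins 20-40, 41-50, 51-59, >= 60 years.
#'
#' @param age_y numeric ages.
#' @return factor of bins.
#' @export
age_bins <- function(age_y) {
  cut(age_y, breaks = c(20, 40.5, 50.5, 59.5, Inf),
      labels = c("20-40y", "41-50y", "51-59y", ">=60y"), right = FALSE)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Groups with fewer than 2 members are excluded with a warning.
#'
#' @param cohort a `cohort`.
#' @param grouping either a column of the donor table (e.g. `"bmi_class"`,
#'   `"tissue_type"`, `"parity"`, `"risk"`) or `"age_bin"`.
#' @param cell_class,compartment as in [age_regression()].
#' @param filter optional predicate over merged donor rows.
#' @return `stat_result` with `F`, `p_value` and `tukey` (named vector of
#'   adjusted pairwise p-values).
#' @export
group_anova <- function(cohort, grouping, cell_class,
                        compartment = "EER_total", filter = NULL) {
  d <- density_subset(cohort$densities, cohort$donors, cell_class,
                      compartment, filter)
  g <- if (grouping == "age_bin") age_bins(d$age_y) else factor(d[[grouping]])
  keep_levels <- names(which(table(g) >= 2L))
  if (length(keep_levels) < nlevels(droplevels(g)))
    warning("excluding groups with < 2 members: ",
            paste(setdiff(levels(droplevels(g)), keep_levels), collapse = ", "))
  sel <- g %in% keep_levels
  d <- d[sel, , drop = FALSE]; g <- droplevels(g[sel])
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 members")
  fit <- stats::aov(d$density ~ g)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  new_stat_result("one-way ANOVA", statistic = sm[["F value"]][1],
                  p_value = sm[["Pr(>F)"]][1],
                  tukey = stats::setNames(tk[, "p adj"], rownames(tk)),
                  group_n = table(g), grouping = grouping,
                  cell_class = cell_class, compartment = compartment)
}

#' Paired comparison of PE versus ILS densities within donors
#'
#' Two-sided paired t-test on per-donor (PE - ILS) differences.
#'
#' @param cohort a `cohort`.
#' @param cell_class cell class.
#' @param filter optional predicate over merged donor rows.
#' @return `stat_result` with `mean_difference` (PE - ILS) and `n` pairs.
#' @export
paired_compare <- function(cohort, cell_class, filter = NULL) {
  pe <- density_subset(cohort$densities, cohort$donors, cell_class, "PE", filter)
  ils <- density_subset(cohort$densities, cohort$donors, cell_class, "ILS", filter)
  m <- merge(pe[, c("donor_id", "density")], ils[, c("donor_id", "density")],
             by = "donor_id", suffixes = c("_pe", "_ils"))
  if (nrow(m) < 3L) stop("need at least 3 complete PE/ILS pairs")
  diffs <- m$density_pe - m$density_ils
  if (stats::sd(diffs) == 0) {
    # identical compartments in every pair: exactly null
    stat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    return(new_stat_result("paired t-test (PE vs ILS)", statistic = stat,
                           p_value = if (stat == 0) 1 else 0,
                           mean_difference = mean(diffs), n = nrow(m),
                           cell_class = cell_class))
  }
  tt <- stats::t.test(m$density_pe, m$density_ils, paired = TRUE)
  new_stat_result("paired t-test (PE vs ILS)", statistic = unname(tt$statistic),
                  p_value = tt$p.value,
                  mean_difference = unname(tt$estimate), n = nrow(m),
                  cell_class = cell_class)
}

#' Unpaired two-group comparison of densities
#'
#' Classic equal-variance two-sided t-test by default (Welch behind a flag).
#'
#' @param cohort a `cohort`.
#' @param grouping donor-table column with exactly 2 levels after filtering
#'   (e.g. `"risk"` for AR vs HR, `"menopause"`).
#' @param cell_class,compartment as in [age_regression()].
#' @param welch use Welch's unequal-variance test.
#' @param filter optional predicate over merged donor rows.
#' @return `stat_result` with group means and ns.
#' @export
unpaired_compare <- function(cohort, grouping, cell_class,
                             compartment = "EER_total", welch = FALSE,
                             filter = NULL) {
  d <- density_subset(cohort$densities, cohort$donors, cell_class,
                      compartment, filter)
  g <- factor(d[[grouping]])
  g <- droplevels(g)
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels, got ",
                             nlevels(g))
  tt <- stats::t.test(d$density ~ g, var.equal = !welch)
  new_stat_result(sprintf("unpaired t-test (%s)", grouping),
                  statistic = unname(tt$statistic), p_value = tt$p.value,
                  group_means = stats::setNames(tapply(d$density, g, mean),
                                                levels(g)),
                  group_n = table(g), cell_class = cell_class,
                  compartment = compartment)
}

#' Tukey boxplot summary
#'
#' Quartiles by linear interpolation (type 7); whiskers at the most extreme
#' data points within 1.5 IQR of the quartiles; points beyond are outliers.
#'
#' @param values numeric vector.
#' @return list: `quartiles` (q1, median, q3), `whiskers` (low, high),
#'   `outliers`.
#' @export
tukey_boxplot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(quartiles = stats::setNames(q, c("q1", "median", "q3")),
       whiskers = c(low = min(values[inside]), high = max(values[inside])),
       outliers = sort(values[!inside]))
}
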