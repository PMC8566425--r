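# statistics layer: regressions, ANOVA + Tukey, paired/unpaired tests,
# Tukey boxplot summaries, significance symbols

mini_cohort <- function(densities_by_donor, ages = NULL, risk = NULL) {
  n <- length(unique(densities_by_donor$donor_id))
  ids <- sort(unique(densities_by_donor$donor_id))
  donors <- data.frame(donor_id = ids,
                       age_y = if (is.null(ages)) seq(30, 70, length.out = n)
                               else ages,
                       risk = if (is.null(risk)) rep(c("AR", "HR"), length.out = n)
                              else risk)
  list(donors = donors, densities = densities_by_donor)
}

test_that("exactly linear density gives r = 1 and a floor p-value", {
  ids <- sprintf("D%02d", 1:20)
  ages <- seq(25, 70, length.out = 20)
  dens <- data.frame(donor_id = ids, cell_class = "T",
                     compartment = "EER_total", density = 1000 - 5 * ages)
  co <- mini_cohort(dens, ages)
  # exact linearity makes lm warn about a perfect fit; that is the point here
  r <- suppressWarnings(age_regression(co, "T", "EER_total"))
  expect_equal(r$r, -1)
  expect_equal(r$slope, -5)
  expect_lt(r$p_value, 1e-12)
  expect_error(age_regression(mini_cohort(dens, ages = rep(50, 20)),
                              "T", "EER_total"), "age variance")
})

test_that("estimated slopes cover the generated truth at the nominal rate", {
  covered <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(700 + s)
    ages <- runif(102, 24, 74)
    dens <- 800 - 6 * ages + rnorm(102, 0, 150)
    d <- data.frame(donor_id = sprintf("D%03d", 1:102), cell_class = "T",
                    compartment = "EER_total", density = dens)
    r <- age_regression(mini_cohort(d, ages), "T", "EER_total")
    if (abs(r$slope - (-6)) < 2 * r$slope_se) covered <- covered + 1
  }
  expect_gte(covered, 34)   # ~95% coverage, allowing binomial noise
})

test_that("regression p-values are uniform under permuted ages", {
  ps <- numeric(60)
  for (s in seq_len(60)) {
    set.seed(800 + s)
    ages <- runif(60, 24, 74)
    dens <- 500 - 4 * ages + rnorm(60, 0, 100)
    d <- data.frame(donor_id = sprintf("D%03d", 1:60), cell_class = "T",
                    compartment = "EER_total", density = dens)
    ps[s] <- age_regression(mini_cohort(d, sample(ages)), "T",
                            "EER_total")$p_value
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("two-group ANOVA F equals t squared", {
  set.seed(900)
  ids <- sprintf("D%02d", 1:30)
  d <- data.frame(donor_id = ids, cell_class = "T",
                  compartment = "EER_total", density = rnorm(30, 100, 20))
  risk <- rep(c("AR", "HR"), each = 15)
  co <- mini_cohort(d, risk = risk)
  a <- group_anova(co, "risk", "T", "EER_total")
  t <- unpaired_compare(co, "risk", "T", "EER_total")
  expect_equal(a$statistic, t$statistic^2, tolerance = 1e-10)
  expect_equal(a$p_value, t$p_value, tolerance = 1e-10)
})

test_that("a strongly shifted group is flagged by every Tukey pair", {
  hits <- 0
  for (s in 1:10) {
    set.seed(910 + s)
    ids <- sprintf("D%02d", 1:60)
    ages <- c(runif(20, 24, 39), runif(20, 41, 50), runif(20, 51, 59))
    dens <- rnorm(60, 100, 20)
    dens[41:60] <- dens[41:60] + 3 * 20    # third age bin shifted +3 sd
    d <- data.frame(donor_id = ids, cell_class = "T",
                    compartment = "EER_total", density = dens)
    a <- group_anova(mini_cohort(d, ages), "age_bin", "T", "EER_total")
    pair_ps <- a$tukey[grep("51-59y", names(a$tukey))]
    if (all(pair_ps < 0.01)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("tukey adjusted p-values are never below the ANOVA floor of raw pairs", {
  set.seed(920)
  ids <- sprintf("D%02d", 1:45)
  ages <- runif(45, 24, 74)
  d <- data.frame(donor_id = ids, cell_class = "T",
                  compartment = "EER_total", density = rnorm(45, 100, 30))
  a <- group_anova(mini_cohort(d, ages), "age_bin", "T", "EER_total")
  expect_true(all(a$tukey >= 0 & a$tukey <= 1))
})

test_that("paired PE/ILS comparison has exact null and antisymmetry", {
  ids <- sprintf("D%02d", 1:12)
  pe <- data.frame(donor_id = ids, cell_class = "T", compartment = "PE",
                   density = c(5, 8, 12, 20, 7, 9, 30, 14, 11, 6, 18, 25))
  ils <- pe; ils$compartment <- "ILS"
  co <- mini_cohort(rbind(pe, ils))
  r <- paired_compare(co, "T")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # antisymmetry: swapping compartments flips t, keeps p
  set.seed(930)
  ils$density <- ils$density + rnorm(12, 50, 30)
  co2 <- mini_cohort(rbind(pe, ils))
  r2 <- paired_compare(co2, "T")
  swapped <- rbind(transform(pe, compartment = "ILS"),
                   transform(ils, compartment = "PE"))
  r3 <- paired_compare(mini_cohort(swapped), "T")
  expect_equal(r3$statistic, -r2$statistic)
  expect_equal(r3$p_value, r2$p_value)
})

test_that("a planted PE-ILS offset is detected reliably", {
  hits <- 0
  for (s in 1:10) {
    set.seed(940 + s)
    ids <- sprintf("D%02d", 1:20)
    base <- rnorm(20, 300, 80)
    pe <- data.frame(donor_id = ids, cell_class = "Mac", compartment = "PE",
                     density = base + 200 + rnorm(20, 0, 100))
    ils <- data.frame(donor_id = ids, cell_class = "Mac", compartment = "ILS",
                      density = base)
    if (paired_compare(mini_cohort(rbind(pe, ils)), "Mac")$p_value < 0.001)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("unpaired comparison is invariant to group order up to sign", {
  set.seed(950)
  ids <- sprintf("D%02d", 1:30)
  d <- data.frame(donor_id = ids, cell_class = "B",
                  compartment = "EER_total", density = rnorm(30, 50, 10))
  co1 <- mini_cohort(d, risk = rep(c("AR", "HR"), 15))
  co2 <- mini_cohort(d, risk = rep(c("HR", "AR"), 15))
  r1 <- unpaired_compare(co1, "risk", "B")
  r2 <- unpaired_compare(co2, "risk", "B")
  expect_equal(abs(r1$statistic), abs(r2$statistic))
  expect_equal(r1$p_value, r2$p_value)
})

test_that("tukey boxplot stats follow the 1.5 IQR rule", {
  # hand-computed 8-value fixture, type-7 (linear interpolation) quartiles:
  # sorted 1..7,100: q1 = 2.75, med = 4.5, q3 = 6.25, IQR = 3.5,
  # fences at -2.5 and 11.5 -> 100 is the only outlier
  v <- c(4, 2, 7, 1, 100, 3, 5, 6)
  s <- tukey_boxplot_stats(v)
  expect_equal(unname(s$quartiles), c(2.75, 4.5, 6.25))
  expect_equal(unname(s$whiskers), c(1, 7))
  expect_equal(s$outliers, 100)
  # symmetric data without extremes: no outliers
  s2 <- tukey_boxplot_stats(c(-2, -1, 0, 1, 2))
  expect_equal(length(s2$outliers), 0L)
})

test_that("significance symbols follow the published thresholds", {
  expect_equal(significance_symbol(c(0.00005, 0.0005, 0.005, 0.03, 0.2)),
               c("****", "***", "**", "*", "NS"))
  expect_equal(significance_symbol(0.05), "*")
  expect_equal(significance_symbol(0.0001), "****")
})
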