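# probe collapse, scaling, signature scoring, age-group testing with Holm

make_sigs <- function() list(sigA = sprintf("g%04d", 1:20),
                             sigB = sprintf("g%04d", 21:40),
                             sigC = sprintf("g%04d", 41:60))

test_that("probe collapse keeps the probe with maximum average expression", {
  expr <- rbind(p1 = c(5, 5, 5), p2 = c(7, 7, 7), p3 = c(1, 2, 3))
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene = c("gA", "gA", "gB"))
  out <- collapse_probes(expr, ann)
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(unname(out["gA", ]), c(7, 7, 7))
  # one probe per gene: identity up to row order
  expr1 <- expr[3, , drop = FALSE]
  out1 <- collapse_probes(expr1, ann)
  expect_equal(unname(out1["gB", ]), c(1, 2, 3))
  expect_error(collapse_probes(expr[0, , drop = FALSE], ann), "empty")
})

test_that("probe collapse agrees with a brute-force argmax oracle", {
  set.seed(80)
  ex <- generate_expression(expression_spec(n_genes = 60, seed = 81),
                            make_sigs())
  out <- collapse_probes(ex$expr, ex$probe_gene)
  # brute force: per gene, scan probes for maximal mean
  for (g in sample(rownames(out), 15)) {
    probes <- ex$probe_gene$probe_id[ex$probe_gene$gene == g]
    means <- rowMeans(ex$expr[probes, , drop = FALSE])
    best <- probes[which.max(means)]
    expect_equal(unname(out[g, ]), unname(ex$expr[best, ]))
  }
})

test_that("gene scaling yields zero mean, unit sd, shift invariance", {
  set.seed(82)
  m <- matrix(rnorm(50 * 10, 5, 2), 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  s <- scale_genes(m)
  expect_lt(max(abs(rowMeans(s))), 1e-12)
  expect_equal(apply(s, 1, sd), rep(1, 50), ignore_attr = TRUE,
               tolerance = 1e-12)
  # constant shifts map to identical outputs
  s2 <- scale_genes(m + 3)
  expect_equal(s, s2)
  m[1, ] <- 7
  expect_warning(s3 <- scale_genes(m), "zero-variance")
  expect_equal(nrow(s3), 49)
})

test_that("signature scores equal the mean over member genes", {
  set.seed(83)
  m <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(sprintf("g%04d", 1:60), sprintf("S%d", 1:8)))
  s <- scale_genes(m)
  sigs <- make_sigs()
  sc <- score_signatures(s, sigs)
  expect_equal(sc$scores["sigA", ], colMeans(s[sigs$sigA, ]))
  # single-gene signature equals that gene's scaled value
  sc1 <- score_signatures(s, list(solo = "g0007"))
  expect_equal(unname(sc1$scores["solo", ]), unname(s["g0007", ]))
  # absent signature flagged, not zero
  sc0 <- score_signatures(s, list(ghost = c("nope1", "nope2")))
  expect_true(all(is.na(sc0$scores["ghost", ])))
  expect_equal(sc0$n_present[["ghost"]], 0L)
})

test_that("Holm step-down matches its definition on the worked example", {
  # sorted p * (m - rank + 1), cumulative max, capped at 1:
  # [0.01, 0.03, 0.04] * [3, 2, 1] = [0.03, 0.06, 0.04] -> [0.03, 0.06, 0.06]
  raw <- c(0.01, 0.04, 0.03)
  manual <- {
    o <- order(raw)
    adj <- pmin(cummax(sort(raw) * (3 - seq_len(3) + 1)), 1)
    out <- numeric(3); out[o] <- adj; out
  }
  expect_equal(manual, c(0.03, 0.06, 0.06))
  expect_equal(p.adjust(raw, "holm"), manual)
  # Holm equals Bonferroni for a single test
  expect_equal(p.adjust(0.02, "holm"), p.adjust(0.02, "bonferroni"))
})

test_that("unknown signature genes error with the missing names", {
  expect_error(generate_expression(expression_spec(n_genes = 10, seed = 84),
                                   list(bad = c("g0001", "gZZZZ"))),
               "gZZZZ")
})

test_that("group sizes default to the study structure", {
  ex <- generate_expression(expression_spec(seed = 85), make_sigs())
  expect_equal(sum(ex$ages <= 35), 51L)
  expect_equal(sum(ex$ages >= 50), 23L)
  expect_equal(length(ex$ages), 121L)
})

test_that("a planted 1-sd shift is detected with direction up", {
  detected <- 0
  for (s in 1:12) {
    sigs <- make_sigs()
    ex <- generate_expression(expression_spec(
      effects = c(sigA = 1.0), seed = 86 + s), sigs)
    gm <- collapse_probes(ex$expr, ex$probe_gene)
    sc <- score_signatures(scale_genes(gm), sigs)
    res <- compare_age_groups(sc$scores, ex$ages)
    row <- res[res$signature == "sigA", ]
    if (row$adjusted_p < 0.05 && row$direction == "up") detected <- detected + 1
  }
  expect_gte(detected, 11)
})

test_that("the global null controls the family-wise error rate", {
  fw_errors <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    sigs <- make_sigs()
    ex <- generate_expression(expression_spec(n_genes = 100, seed = 200 + s),
                              sigs)
    gm <- collapse_probes(ex$expr, ex$probe_gene)
    sc <- score_signatures(scale_genes(gm), sigs)
    res <- compare_age_groups(sc$scores, ex$ages)
    if (any(res$adjusted_p < 0.05)) fw_errors <- fw_errors + 1
  }
  # FWER <= 0.05: expect ~1 of 25; allow generous binomial slack
  expect_lte(fw_errors, 4)
})

test_that("adjusted p-values are monotone above raw and within [0, 1]", {
  sigs <- make_sigs()
  ex <- generate_expression(expression_spec(effects = c(sigB = 0.5),
                                            seed = 87), sigs)
  gm <- collapse_probes(ex$expr, ex$probe_gene)
  sc <- score_signatures(scale_genes(gm), sigs)
  res <- compare_age_groups(sc$scores, ex$ages)
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_true(all(res$adjusted_p <= 1))
})

test_that("GMT files round-trip", {
  sigs <- make_sigs()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sigs, path)
  back <- read_gmt(path)
  expect_equal(back, sigs)
})
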