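# Star codes, percent change, gray tones, ANOVA + Tukey, Mann-Whitney,
# study contrasts with calibration and power behaviour.

test_that("star codes follow the strict-threshold convention", {
  expect_equal(star_code(0.03), "*")
  expect_equal(star_code(0.0003), "***")
  expect_equal(star_code(0.05), "ns")     # strict '<' at the boundary
  expect_equal(star_code(0.009), "**")
  expect_equal(star_code(5e-5), "****")
  expect_equal(star_code(0.9), "ns")
  expect_error(star_code(1.2), "within")
  # monotone: smaller p never yields fewer stars
  ps <- sort(runif(50))
  n_stars <- nchar(gsub("ns", "", star_code(ps)))
  expect_true(all(diff(n_stars) <= 0))
})

test_that("percent change reports magnitude and direction", {
  expect_equal(percent_change(100, 161.7),
               list(percent_change = 61.7, direction = "increase"))
  expect_equal(percent_change(100, 100)$direction, "none")
  expect_equal(percent_change(200, 150),
               list(percent_change = -25, direction = "decrease"))
  expect_error(percent_change(0, 5), "non-zero")
})

test_that("gray tone maps intensity monotonically onto the display range", {
  expect_equal(gray_tone(0), 0)
  expect_equal(gray_tone(250), 250)
  expect_equal(gray_tone(255), 250)  # clipped at the display maximum
  v <- sort(runif(20, 0, 255))
  expect_true(all(diff(gray_tone(v)) >= 0))
})

test_that("ANOVA omnibus F matches the closed-form two-group oracle", {
  # hand-computed on {A: 1,2; B: 5,6}: MSB = 16, MSW = 0.5, F = 32
  res <- anova_tukey(list(A = c(1, 2), B = c(5, 6)))
  omni <- res[res$test == "anova", ]
  expect_equal(omni$statistic, 32)
  expect_equal(omni$p_value, 1 - pf(32, 1, 2))

  ident <- anova_tukey(list(A = 1:3, B = 1:3, C = 1:3))
  expect_equal(ident[ident$test == "anova", "statistic"], 0)
  expect_equal(ident[ident$test == "anova", "p_value"], 1)
  expect_true(all(ident[ident$test == "tukey_pair", "p_value"] == 1))

  # zero within-group variance with unequal means: limiting p = 0
  deg <- anova_tukey(list(A = c(2, 2), B = c(5, 5)))
  expect_equal(deg[deg$test == "anova", "p_value"], 0)

  expect_error(anova_tukey(list(A = 1)), "insufficient")
  expect_error(anova_tukey(list(A = c(1, 2), B = 3)), "insufficient")
})

test_that("Tukey-adjusted pairwise p-values dominate unadjusted ones", {
  set.seed(5)
  for (k in 1:5) {
    samples <- list(a = rnorm(6 + k), b = rnorm(8), c = rnorm(5) + k / 4)
    res <- anova_tukey(samples)
    pairs <- res[res$test == "tukey_pair", ]
    # the unadjusted counterpart of a Tukey pair is the pooled-variance
    # pairwise t-test on the same fit
    values <- unlist(samples, use.names = FALSE)
    fac <- factor(rep(names(samples), lengths(samples)))
    raw <- stats::pairwise.t.test(values, fac, pool.sd = TRUE,
                                  p.adjust.method = "none")$p.value
    lookup <- function(x, y) {
      if (x %in% rownames(raw) && y %in% colnames(raw) &&
          !is.na(raw[x, y])) raw[x, y] else raw[y, x]
    }
    for (i in seq_len(nrow(pairs))) {
      nm <- strsplit(pairs$contrast[i], "-")[[1]]
      expect_gte(pairs$p_value[i] + 1e-10, lookup(nm[1], nm[2]))
    }
  }
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)   # U_a
  expect_equal(r$u_b, 9)
  expect_equal(r$p_value, 0.1)   # 2 of the 20 orderings are as extreme
  expect_true(r$exact)

  tied <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$p_value, 1)

  set.seed(31)
  for (k in 1:6) {
    a <- round(rnorm(6, 0, 5), 3)
    b <- round(rnorm(6, 1, 5), 3)
    r <- mann_whitney(a, b)
    expect_true(r$exact)
    expect_equal(r$statistic + r$u_b, 36)
    expect_equal(r$p_value, mw_enumeration_p(a, b), tolerance = 1e-9)
    # symmetry: swapping samples preserves p and swaps U_a / U_b
    rs <- mann_whitney(b, a)
    expect_equal(rs$p_value, r$p_value)
    expect_equal(rs$statistic, r$u_b)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "insufficient")
})

test_that("ANOVA F is invariant under shift and scale of the data", {
  set.seed(77)
  samples <- list(a = rnorm(8, 10), b = rnorm(7, 11), c = rnorm(9, 10.5))
  f0 <- anova_tukey(samples)[1, "statistic"]
  shifted <- lapply(samples, `+`, 100)
  scaled <- lapply(samples, `*`, 3.7)
  expect_equal(anova_tukey(shifted)[1, "statistic"], f0)
  expect_equal(anova_tukey(scaled)[1, "statistic"], f0)
})

test_that("run_study_contrasts emits the full deterministic contrast set", {
  study <- simulate_study(n_per_stratum = 12, ages = c(6, 12),
                          layers = "OPL",
                          variables = list(soma_area_um2 = c(55, 14)),
                          seed = 3)
  res <- run_study_contrasts(study)
  # per stratum: 2 omnibus + 2 x 1 tukey pair + 2 between-group tests
  expect_equal(sum(res$test == "anova"), 2)
  expect_equal(sum(res$test == "tukey_pair"), 2)
  expect_equal(sum(res$test == "mann_whitney"), 2)
  expect_true(all(res$star == star_code(res$p_value)))
  mw <- res[res$test == "mann_whitney", ]
  expect_true(all(mw$direction %in% c("increase", "decrease", "none")))
  expect_true(all(sign(mw$percent_change[mw$direction == "increase"]) == 1))

  # rerun is identical
  expect_identical(run_study_contrasts(study), res)
  # field pooling aggregates to per-field medians first
  res_f <- run_study_contrasts(study, pooling = "field")
  expect_true(nrow(res_f) > 0)
  # BH adjustment appends a monotone column
  res_adj <- run_study_contrasts(study, fdr_adjust = TRUE)
  o <- order(res_adj$p_value)
  expect_true(all(diff(res_adj$p_adj[o]) >= -1e-12))
  expect_error(run_study_contrasts(study[, -1]), "missing column")
})

test_that("null studies reject near the nominal rate; planted effects are detected", {
  # calibration: nominal-alpha tests (omnibus ANOVA + Mann-Whitney) under a
  # null generator; Tukey-adjusted pairs control the family-wise rate by
  # design and are excluded from the pooled rate
  ps <- numeric(0)
  for (rep in 1:3) {
    study <- simulate_study(n_per_stratum = 60, seed = 100 + rep)
    res <- run_study_contrasts(study)
    ps <- c(ps, res$p_value[res$test %in% c("anova", "mann_whitney")])
  }
  n <- length(ps)
  expect_gte(n, 200)
  rate <- mean(ps < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)

  # power: a planted 30% soma-area increase at one age, 60 cells per group
  eff <- data.frame(group = "APP", age = 12, layer = "OPL",
                    variable = "soma_area_um2", multiplier = 1.3)
  hits <- 0
  for (rep in 1:60) {
    st <- simulate_study(n_per_stratum = 60, ages = 12, layers = "OPL",
                         variables = list(soma_area_um2 = c(55, 14)),
                         effects = eff, seed = 500 + rep)
    wt <- st$value[st$group == "WT"]
    app <- st$value[st$group == "APP"]
    if (mann_whitney(wt, app)$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 60, 0.9)
})
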