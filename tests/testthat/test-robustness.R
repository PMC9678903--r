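test_that("percent effect change follows the printed formula and doubling flag", {
  main <- make_records("e1", c("f1", "f2", "f3"),
    effect = c(0.5, 0.5, 0.4), p = 0.01, model_tag = "main"
  )
  alt <- make_records("e1", c("f1", "f2", "f3"),
    effect = c(1.2, 0.5, 0.1), p = 0.01, model_tag = "no_zbmi"
  )
  pc <- percent_effect_change(main, alt)
  expect_equal(pc$percent_change, c(-140, 0, 75))
  expect_equal(pc$flagged, c(TRUE, FALSE, FALSE))
  main0 <- make_records("e1", "f1", effect = 0, p = 0.5)
  expect_warning(
    pc0 <- percent_effect_change(main0, alt[1, ]),
    "undefined"
  )
  expect_true(is.na(pc0$percent_change))
})

test_that("meta-analysis reproduces hand-computed fixed/random pooling", {
  # two identical cohorts: beta 0.3, se 0.1
  m1 <- cohort_meta_analysis(make_records("e", "f",
    effect = c(0.3, 0.3),
    p = 0.5, se = 0.1
  ) |> dplyr::mutate(cohort = c("a", "b")))
  expect_equal(m1$beta_fixed, 0.3)
  expect_equal(m1$se_fixed, 0.1 / sqrt(2))
  expect_equal(m1$q, 0)
  expect_equal(m1$tau2, 0)
  expect_equal(m1$i2, 0)
  expect_equal(m1$beta_random, m1$beta_fixed)
  expect_equal(m1$se_random, m1$se_fixed)

  # opposed effects: Q = 100*0.25 + 100*0.25 = 50, I2 = 49/50 * 100 = 98
  m2 <- cohort_meta_analysis(make_records("e", "f",
    effect = c(0.5, -0.5),
    p = 0.5, se = 0.1
  ) |> dplyr::mutate(cohort = c("a", "b")))
  expect_equal(m2$beta_fixed, 0)
  expect_equal(m2$q, 50)
  expect_equal(m2$i2, 98)

  # homogeneity limit: identical estimates, arbitrary SEs
  m3 <- cohort_meta_analysis(make_records("e", "f",
    effect = rep(0.2, 4),
    p = 0.5, se = c(0.1, 0.2, 0.05, 0.3)
  ) |> dplyr::mutate(cohort = letters[1:4]))
  expect_equal(m3$i2, 0)
  expect_equal(m3$beta_random, m3$beta_fixed)

  expect_error(
    cohort_meta_analysis(make_records("e", "f",
      effect = c(1, 2), p = 0.5,
      se = c(0.1, 0)
    ) |> dplyr::mutate(cohort = c("a", "bad_cohort"))),
    "bad_cohort"
  )
})

test_that("single-cohort pooling degenerates to the cohort estimate", {
  m <- cohort_meta_analysis(
    make_records("e", "f", effect = 0.4, p = 0.5, se = 0.12) |>
      dplyr::mutate(cohort = "only")
  )
  expect_equal(m$beta_fixed, 0.4)
  expect_equal(m$beta_random, 0.4)
  expect_true(is.na(m$i2))
})

test_that("pooling is order-invariant and the fixed SE dominates every cohort", {
  set.seed(51)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    est <- rnorm(k)
    se <- runif(k, 0.05, 0.5)
    rec <- make_records("e", "f", effect = est, p = 0.5, se = se) |>
      dplyr::mutate(cohort = paste0("c", 1:k))
    m <- cohort_meta_analysis(rec)
    mp <- cohort_meta_analysis(rec[sample(k), ])
    expect_equal(m$beta_fixed, mp$beta_fixed)
    expect_lte(m$se_fixed, min(se))
    expect_gte(m$i2, 0)
    expect_lte(m$i2, 100)
    if (m$tau2 == 0) expect_equal(m$beta_random, m$beta_fixed)
  }
})

test_that("DerSimonian-Laird pooling agrees with metafor", {
  set.seed(52)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    est <- rnorm(k, 0.3, 0.3)
    se <- runif(k, 0.05, 0.4)
    m <- cohort_meta_analysis(
      make_records("e", "f", effect = est, p = 0.5, se = se) |>
        dplyr::mutate(cohort = paste0("c", 1:k))
    )
    fe <- metafor::rma(yi = est, sei = se, method = "FE")
    re <- metafor::rma(yi = est, sei = se, method = "DL")
    expect_equal(m$beta_fixed, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(m$se_fixed, fe$se, tolerance = 1e-10)
    expect_equal(m$tau2, re$tau2, tolerance = 1e-10)
    expect_equal(m$beta_random, as.numeric(re$beta), tolerance = 1e-10)
    expect_equal(m$q, re$QE, tolerance = 1e-10)
  }
})

test_that("homogeneous cohorts give low I2 and heterogeneous cohorts high I2", {
  run_one <- function(het, seed) {
    pe <- tibble::tibble(
      exposure = rep(sprintf("metals_%d_chil", 1:5), each = 10),
      feature = sprintf("prot_%04d", 1:50), beta = 0.5
    )
    sc <- sim_scenario(
      n_samples = 600, n_cohorts = 6,
      exposure_spec = tibble::tibble(
        family = "metals", n_exposures = 5L, rho = 0.3, n_categorical = 0L
      ),
      omics_spec = tibble::tibble(
        layer = "protein", n_features = 50L, scale = "log2", noise_sd = 0.5
      ),
      planted_effects = pe, cohort_heterogeneity = het, seed = seed
    )
    st <- simulate_study(sc)
    bc <- run_exwas_by_cohort(
      st$exposome, st$layers, st$covariates, exwas_spec(n_svs = 0)
    )
    bc <- dplyr::semi_join(bc, pe, by = c("exposure", "feature"))
    m <- cohort_meta_analysis(bc)
    pooled <- run_exwas(
      st$exposome, st$layers, st$covariates, exwas_spec(n_svs = 0)
    ) |> dplyr::semi_join(pe, by = c("exposure", "feature"))
    list(meta = m, pooled = pooled)
  }
  hom <- run_one(0, 61)
  expect_lt(median(hom$meta$i2), 25)
  # all-samples cohort-adjusted estimates agree with fixed-effects pooling
  cmp <- dplyr::inner_join(
    hom$pooled[, c("exposure", "feature", "effect", "se")],
    hom$meta[, c("exposure", "feature", "beta_fixed", "se_fixed")],
    by = c("exposure", "feature")
  )
  expect_true(all(
    abs(cmp$effect - cmp$beta_fixed) < 2 * pmax(cmp$se, cmp$se_fixed)
  ))
  het <- run_one(0.5, 61)
  expect_gt(median(het$meta$i2), 50)
})

test_that("multi-exposure selection applies the group and correlation rules", {
  meta <- exposure_metadata(
    exposure = c("hg", "fish", "pcb153", "pcb180", "a", "b", "c"),
    period = "childhood",
    family = c(
      "metals", "diet", "organochlorines", "organochlorines",
      "meteo", "air_pollution", "lifestyle"
    )
  )
  vars <- meta$exposure
  cmat <- diag(1, 7)
  dimnames(cmat) <- list(vars, vars)
  cmat["hg", "fish"] <- cmat["fish", "hg"] <- 0.5
  cmat["pcb153", "pcb180"] <- cmat["pcb180", "pcb153"] <- 0.9
  cmat["a", "b"] <- cmat["b", "a"] <- 0.9

  # both survive: different groups, correlation below cutoff
  f1 <- make_records(c("hg", "fish"), "feat1",
    effect = 0.2,
    p = c(0.001, 0.002), significant = TRUE
  )
  # same family (organochlorines): one group representative, then < 2 left
  f2 <- make_records(c("pcb153", "pcb180"), "feat2",
    effect = 0.2,
    p = c(0.001, 0.002), significant = TRUE
  )
  # greedy correlation rule: corr(a, b) = 0.9, p_a < p_b -> {a, c}
  f3 <- make_records(c("a", "b", "c"), "feat3",
    effect = 0.2,
    p = c(0.001, 0.002, 0.003), significant = TRUE
  )
  flags <- dplyr::bind_rows(f1, f2, f3)
  sets <- select_multi_exposure_sets(flags, cmat, meta)
  expect_setequal(sets$feature, c("feat1", "feat3"))
  expect_setequal(sets$exposures[[which(sets$feature == "feat1")]]$exposure,
    c("hg", "fish"))
  expect_setequal(sets$exposures[[which(sets$feature == "feat3")]]$exposure,
    c("a", "c"))
  excl <- attr(sets, "exclusions")
  expect_true(any(
    excl$excluded == "pcb180" & excl$reason == "same_correlation_group" &
      excl$retained == "pcb153"
  ))
  expect_true(any(
    excl$excluded == "b" & excl$reason == "correlation_at_or_above_cutoff" &
      excl$retained == "a"
  ))
  expect_error(
    select_multi_exposure_sets(flags, cmat[1:3, 1:3], meta),
    "missing from the correlation matrix"
  )
})

test_that("joint models leave orthogonal exposures unchanged and shrink proxies", {
  # metals family at rho 0.7: metals_2 is causal, the others are proxies
  sc <- sim_scenario(
    n_samples = 400, n_cohorts = 2,
    exposure_spec = tibble::tibble(
      family = "metals", n_exposures = 4L, rho = 0.7, n_categorical = 0L
    ),
    omics_spec = tibble::tibble(
      layer = "protein", n_features = 10L, scale = "log2", noise_sd = 0.5
    ),
    planted_effects = tibble::tibble(
      exposure = "metals_2_chil", feature = "prot_0005", beta = 0.6
    ),
    seed = 11
  )
  st <- simulate_study(sc)
  res <- run_exwas(
    st$exposome, st$layers, st$covariates, exwas_spec(n_svs = 0)
  )
  flagged <- apply_correction(res, st$layers)
  sets <- select_multi_exposure_sets(
    flagged, exposure_correlation(st$exposome), st$exposome$meta
  )
  joint <- fit_multi_exposure(
    sets, st$exposome, st$layers, st$covariates, exwas_spec(n_svs = 0)
  )
  causal <- dplyr::filter(joint, exposure == "metals_2_chil")
  proxies <- dplyr::filter(joint, exposure != "metals_2_chil")
  # the causal exposure keeps its effect (within 2 joint SEs)
  expect_true(all(
    abs(causal$effect_joint - causal$single_effect) <
      2 * causal$se_joint + 0.05
  ))
  # proxies are attenuated by more than 25%
  expect_true(all(proxies$percent_change > 25))
})

test_that("joint designs include one column per categorical level contrast", {
  sc <- sim_scenario(
    n_samples = 300, n_cohorts = 2,
    exposure_spec = tibble::tibble(
      family = "metals", n_exposures = 3L, rho = 0.3, n_categorical = 1L
    ),
    omics_spec = tibble::tibble(
      layer = "protein", n_features = 5L, scale = "log2", noise_sd = 0.5
    ),
    seed = 71
  )
  st <- simulate_study(sc)
  sets <- tibble::tibble(
    feature = "prot_0001", period = "childhood", layer = "protein",
    exposures = list(tibble::tibble(
      exposure = c("metals_1_chil", "metals_2_chil"),
      contrast = NA_character_, effect = c(0.1, 0.1), se = 0.1,
      p = c(0.01, 0.02)
    ))
  )
  class(sets) <- c("multi_exposure_sets", class(sets))
  joint <- fit_multi_exposure(
    sets, st$exposome, st$layers, st$covariates, exwas_spec(n_svs = 0)
  )
  # metals_1 is 3-level categorical (2 contrasts), metals_2 continuous
  expect_equal(nrow(joint), 3L)
  expect_equal(sum(joint$exposure == "metals_1_chil"), 2L)
  expect_setequal(
    joint$contrast[joint$exposure == "metals_1_chil"], c("medium", "high")
  )
})
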