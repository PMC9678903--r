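#' Define a synthetic cohort scenario
#'
#' A scenario fully determines (together with its seed) a synthetic
#' mother-child cohort with the statistical structure the association
#' pipeline assumes: several recruitment cohorts, exposure families with
#' block-equicorrelated continuous variables and thresholded categorical
#' variables, low pregnancy-childhood correlation of repeated exposures,
#' multi-layer omics matrices with planted per-IQR linear effects, dense
#' latent factors standing in for batch and blood cell composition, and an
#' optional adiposity-confounding path (zBMI raises both a lipophilic
#' pollutant and an adipokine-like protein with no direct
#' pollutant-protein effect).
#'
#' @param n_samples Number of children.
#' @param n_cohorts Number of recruitment cohorts (default 6).
#' @param exposure_spec Tibble with columns `family`, `n_exposures`,
#'   `rho` (within-family equicorrelation in \[0, 1)) and `n_categorical`
#'   (how many of the family's variables are 3-level categorical).
#'   Each family is generated in both exposure periods.
#' @param cross_period_correlation Correlation between the pregnancy and
#'   childhood copy of the same variable (default 0.2; repeated exposures
#'   correlate only weakly across periods).
#' @param cohort_exposure_shift_sd SD of cohort-specific exposure mean
#'   shifts (0 disables between-cohort exposure heterogeneity).
#' @param omics_spec Tibble with columns `layer`, `n_features`, `scale`,
#'   `noise_sd`.
#' @param planted_effects Tibble with columns `exposure`, `feature`,
#'   `beta`: true per-IQR effects on the feature's linear scale
#'   (logit scale for methylation).
#' @param n_latent_factors Number of dense latent factors per genome-wide
#'   layer (batch + cell composition stand-in).
#' @param latent_loading_sd SD of nonzero latent-factor loadings.
#' @param latent_feature_fraction Fraction of features loaded by each
#'   factor (default 0.3).
#' @param covariate_effect_sd SD of per-feature covariate effects.
#' @param covariate_effect_fraction Fraction of features carrying
#'   covariate signal.
#' @param cohort_heterogeneity SD of cohort-specific multiplicative
#'   factors applied to planted betas (0 = homogeneous effects across
#'   cohorts; positive values exercise meta-analytic I-squared).
#' @param confounding Optional list
#'   `list(exposure=, feature=, zbmi_to_exposure=, zbmi_to_feature=)`
#'   describing the adiposity scenario.
#' @param seed Integer seed; identical scenarios give bit-identical data.
#' @return A validated object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_samples = 1300,
                         n_cohorts = 6,
                         exposure_spec = default_exposure_spec(),
                         cross_period_correlation = 0.2,
                         cohort_exposure_shift_sd = 0,
                         omics_spec = default_omics_spec(),
                         planted_effects = NULL,
                         n_latent_factors = 0,
                         latent_loading_sd = 1,
                         latent_feature_fraction = 0.3,
                         covariate_effect_sd = 0.1,
                         covariate_effect_fraction = 0.2,
                         cohort_heterogeneity = 0,
                         confounding = NULL,
                         seed = 1) {
  exposure_spec <- as_tibble(exposure_spec)
  omics_spec <- as_tibble(omics_spec)
  stopifnot_cols(
    exposure_spec, c("family", "n_exposures", "rho", "n_categorical"),
    "exposure_spec"
  )
  stopifnot_cols(
    omics_spec, c("layer", "n_features", "scale", "noise_sd"), "omics_spec"
  )
  if (any(exposure_spec$rho < 0 | exposure_spec$rho >= 1)) {
    abort("within-family correlation rho must lie in [0, 1)")
  }
  if (cross_period_correlation < 0 || cross_period_correlation >= 1) {
    abort("cross_period_correlation must lie in [0, 1)")
  }
  bad_layer <- setdiff(omics_spec$layer, OMICS_LAYERS)
  if (length(bad_layer) > 0) {
    abort(sprintf("unknown omics layer(s): %s", compact_chr(bad_layer)))
  }
  scenario <- structure(
    list(
      n_samples = as.integer(n_samples),
      n_cohorts = as.integer(n_cohorts),
      exposure_spec = exposure_spec,
      cross_period_correlation = cross_period_correlation,
      cohort_exposure_shift_sd = cohort_exposure_shift_sd,
      omics_spec = omics_spec,
      planted_effects = if (is.null(planted_effects)) {
        tibble(exposure = character(), feature = character(), beta = double())
      } else {
        as_tibble(planted_effects)
      },
      n_latent_factors = as.integer(n_latent_factors),
      latent_loading_sd = latent_loading_sd,
      latent_feature_fraction = latent_feature_fraction,
      covariate_effect_sd = covariate_effect_sd,
      covariate_effect_fraction = covariate_effect_fraction,
      cohort_heterogeneity = cohort_heterogeneity,
      confounding = confounding,
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
  all_exposures <- scenario_exposure_names(scenario)$exposure
  all_features <- scenario_feature_names(scenario)$feature_id
  pe <- scenario$planted_effects
  if (nrow(pe) > 0) {
    bad <- setdiff(pe$exposure, all_exposures)
    if (length(bad) > 0) {
      abort(sprintf("planted effect on unknown exposure: %s", compact_chr(bad)))
    }
    bad <- setdiff(pe$feature, all_features)
    if (length(bad) > 0) {
      abort(sprintf("planted effect on unknown feature: %s", compact_chr(bad)))
    }
  }
  if (!is.null(confounding)) {
    stopifnot(all(
      c("exposure", "feature", "zbmi_to_exposure", "zbmi_to_feature") %in%
        names(confounding)
    ))
    if (!confounding$exposure %in% all_exposures) {
      abort("confounding exposure not in scenario")
    }
    if (!confounding$feature %in% all_features) {
      abort("confounding feature not in scenario")
    }
  }
  scenario
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> n=%d, %d cohorts, %d exposures/period, %d omics layers, seed=%d\n",
    x$n_samples, x$n_cohorts, sum(x$exposure_spec$n_exposures),
    nrow(x$omics_spec), x$seed
  ))
  invisible(x)
}

#' @rdname sim_scenario
#' @export
default_exposure_spec <- function() {
  tribble(
    ~family, ~n_exposures, ~rho, ~n_categorical,
    "metals", 5L, 0.3, 1L,
    "organochlorines", 5L, 0.6, 0L,
    "diet", 5L, 0.3, 2L,
    "air_pollution", 5L, 0.5, 0L
  )
}

#' @rdname sim_scenario
#' @export
default_omics_spec <- function() {
  tribble(
    ~layer, ~n_features, ~scale, ~noise_sd,
    "methylation", 500L, "beta_0_1", 0.5,
    "expression", 100L, "log2", 0.5,
    "mirna", 50L, "log2", 0.5,
    "protein", 30L, "log2", 0.5,
    "serum_metab", 50L, "log2", 0.5
  )
}

#' The compact benchmark scenario used throughout the test-suite
#'
#' 300 children in 2 cohorts, 40 exposures (20 per period across 4
#' families) and 5 omics layers with 500/100/50/30/50 features. All other
#' structure (planted effects, latent factors, confounding) is off unless
#' supplied.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
helix_mini_scenario <- function(seed = 1, ...) {
  sim_scenario(
    n_samples = 300,
    n_cohorts = 2,
    seed = seed,
    ...
  )
}

# Deterministic naming of scenario exposures and features ---------------

scenario_exposure_names <- function(scenario) {
  rows <- purrr::pmap(scenario$exposure_spec, function(family, n_exposures,
                                                      rho, n_categorical) {
    purrr::map(EXPOSURE_PERIODS, function(period) {
      idx <- seq_len(n_exposures)
      tibble(
        exposure = sprintf("%s_%d_%s", family, idx, substr(period, 1, 4)),
        period = period,
        family = family,
        vartype = ifelse(idx <= n_categorical, "categorical", "continuous"),
        base_index = idx
      )
    })
  })
  bind_rows(purrr::flatten(rows))
}

scenario_feature_names <- function(scenario) {
  prefix <- c(
    methylation = "cpg", expression = "tc", mirna = "mir",
    protein = "prot", serum_metab = "smet", urine_metab = "umet"
  )
  bind_rows(purrr::pmap(
    scenario$omics_spec[, c("layer", "n_features")],
    function(layer, n_features) {
      tibble(
        feature_id = sprintf(
          "%s_%0*d", prefix[[layer]],
          max(4, nchar(n_features)), seq_len(n_features)
        ),
        layer = layer
      )
    }
  ))
}

#' Generate the covariates and exposome of a synthetic cohort
#'
#' Covariates (cohort, sex, age, zBMI, ancestry, maternal education, time
#' to last meal) are drawn per child. Exposure families are generated from
#' block-equicorrelated standard Gaussians (zero correlation across
#' families), the same variable in the two periods is correlated at the
#' scenario's cross-period correlation, and categorical exposures arise by
#' tertile-thresholding latent Gaussians. When the scenario declares the
#' adiposity confounding path, zBMI is added to the named pollutant
#' exposure with the declared coefficient.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with elements `exposome` (an [exposome_set()]),
#'   `covariates` (tibble) and `truth` (partial truth: confounder paths).
#' @export
simulate_cohort <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))
  cohorts <- sprintf("cohort_%d", seq_len(scenario$n_cohorts))
  covariates <- tibble(
    sample_id = sample_id,
    cohort = sample(rep_len(cohorts, n)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = round(runif(n, 6, 11), 2),
    zbmi = rnorm(n),
    ancestry = sample(
      c("european", "pakistani", "other"), n,
      replace = TRUE, prob = c(0.90, 0.08, 0.02)
    ),
    maternal_education = sample(
      c("low", "medium", "high"), n,
      replace = TRUE, prob = c(0.2, 0.4, 0.4)
    ),
    time_to_last_meal = round(runif(n, 1, 6), 2)
  )

  naming <- scenario_exposure_names(scenario)
  rho_p <- scenario$cross_period_correlation
  values <- list()
  for (f in seq_len(nrow(scenario$exposure_spec))) {
    spec <- scenario$exposure_spec[f, ]
    m <- spec$n_exposures
    sigma <- matrix(spec$rho, m, m)
    diag(sigma) <- 1
    ch <- tryCatch(chol(sigma), error = function(e) {
      abort(sprintf(
        "family '%s': implied correlation matrix is not positive definite",
        spec$family
      ))
    })
    z_preg <- matrix(rnorm(n * m), n, m) %*% ch
    z_ind <- matrix(rnorm(n * m), n, m) %*% ch
    z_child <- rho_p * z_preg + sqrt(1 - rho_p^2) * z_ind
    for (period in EXPOSURE_PERIODS) {
      z <- if (period == "pregnancy") z_preg else z_child
      fam_names <- naming$exposure[
        naming$family == spec$family & naming$period == period
      ]
      if (scenario$cohort_exposure_shift_sd > 0) {
        shift <- matrix(
          rnorm(scenario$n_cohorts * m, sd = scenario$cohort_exposure_shift_sd),
          scenario$n_cohorts, m,
          dimnames = list(cohorts, NULL)
        )
        z <- z + shift[covariates$cohort, , drop = FALSE]
      }
      for (j in seq_len(m)) values[[fam_names[j]]] <- z[, j]
    }
  }

  if (!is.null(scenario$confounding)) {
    cf <- scenario$confounding
    values[[cf$exposure]] <-
      values[[cf$exposure]] + cf$zbmi_to_exposure * covariates$zbmi
  }

  # Tertile-threshold the latent Gaussian for categorical exposures.
  cat_levels <- c("low", "medium", "high")
  cuts <- qnorm(c(1 / 3, 2 / 3))
  data <- tibble(sample_id = sample_id)
  levels_list <- vector("list", nrow(naming))
  for (i in seq_len(nrow(naming))) {
    nm <- naming$exposure[i]
    if (naming$vartype[i] == "categorical") {
      data[[nm]] <- cat_levels[findInterval(values[[nm]], cuts) + 1]
      levels_list[[i]] <- cat_levels
    } else {
      data[[nm]] <- values[[nm]]
    }
  }
  meta <- exposure_metadata(
    exposure = naming$exposure,
    period = naming$period,
    family = naming$family,
    vartype = naming$vartype,
    levels = levels_list
  )
  truth <- list(
    confounder_paths = if (is.null(scenario$confounding)) {
      tibble(from = character(), to = character(), coef = double())
    } else {
      tibble(
        from = "zbmi",
        to = c(scenario$confounding$exposure, scenario$confounding$feature),
        coef = c(
          scenario$confounding$zbmi_to_exposure,
          scenario$confounding$zbmi_to_feature
        )
      )
    }
  )
  list(
    exposome = exposome_set(data, meta),
    covariates = covariates,
    truth = truth
  )
}

#' Generate the multi-omics layers of a synthetic cohort
#'
#' Each feature is built as intercept + planted per-IQR exposure effects +
#' covariate signal (sex, age, zBMI, cohort offsets on a random subset of
#' features) + dense latent-factor contributions + Gaussian noise.
#' Methylation is simulated on the logit scale and squashed through the
#' inverse logit so its values stay in (0, 1); the recorded truth carries
#' the logit-scale coefficient. With a positive `cohort_heterogeneity`
#' the planted betas are multiplied by cohort-specific factors. The
#' adiposity scenario adds the zBMI-to-protein path while the direct
#' pollutant-to-protein effect stays exactly zero.
#'
#' @param scenario A [sim_scenario()].
#' @param exposome,covariates Output of [simulate_cohort()].
#' @return A list with `layers` (named list of [omics_layer()]) and
#'   `truth` (planted effects, latent loadings, confounder paths).
#' @export
simulate_multiomics <- function(scenario, exposome, covariates) {
  set.seed(scenario$seed + 1L)
  n <- nrow(covariates)
  cohorts <- sort(unique(covariates$cohort))
  feature_names <- scenario_feature_names(scenario)
  planted <- scenario$planted_effects
  if (nrow(planted) > 0) {
    planted <- left_join(planted, feature_names, by = c(feature = "feature_id"))
  } else {
    planted$layer <- character()
  }

  het_factors <- NULL
  if (scenario$cohort_heterogeneity > 0 && nrow(planted) > 0) {
    het_factors <- matrix(
      rnorm(length(cohorts) * nrow(planted),
        mean = 1, sd = scenario$cohort_heterogeneity
      ),
      length(cohorts), nrow(planted),
      dimnames = list(cohorts, NULL)
    )
  }

  sex_ind <- as.numeric(covariates$sex == "male")
  age_c <- covariates$age - mean(covariates$age)
  zbmi <- covariates$zbmi

  layers <- list()
  truth_effects <- list()
  loadings_list <- list()
  gene_pool <- sprintf("G%04d", seq_len(2000))
  for (li in seq_len(nrow(scenario$omics_spec))) {
    spec <- scenario$omics_spec[li, ]
    m <- spec$n_features
    ids <- feature_names$feature_id[feature_names$layer == spec$layer]
    is_meth <- spec$layer == "methylation"

    intercept <- if (is_meth) rnorm(m, 0, 0.4) else rnorm(m, 5, 1)
    y <- matrix(rep(intercept, each = n), n, m)

    # Covariate signal on a random subset of features.
    n_cov <- ceiling(scenario$covariate_effect_fraction * m)
    cov_idx <- sort(sample.int(m, n_cov))
    for (j in cov_idx) {
      b <- rnorm(3, 0, scenario$covariate_effect_sd)
      coh_off <- rnorm(length(cohorts), 0, scenario$covariate_effect_sd)
      names(coh_off) <- cohorts
      y[, j] <- y[, j] + b[1] * sex_ind + b[2] * age_c + b[3] * zbmi +
        coh_off[covariates$cohort]
    }

    # Dense latent factors (batch + cell composition stand-in) on
    # genome-wide layers.
    if (scenario$n_latent_factors > 0 && spec$layer %in% GENOME_WIDE_LAYERS) {
      scores <- matrix(rnorm(n * scenario$n_latent_factors), n)
      loadings <- matrix(0, m, scenario$n_latent_factors)
      for (k in seq_len(scenario$n_latent_factors)) {
        rows <- sample.int(m, ceiling(scenario$latent_feature_fraction * m))
        loadings[rows, k] <- rnorm(length(rows), 0, scenario$latent_loading_sd)
      }
      y <- y + scores %*% t(loadings)
      loadings_list[[spec$layer]] <- loadings
    }

    # Planted per-IQR effects.
    pl <- planted[planted$layer == spec$layer, , drop = FALSE]
    if (nrow(pl) > 0) {
      for (r in seq_len(nrow(pl))) {
        x <- exposome$data[[pl$exposure[r]]]
        xs <- x / iqr(x)
        j <- match(pl$feature[r], ids)
        if (is_meth) y[, j] <- y[, j] - intercept[j] # baseline 0.5
        beta <- rep(pl$beta[r], n)
        if (!is.null(het_factors)) {
          pr <- match(pl$feature[r], planted$feature)
          beta <- beta * het_factors[covariates$cohort, pr]
        }
        y[, j] <- y[, j] + beta * xs
      }
      truth_effects[[spec$layer]] <- tibble(
        exposure = pl$exposure, feature = pl$feature, layer = spec$layer,
        beta = pl$beta,
        scale = if (is_meth) "logit" else spec$scale
      )
    }

    if (!is.null(scenario$confounding)) {
      cf <- scenario$confounding
      j <- match(cf$feature, ids)
      if (!is.na(j)) y[, j] <- y[, j] + cf$zbmi_to_feature * zbmi
    }

    y <- y + matrix(rnorm(n * m, 0, spec$noise_sd), n, m)
    if (is_meth) y <- plogis(y)
    dimnames(y) <- list(covariates$sample_id, ids)

    features <- tibble(feature_id = ids)
    if (spec$layer %in% c("methylation", "expression")) {
      features$chrom <- sample(paste0("chr", 1:3), m, replace = TRUE)
      features$position <- round(runif(m, 1, 6e7))
      features$strand <- sample(c("+", "-"), m, replace = TRUE)
      features$gene <- if (spec$layer == "expression") {
        gene_pool[seq_len(m)]
      } else {
        sample(gene_pool[seq_len(max(m, 100))], m, replace = TRUE)
      }
    } else if (spec$layer == "protein") {
      features$gene <- sprintf("P%03d", seq_len(m))
    }
    layers[[spec$layer]] <- omics_layer(
      spec$layer, y,
      features = features, scale = spec$scale
    )
  }

  truth <- list(
    planted_effects = if (length(truth_effects) > 0) {
      bind_rows(truth_effects)
    } else {
      tibble(
        exposure = character(), feature = character(), layer = character(),
        beta = double(), scale = character()
      )
    },
    latent_factor_loadings = loadings_list,
    confounder_paths = if (is.null(scenario$confounding)) {
      tibble(from = character(), to = character(), coef = double())
    } else {
      tibble(
        from = "zbmi",
        to = c(scenario$confounding$exposure, scenario$confounding$feature),
        coef = c(
          scenario$confounding$zbmi_to_exposure,
          scenario$confounding$zbmi_to_feature
        )
      )
    }
  )
  list(layers = layers, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_cohort()] then
#' [simulate_multiomics()].
#'
#' @param scenario A [sim_scenario()].
#' @return A list with `exposome`, `covariates`, `layers`, `truth` and the
#'   `scenario` itself.
#' @export
simulate_study <- function(scenario) {
  cohort <- simulate_cohort(scenario)
  omics <- simulate_multiomics(scenario, cohort$exposome, cohort$covariates)
  list(
    exposome = cohort$exposome,
    covariates = cohort$covariates,
    layers = omics$layers,
    truth = omics$truth,
    scenario = scenario
  )
}

#' Write a simulated study as a fixture file set
#'
#' Writes the exposome matrix and metadata, the covariate table, every
#' omics matrix with its feature annotation, the planted-effect truth
#' table and a JSON manifest carrying the scenario hash, the seed and
#' content digests of every file.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_set <- function(study, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("directory '%s' is not empty (use overwrite = TRUE)", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, c("exposome.tsv", "exposome_meta.tsv"))
  write_exposome(study$exposome, p[1], p[2])
  paths <- c(paths, p)
  p <- file.path(dir, "covariates.tsv")
  readr::write_tsv(format_full_precision(study$covariates), p, progress = FALSE)
  paths <- c(paths, p)
  for (nm in names(study$layers)) {
    p <- file.path(dir, sprintf(c("layer_%s.tsv", "layer_%s_features.tsv"), nm))
    write_omics_layer(study$layers[[nm]], p[1], p[2])
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.tsv")
  readr::write_tsv(
    format_full_precision(study$truth$planted_effects), p,
    progress = FALSE
  )
  paths <- c(paths, p)
  manifest <- list(
    scenario_hash = rlang::hash(study$scenario),
    seed = study$scenario$seed,
    files = lapply(
      setNames(paths, basename(paths)),
      function(f) rlang::hash(readChar(f, file.info(f)$size, useBytes = TRUE))
    )
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
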