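#' Percent change in effect size between two model variants
#'
#' For each association present in both tables the change is
#' `(effect_main - effect_alt) / effect_main * 100`; associations with an
#' absolute change above 100 ("more than a doubling") are flagged.
#'
#' @param main Association records from the main model.
#' @param alt Association records from the alternative model (different
#'   `model_tag`).
#' @param by Key columns identifying an association.
#' @return Tibble keyed by association with `effect_main`, `effect_alt`,
#'   `percent_change` and `flagged`. A zero main effect yields `NA` with a
#'   warning.
#' @export
percent_effect_change <- function(main, alt,
                                  by = c(
                                    "exposure", "period", "feature",
                                    "layer", "contrast"
                                  )) {
  by <- intersect(by, intersect(names(main), names(alt)))
  joined <- inner_join(
    select(main, all_of(by), effect_main = "effect"),
    select(alt, all_of(by), effect_alt = "effect"),
    by = by
  )
  if (any(joined$effect_main == 0)) {
    warn("zero main-model effect(s): percent change undefined, set to NA")
  }
  mutate(joined,
    percent_change = ifelse(
      .data$effect_main == 0, NA_real_,
      (.data$effect_main - .data$effect_alt) / .data$effect_main * 100
    ),
    flagged = !is.na(.data$percent_change) & abs(.data$percent_change) > 100
  )
}

# DerSimonian-Laird fixed/random pooling of one association.
pool_one <- function(estimate, se, cohort) {
  bad <- se <= 0 | !is.finite(se) | !is.finite(estimate)
  if (any(bad)) {
    abort(sprintf(
      "non-positive or non-finite standard error for cohort(s): %s",
      compact_chr(cohort[bad])
    ))
  }
  k <- length(estimate)
  w <- 1 / se^2
  beta_fixed <- sum(w * estimate) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (k == 1) {
    return(tibble(
      k = 1L, beta_fixed = beta_fixed, se_fixed = se_fixed,
      beta_random = beta_fixed, se_random = se_fixed,
      tau2 = 0, q = 0, i2 = NA_real_
    ))
  }
  q <- sum(w * (estimate - beta_fixed)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  beta_random <- sum(wr * estimate) / sum(wr)
  se_random <- sqrt(1 / sum(wr))
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  tibble(
    k = as.integer(k), beta_fixed = beta_fixed, se_fixed = se_fixed,
    beta_random = beta_random, se_random = se_random,
    tau2 = tau2, q = q, i2 = i2
  )
}

#' Inverse-variance meta-analysis of per-cohort association estimates
#'
#' Pools cohort-specific effect estimates by fixed-effect inverse-variance
#' weighting and by DerSimonian-Laird random effects, reporting Cochran's
#' Q, the between-cohort variance tau-squared and the I-squared
#' heterogeneity percentage for every association.
#'
#' @param records Cohort-stratified association records (e.g. from
#'   [run_exwas_by_cohort()]) with columns `cohort`, `effect`, `se`.
#' @param by Key columns identifying an association.
#' @return A tibble of class `exwas_meta`, one row per association, with
#'   `k`, `beta_fixed`, `se_fixed`, `beta_random`, `se_random`, `tau2`,
#'   `q`, `i2`, plus a `cohorts` list column carrying the per-cohort
#'   estimates, standard errors and fixed weights. With a single cohort
#'   the pooled values equal the cohort estimate and `i2` is `NA`.
#' @export
cohort_meta_analysis <- function(records,
                                 by = c(
                                   "exposure", "period", "feature",
                                   "layer", "contrast"
                                 )) {
  stopifnot_cols(records, c("cohort", "effect", "se"), "cohort records")
  by <- intersect(by, names(records))
  out <- records |>
    group_by(across(all_of(by))) |>
    group_modify(function(d, key) {
      d <- d[order(d$cohort), , drop = FALSE]
      pooled <- pool_one(d$effect, d$se, d$cohort)
      pooled$cohorts <- list(tibble(
        cohort = d$cohort, estimate = d$effect, se = d$se,
        n = if ("n" %in% names(d)) d$n else NA_integer_,
        weight_pct = 100 * (1 / d$se^2) / sum(1 / d$se^2)
      ))
      pooled
    }) |>
    ungroup()
  class(out) <- c("exwas_meta", class(out))
  out
}

#' Select exposures for mutually adjusted multi-exposure models
#'
#' For each omics feature (within a period and layer) associated with
#' more than one exposure, selects the exposures eligible to enter one
#' joint model: one representative per correlation group (the member with
#' the smallest single-exposure p-value), then greedy removal of the
#' weaker member of any remaining pair whose correlation magnitude is at
#' or above the cutoff. Features left with fewer than two exposures are
#' dropped. Every exclusion is logged.
#'
#' @param records Flagged association records ([apply_correction()]);
#'   only rows with `significant == TRUE` are considered.
#' @param corr An [exposure_correlation()] result (or its matrix form).
#' @param meta Exposure metadata carrying `correlation_group`.
#' @param cutoff Correlation-magnitude cutoff (default 0.8, applied to
#'   the \[0, 1\] magnitude scale of the mixed-type measures).
#' @return A tibble of class `multi_exposure_sets`: one row per retained
#'   (feature, period, layer) with an `exposures` list column of tibbles
#'   (exposure, single-model effect, se, p), and an `exclusions`
#'   attribute logging every dropped exposure with its reason and the
#'   retained competitor.
#' @export
select_multi_exposure_sets <- function(records, corr, meta, cutoff = 0.8) {
  cmat <- if (inherits(corr, "exposure_cor")) cor_matrix(corr) else corr
  sig <- filter(records, .data$significant)
  # Collapse categorical contrasts: one row per exposure-feature pair,
  # keeping the smallest-p contrast.
  sig <- sig |>
    group_by(.data$feature, .data$period, .data$layer, .data$exposure) |>
    slice_min(.data$p, n = 1, with_ties = FALSE) |>
    ungroup() |>
    left_join(
      select(meta, "exposure", "correlation_group"),
      by = "exposure"
    )
  exclusions <- list()
  sets <- list()
  groups <- sig |>
    group_by(.data$feature, .data$period, .data$layer) |>
    group_split()
  for (g in groups) {
    key <- g[1, c("feature", "period", "layer")]
    if (nrow(g) < 2) next
    g <- arrange(g, .data$p, .data$exposure)
    # One representative per correlation group (smallest p, then name).
    reps <- g |>
      group_by(.data$correlation_group) |>
      slice(1) |>
      ungroup()
    dropped_group <- anti_join(g, reps, by = "exposure")
    if (nrow(dropped_group) > 0) {
      retained_map <- setNames(reps$exposure, reps$correlation_group)
      exclusions[[length(exclusions) + 1]] <- tibble(
        key,
        excluded = dropped_group$exposure,
        reason = "same_correlation_group",
        retained = unname(retained_map[dropped_group$correlation_group]),
        correlation = NA_real_
      )
    }
    # Greedy removal of highly correlated pairs, strongest p dropped.
    keep <- arrange(reps, .data$p, .data$exposure)
    missing <- setdiff(keep$exposure, rownames(cmat))
    if (length(missing) > 0) {
      abort(sprintf(
        "exposure(s) missing from the correlation matrix: %s",
        compact_chr(missing)
      ))
    }
    i <- 1L
    while (i < nrow(keep)) {
      j <- i + 1L
      while (j <= nrow(keep)) {
        r <- abs(cmat[keep$exposure[i], keep$exposure[j]])
        if (!is.na(r) && r >= cutoff) {
          exclusions[[length(exclusions) + 1]] <- tibble(
            key,
            excluded = keep$exposure[j],
            reason = "correlation_at_or_above_cutoff",
            retained = keep$exposure[i],
            correlation = r
          )
          keep <- keep[-j, ]
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (nrow(keep) < 2) {
      exclusions[[length(exclusions) + 1]] <- tibble(
        key,
        excluded = keep$exposure,
        reason = "fewer_than_two_exposures_left",
        retained = NA_character_,
        correlation = NA_real_
      )
      next
    }
    sets[[length(sets) + 1]] <- tibble(
      key,
      exposures = list(select(
        keep, "exposure", "contrast", "effect", "se", "p"
      ))
    )
  }
  out <- if (length(sets) > 0) {
    bind_rows(sets)
  } else {
    tibble(
      feature = character(), period = character(), layer = character(),
      exposures = list()
    )
  }
  attr(out, "exclusions") <- if (length(exclusions) > 0) {
    bind_rows(exclusions)
  } else {
    tibble(
      feature = character(), period = character(), layer = character(),
      excluded = character(), reason = character(), retained = character(),
      correlation = double()
    )
  }
  class(out) <- c("multi_exposure_sets", class(out))
  out
}

#' Fit the mutually adjusted multi-exposure models
#'
#' One joint ordinary-least-squares model per selected feature, entering
#' all selected exposures simultaneously (IQR-scaled or reference-coded)
#' together with the standard covariates and, for genome-wide layers,
#' surrogate variables. Each exposure's joint effect is compared with its
#' single-exposure effect via [percent_effect_change()]. A singular joint
#' design is refitted after dropping the collinear exposure, and the drop
#' is logged in the `dropped` attribute.
#'
#' @param sets Output of [select_multi_exposure_sets()].
#' @param exposome,layers,covariates,spec As in [run_exwas()].
#' @return Tibble with one row per (feature, exposure, contrast): joint
#'   effect, se, p, the single-model effect and the percent change
#'   between them.
#' @export
fit_multi_exposure <- function(sets, exposome, layers, covariates,
                               spec = exwas_spec()) {
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  names(layers) <- vapply(layers, function(l) l$layer, character(1))
  meta <- exposome$meta
  dropped <- list()
  out <- list()
  for (si in seq_len(nrow(sets))) {
    row <- sets[si, ]
    layer <- layers[[row$layer]]
    ids <- align_samples(
      exposome$data$sample_id, covariates$sample_id, rownames(layer$values)
    )
    cov <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
    base <- build_design(cov, c(spec$covariates, layer$technical_covariates))
    if (layer$genome_wide && !identical(spec$n_svs, 0)) {
      sv <- estimate_svs(
        layer, cov,
        k = spec$n_svs,
        covariate_names = c(spec$covariates, layer$technical_covariates),
        seed = spec$sv_seed
      )
      if (sv$k > 0) base <- cbind(base, sv$values[ids, , drop = FALSE])
    }
    singles <- row$exposures[[1]]
    x_all <- exposome$data[match(ids, exposome$data$sample_id), , drop = FALSE]
    build_cols <- function(exposures) {
      cols <- lapply(exposures, function(e) {
        mrow <- meta[meta$exposure == e, ]
        xc <- exposure_design(x_all[[e]], mrow, e)
        colnames(xc) <- ifelse(
          colnames(xc) == "__continuous__", e, paste(e, colnames(xc), sep = ":")
        )
        xc
      })
      do.call(cbind, cols)
    }
    exposures <- singles$exposure
    xc <- build_cols(exposures)
    y <- layer$values[ids, row$feature, drop = FALSE]
    fit <- NULL
    repeat {
      fit <- tryCatch(
        fit_design_block(y, base, xc),
        error = function(e) e
      )
      if (!inherits(fit, "error")) break
      # Drop the collinear exposure named in the error and refit.
      msg <- conditionMessage(fit)
      bad <- exposures[vapply(
        exposures, function(e) grepl(e, msg, fixed = TRUE), logical(1)
      )]
      if (length(bad) == 0 || length(exposures) <= 2) {
        abort(sprintf(
          "feature '%s': joint design unusable (%s)", row$feature, msg
        ))
      }
      dropped[[length(dropped) + 1]] <- tibble(
        feature = row$feature, period = row$period, layer = row$layer,
        exposure = bad[1], reason = "collinear_in_joint_design"
      )
      exposures <- setdiff(exposures, bad[1])
      xc <- build_cols(exposures)
    }
    fit$exposure <- purrr::map_chr(
      strsplit(fit$contrast, ":", fixed = TRUE), 1
    )
    fit$contrast <- purrr::map_chr(
      strsplit(fit$contrast, ":", fixed = TRUE),
      ~ if (length(.x) > 1) .x[2] else NA_character_
    )
    res <- fit |>
      left_join(
        select(singles,
          exposure = "exposure", single_effect = "effect",
          single_p = "p"
        ),
        by = "exposure"
      ) |>
      mutate(
        feature = row$feature, period = row$period, layer = row$layer,
        percent_change = ifelse(
          .data$single_effect == 0, NA_real_,
          (.data$single_effect - .data$effect) / .data$single_effect * 100
        )
      ) |>
      select(
        "feature", "period", "layer", "exposure", "contrast",
        effect_joint = "effect", se_joint = "se", p_joint = "p",
        "single_effect", "single_p", "percent_change"
      )
    out[[length(out) + 1]] <- res
  }
  res <- if (length(out) > 0) bind_rows(out) else tibble()
  attr(res, "dropped") <- if (length(dropped) > 0) {
    bind_rows(dropped)
  } else {
    tibble(
      feature = character(), period = character(), layer = character(),
      exposure = character(), reason = character()
    )
  }
  res
}
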