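#' Model specification for the association engine
#'
#' Names the adjustment covariates and the surrogate-variable policy used
#' by [run_exwas()]. The default covariate set matches the study design of
#' multi-cohort child studies: cohort, sex, age, zBMI, ancestry and
#' maternal education, plus any layer-specific technical covariates each
#' layer declares.
#'
#' @param covariates Covariate column names to adjust for.
#' @param adjust_zbmi Keep zBMI in the model? Setting `FALSE` yields the
#'   adiposity sensitivity variant.
#' @param n_svs `"auto"` (permutation parallel analysis), a fixed count,
#'   or `0` to disable surrogate variables. Only genome-wide layers are
#'   SV-adjusted.
#' @param restrict_to Optional character vector of sample IDs to restrict
#'   the analysis to (e.g. children of European ancestry).
#' @param model_tag Label stored on every association record.
#' @param sv_seed Seed for the surrogate-variable permutation analysis.
#' @param min_extra_samples Minimum number of samples required beyond the
#'   number of design columns.
#' @return A list of class `exwas_spec`.
#' @export
exwas_spec <- function(covariates = c(
                         "cohort", "sex", "age", "zbmi",
                         "ancestry", "maternal_education"
                       ),
                       adjust_zbmi = TRUE,
                       n_svs = "auto",
                       restrict_to = NULL,
                       model_tag = NULL,
                       sv_seed = 1,
                       min_extra_samples = 10) {
  if (!adjust_zbmi) covariates <- setdiff(covariates, "zbmi")
  if (is.null(model_tag)) {
    model_tag <- if (adjust_zbmi) "main" else "no_zbmi"
  }
  structure(
    list(
      covariates = covariates,
      adjust_zbmi = adjust_zbmi,
      n_svs = n_svs,
      restrict_to = restrict_to,
      model_tag = model_tag,
      sv_seed = sv_seed,
      min_extra_samples = min_extra_samples
    ),
    class = "exwas_spec"
  )
}

# Expand a covariate tibble into a full-rank design matrix with intercept.
build_design <- function(covariates, covariate_names) {
  covariate_names <- intersect(covariate_names, names(covariates))
  if (length(covariate_names) == 0) {
    return(matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(covariates[, covariate_names, drop = FALSE])
  for (nm in names(df)) {
    if (is.character(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]], levels = sort(unique(df[[nm]])))
    }
    # constant columns (e.g. ancestry after an ancestry restriction)
    # carry no information and would make the design singular
    if (length(unique(df[[nm]])) < 2) df[[nm]] <- NULL
  }
  if (length(df) == 0) {
    return(matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)")))
  }
  model.matrix(~., data = df)
}

#' Estimate surrogate variables for a genome-wide omics layer
#'
#' Residualizes the feature matrix on the known covariates and takes the
#' top left singular vectors of the residual matrix as surrogate
#' variables, capturing unmeasured structure such as batch effects and
#' blood cell composition. With `k = "auto"` the number of components is
#' chosen by permutation parallel analysis: each residual column is
#' independently permuted `n_perm` times, and components are retained
#' while their singular value exceeds the 95th percentile of the matching
#' permuted singular values.
#'
#' @param layer A genome-wide [omics_layer()].
#' @param covariates Covariate tibble with `sample_id`.
#' @param k `"auto"` or a fixed non-negative component count.
#' @param covariate_names Known covariates to residualize on.
#' @param n_perm Number of column permutations for parallel analysis.
#' @param seed Seed for the permutations (RNG state is restored).
#' @return An object of class `sv_set`: list with `layer`, `values`
#'   (sample-by-K matrix of unit-variance columns), `k`, `method_tag`.
#' @export
estimate_svs <- function(layer, covariates, k = "auto",
                         covariate_names = c(
                           "cohort", "sex", "age", "zbmi",
                           "ancestry", "maternal_education"
                         ),
                         n_perm = 20, seed = 1) {
  if (!inherits(layer, "omics_layer")) abort("layer must be an omics_layer")
  if (!layer$genome_wide) {
    abort(sprintf(
      "surrogate variables are only computed for genome-wide layers, not '%s'",
      layer$layer
    ))
  }
  ids <- align_samples(rownames(layer$values), covariates$sample_id)
  y <- layer$values[ids, , drop = FALSE]
  cov <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  x <- build_design(cov, covariate_names)
  qrx <- qr(x)
  r <- qr.resid(qrx, y)
  n <- nrow(r)
  sv <- svd(r)
  if (identical(k, "auto")) {
    n_keep <- min(n - ncol(x), ncol(r))
    perm_d <- with_preserved_seed(seed, {
      ss_r <- sum(r^2)
      t(vapply(seq_len(n_perm), function(b) {
        # re-residualize so permuted matrices share the observed residual
        # rank, then rescale to the observed total sum of squares: the
        # projection removes variance a second time and would otherwise
        # bias the null singular values low
        rp <- qr.resid(qrx, apply(r, 2, sample))
        rp <- rp * sqrt(ss_r / sum(rp^2))
        svd(rp, nu = 0, nv = 0)$d
      }, numeric(length(sv$d))))
    })
    thresh <- apply(perm_d, 2, quantile, probs = 0.95, names = FALSE)
    keep <- sv$d > thresh
    k <- if (!keep[1]) 0L else min(which(!c(keep, FALSE))[1] - 1L, n_keep)
  }
  k <- as.integer(k)
  if (k >= n) abort("requested more surrogate variables than samples")
  values <- sv$u[, seq_len(k), drop = FALSE]
  if (k > 0) values <- scale(values, center = TRUE, scale = TRUE)[, , drop = FALSE]
  rownames(values) <- ids
  colnames(values) <- if (k > 0) sprintf("SV%d", seq_len(k)) else character()
  structure(
    list(
      layer = layer$layer, values = values, k = k,
      method_tag = "residual_svd_parallel_analysis"
    ),
    class = "sv_set"
  )
}

# Core vectorized OLS of every feature on [covariate design | exposure
# columns]; returns one row per exposure column per feature.
fit_design_block <- function(y, base_design, x_cols) {
  d <- cbind(base_design, x_cols)
  n <- nrow(d)
  p <- ncol(d)
  qrd <- qr(d)
  if (qrd$rank < p) {
    bad <- colnames(d)[qrd$pivot[(qrd$rank + 1):p]]
    abort(sprintf("singular design; collinear column(s): %s", compact_chr(bad)))
  }
  coef <- qr.coef(qrd, y)
  res <- qr.resid(qrd, y)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtxinv_diag <- diag(chol2inv(chol(crossprod(d))))
  idx <- (ncol(base_design) + 1):p
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    j <- idx[i]
    effect <- coef[j, ]
    se <- sqrt(sigma2 * xtxinv_diag[j])
    tval <- effect / se
    pval <- 2 * pt(-abs(tval), df)
    out[[i]] <- tibble(
      feature = colnames(y),
      contrast = colnames(d)[j],
      effect = unname(effect),
      se = unname(se),
      p = pmax(unname(pval), .Machine$double.xmin),
      n = n
    )
  }
  bind_rows(out)
}

# Exposure design columns: IQR-scaled continuous value or reference-coded
# indicators for observed non-reference levels.
exposure_design <- function(x, meta_row, exposure, iqr_ref = NULL) {
  if (meta_row$vartype == "continuous") {
    s <- iqr_ref %||% iqr(x)
    if (s == 0) {
      abort(sprintf("degenerate exposure '%s': IQR is zero", exposure))
    }
    matrix(x / s, ncol = 1, dimnames = list(NULL, "__continuous__"))
  } else {
    lv <- meta_row$levels[[1]]
    observed <- lv[lv %in% unique(x)]
    f <- factor(x, levels = observed)
    mm <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- observed[-1]
    mm
  }
}

#' Fit a single exposure-feature association
#'
#' The per-pair building block of the association engine: an ordinary
#' least-squares regression of one molecular feature on one exposure plus
#' adjustment covariates. Continuous exposures enter scaled by their IQR
#' so the coefficient reads as the per-IQR effect (a log2 fold change for
#' log2-scale layers, a methylation difference for beta-scale layers);
#' categorical exposures yield one record per non-reference level.
#'
#' @param x Exposure values.
#' @param y Feature values.
#' @param covariates Optional covariate data frame (columns expanded to a
#'   design with intercept); `NULL` means intercept only.
#' @param vartype `"continuous"` or `"categorical"`.
#' @param levels Ordered level labels for categorical exposures (first =
#'   reference).
#' @param exposure,feature,layer,period,family,model_tag Record labels.
#' @param min_extra_samples Required samples beyond the design column
#'   count (default 10; set to 0 for closed-form toy designs).
#' @return A tibble of association records (one per contrast).
#' @export
fit_association <- function(x, y, covariates = NULL,
                            vartype = "continuous", levels = NULL,
                            exposure = "exposure", feature = "feature",
                            layer = NA_character_, period = NA_character_,
                            family = NA_character_, model_tag = "single",
                            min_extra_samples = 10) {
  base <- if (is.null(covariates)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    build_design(as_tibble(covariates), names(covariates))
  }
  meta_row <- tibble(
    vartype = vartype,
    levels = list(levels)
  )
  xc <- exposure_design(x, meta_row, exposure)
  if (length(y) < ncol(base) + ncol(xc) + min_extra_samples) {
    abort("too few samples for the requested design")
  }
  ym <- matrix(y, ncol = 1, dimnames = list(NULL, feature))
  res <- fit_design_block(ym, base, xc)
  transmute(res,
    exposure = .env$exposure, period = .env$period, family = .env$family,
    feature = .data$feature, layer = .env$layer,
    contrast = ifelse(.data$contrast == "__continuous__",
      NA_character_, .data$contrast
    ),
    effect = .data$effect, se = .data$se, p = .data$p, n = .data$n,
    model_tag = .env$model_tag
  )
}

#' Run the exposome-omics-wide association study
#'
#' Regresses every molecular feature of every layer on every exposure of
#' both exposure periods, adjusting for the specified covariates, each
#' layer's technical covariates, and (for genome-wide layers) surrogate
#' variables. Continuous exposures are IQR-scaled; categorical exposures
#' produce one record per non-reference level. Per-layer sample
#' availability is respected: each record's `n` is the size of that
#' layer's aligned sample set.
#'
#' @param exposome An [exposome_set()].
#' @param layers A named list of [omics_layer()] objects (or a single
#'   layer).
#' @param covariates Covariate tibble with `sample_id`.
#' @param spec An [exwas_spec()].
#' @param svs Optional named list of precomputed `sv_set` objects (or
#'   sample-by-K matrices) keyed by layer name; otherwise estimated
#'   per layer when the spec requests them.
#' @param iqr_ref Optional named vector of reference IQRs per continuous
#'   exposure. Cohort- or subset-restricted refits pass the whole-study
#'   IQRs here so that per-IQR effects stay on a common scale across
#'   strata.
#' @return A tibble of class `exwas_tbl` with columns `exposure`,
#'   `period`, `family`, `feature`, `layer`, `contrast`, `effect`, `se`,
#'   `p`, `n`, `model_tag`, ordered by (period, layer, exposure,
#'   feature).
#' @export
run_exwas <- function(exposome, layers, covariates, spec = exwas_spec(),
                      svs = NULL, iqr_ref = NULL) {
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  names(layers) <- vapply(layers, function(l) l$layer, character(1))
  meta <- exposome$meta
  out <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    layer <- layers[[li]]
    ids <- align_samples(
      exposome$data$sample_id, covariates$sample_id, rownames(layer$values)
    )
    if (!is.null(spec$restrict_to)) ids <- ids[ids %in% spec$restrict_to]
    cov_names <- c(spec$covariates, layer$technical_covariates)
    cov <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
    base <- build_design(cov, cov_names)
    if (length(ids) < ncol(base) + 1 + spec$min_extra_samples) {
      abort(sprintf(
        "layer '%s': sample intersection (n=%d) below the minimum model size",
        layer$layer, length(ids)
      ))
    }
    if (layer$genome_wide && !identical(spec$n_svs, 0) &&
      !identical(spec$n_svs, 0L)) {
      sv <- svs[[layer$layer]]
      if (is.null(sv)) {
        sv <- estimate_svs(
          layer, cov,
          k = spec$n_svs,
          covariate_names = cov_names, seed = spec$sv_seed
        )
      }
      svv <- if (inherits(sv, "sv_set")) sv$values else sv
      svv <- svv[match(ids, rownames(svv)), , drop = FALSE]
      if (anyNA(svv)) {
        abort(sprintf(
          "surrogate variables for layer '%s' do not cover all samples",
          layer$layer
        ))
      }
      if (ncol(svv) > 0) base <- cbind(base, svv)
    }
    y <- layer$values[ids, , drop = FALSE]
    x_all <- exposome$data[match(ids, exposome$data$sample_id), , drop = FALSE]
    layer_out <- vector("list", nrow(meta))
    for (ei in seq_len(nrow(meta))) {
      mrow <- meta[ei, ]
      xc <- exposure_design(
        x_all[[mrow$exposure]], mrow, mrow$exposure,
        iqr_ref = iqr_ref[[mrow$exposure]]
      )
      if (nrow(y) < ncol(base) + ncol(xc) + spec$min_extra_samples) {
        abort(sprintf(
          "layer '%s': too few samples for exposure '%s'",
          layer$layer, mrow$exposure
        ))
      }
      res <- fit_design_block(y, base, xc)
      res$exposure <- mrow$exposure
      res$period <- mrow$period
      res$family <- mrow$family
      res$layer <- layer$layer
      layer_out[[ei]] <- res
    }
    out[[li]] <- bind_rows(layer_out)
  }
  records <- bind_rows(out)
  records <- transmute(records,
    exposure = .data$exposure, period = .data$period, family = .data$family,
    feature = .data$feature, layer = .data$layer,
    contrast = ifelse(.data$contrast == "__continuous__",
      NA_character_, .data$contrast
    ),
    effect = .data$effect, se = .data$se, p = .data$p, n = .data$n,
    model_tag = spec$model_tag
  )
  records <- arrange(
    records,
    match(.data$period, EXPOSURE_PERIODS),
    match(.data$layer, OMICS_LAYERS),
    .data$exposure, .data$feature, .data$contrast
  )
  class(records) <- c("exwas_tbl", class(records))
  attr(records, "spec") <- spec
  records
}

#' Run the association study separately within each cohort
#'
#' Refits the per-exposure models cohort by cohort (dropping the cohort
#' covariate) so that estimates can be pooled by inverse-variance
#' meta-analysis. Surrogate variables are re-estimated within a cohort
#' when it has at least `min_cohort_n` samples; smaller cohorts reuse the
#' globally estimated surrogate variables restricted to their samples.
#'
#' @inheritParams run_exwas
#' @param min_cohort_n Minimum cohort size for within-cohort surrogate
#'   variable estimation.
#' @return An `exwas_tbl` with an additional `cohort` column.
#' @export
run_exwas_by_cohort <- function(exposome, layers, covariates,
                                spec = exwas_spec(), min_cohort_n = 100) {
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  names(layers) <- vapply(layers, function(l) l$layer, character(1))
  cohort_spec <- spec
  cohort_spec$covariates <- setdiff(spec$covariates, "cohort")
  global_svs <- list()
  for (layer in layers) {
    if (layer$genome_wide && !identical(spec$n_svs, 0)) {
      global_svs[[layer$layer]] <- estimate_svs(
        layer, covariates,
        k = spec$n_svs,
        covariate_names = c(spec$covariates, layer$technical_covariates),
        seed = spec$sv_seed
      )
    }
  }
  # whole-study IQRs keep per-IQR effects on one scale across cohorts
  cont <- exposome$meta$exposure[exposome$meta$vartype == "continuous"]
  iqr_ref <- vapply(cont, function(e) iqr(exposome$data[[e]]), numeric(1))
  cohorts <- sort(unique(covariates$cohort))
  out <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    ids <- covariates$sample_id[covariates$cohort == cohorts[ci]]
    sub_spec <- cohort_spec
    sub_spec$restrict_to <- intersect(spec$restrict_to %||% ids, ids)
    svs <- if (length(ids) >= min_cohort_n) NULL else global_svs
    res <- run_exwas(exposome, layers, covariates, sub_spec,
      svs = svs, iqr_ref = iqr_ref
    )
    res$cohort <- cohorts[ci]
    out[[ci]] <- res
  }
  records <- bind_rows(out)
  class(records) <- c("exwas_tbl", class(records))
  attr(records, "spec") <- spec
  records
}
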