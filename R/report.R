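#' Export the association catalogue
#'
#' The public catalogue convention: targeted layers keep all rows;
#' genome-wide layers keep only rows with `p < p_cutoff` (default 0.01)
#' to keep the export tractable.
#'
#' @param records Flagged association records.
#' @param path Optional output file (tab-delimited).
#' @param p_cutoff Filter for genome-wide layer rows.
#' @return The exported tibble (invisibly when `path` is given).
#' @export
export_catalogue <- function(records, path = NULL, p_cutoff = 0.01) {
  out <- filter(
    records,
    !(.data$layer %in% GENOME_WIDE_LAYERS) | .data$p < p_cutoff
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}

#' Plot-ready table for a Miami plot
#'
#' One row per association: the signed log p-value
#' (`-log10(p)` multiplied by the sign of the effect), the exposure
#' family grouping and a seeded jitter column for the x position, so
#' associations of one exposure spread around its family slot. Zero or
#' underflowing p-values are capped at the smallest positive double.
#'
#' @param records Association records.
#' @param period Optional period filter.
#' @param seed Jitter seed (RNG state is restored).
#' @return Tibble with `exposure`, `family`, `feature`, `layer`,
#'   `signed_log10p`, `x`, `jitter`.
#' @export
miami_table <- function(records, period = NULL, seed = 1) {
  if (!is.null(period)) {
    records <- filter(records, .data$period == .env$period)
  }
  n_under <- sum(records$p <= .Machine$double.xmin)
  if (n_under > 0) {
    inform(sprintf("%d p-value(s) at or below double precision capped", n_under))
  }
  fams <- sort(unique(records$family))
  expos <- sort(unique(records$exposure))
  jit <- with_preserved_seed(seed, runif(length(expos), -0.3, 0.3))
  names(jit) <- expos
  records |>
    mutate(
      signed_log10p = sign(.data$effect) *
        -log10(pmax(.data$p, .Machine$double.xmin)),
      jitter = unname(jit[.data$exposure]),
      x = match(.data$family, fams) + .data$jitter
    ) |>
    select(
      "exposure", "period", "family", "feature", "layer",
      "effect", "p", "signed_log10p", "x", "jitter"
    )
}

#' Plot-ready table for forest plots of meta-analysed associations
#'
#' Per association: one row per cohort (estimate, confidence bounds,
#' inverse-variance weight percentage) followed by the pooled fixed- and
#' random-effects rows with their confidence intervals and the I-squared
#' annotation.
#'
#' @param meta An `exwas_meta` table from [cohort_meta_analysis()].
#' @param level Confidence level (default 0.95).
#' @param by Key columns identifying an association.
#' @return A long tibble with `row_type` (`"cohort"`, `"fixed"`,
#'   `"random"`), `label`, `estimate`, `conf_low`, `conf_high`,
#'   `weight_pct`, `i2`.
#' @export
forest_table <- function(meta, level = 0.95,
                         by = c(
                           "exposure", "period", "feature", "layer",
                           "contrast"
                         )) {
  z <- qnorm(1 - (1 - level) / 2)
  by <- intersect(by, names(meta))
  per_assoc <- function(row) {
    cohorts <- row$cohorts[[1]] |>
      transmute(
        row_type = "cohort", label = .data$cohort,
        estimate = .data$estimate,
        conf_low = .data$estimate - z * .data$se,
        conf_high = .data$estimate + z * .data$se,
        weight_pct = .data$weight_pct, i2 = NA_real_
      )
    pooled <- tibble(
      row_type = c("fixed", "random"),
      label = c("fixed effects", "random effects"),
      estimate = c(row$beta_fixed, row$beta_random),
      conf_low = c(
        row$beta_fixed - z * row$se_fixed,
        row$beta_random - z * row$se_random
      ),
      conf_high = c(
        row$beta_fixed + z * row$se_fixed,
        row$beta_random + z * row$se_random
      ),
      weight_pct = NA_real_,
      i2 = row$i2
    )
    bind_rows(cohorts, pooled)
  }
  meta |>
    rowwise() |>
    group_split() |>
    purrr::map(function(row) {
      bind_cols(
        row[rep(1, nrow(row$cohorts[[1]]) + 2), by, drop = FALSE],
        per_assoc(row)
      )
    }) |>
    bind_rows()
}

#' Run the full association pipeline on a configuration
#'
#' Orchestrates the stages end to end: simulate (or load) the cohort,
#' run the exposome-omics-wide association study, apply layered
#' multiple-testing correction, meta-analyse the significant associations
#' by cohort, build the period networks with communities, export the
#' catalogue and plot-ready tables, and write a manifest with content
#' digests of every output. A stage failure halts the pipeline with the
#' stage name; outputs of completed stages are preserved.
#'
#' @param config A configuration list or path to a YAML file (see
#'   [read_run_config()]). Either `scenario: helix_mini` (plus optional
#'   `seed`) for a synthetic run, or file paths `exposome`,
#'   `exposome_meta`, `covariates` and a `layers` list naming each
#'   layer's matrix/scale.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a list with the main result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    abort(sprintf("directory '%s' is not empty (use overwrite = TRUE)", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf(
        "pipeline stage '%s' failed: %s (partial outputs kept in %s)",
        name, conditionMessage(e), out_dir
      ))
    })
  }
  alpha <- config$alpha %||% 0.05
  global_cutoff <- config$global_cutoff %||% 1e-9

  data <- stage("load", {
    if (!is.null(config$scenario)) {
      scenario <- if (identical(config$scenario, "helix_mini")) {
        helix_mini_scenario(seed = config$seed %||% 1)
      } else {
        do.call(sim_scenario, config$scenario)
      }
      simulate_study(scenario)
    } else {
      for (f in c("exposome", "exposome_meta", "covariates")) {
        if (is.null(config[[f]]) || !file.exists(config[[f]])) {
          abort(sprintf("input file for '%s' missing or not found", f))
        }
      }
      layers <- lapply(config$layers, function(l) {
        if (!file.exists(l$path)) abort(sprintf("layer file not found: %s", l$path))
        load_omics_layer(
          l$path, l$layer,
          scale = l$scale %||% "log2",
          annotation_path = l$annotation
        )
      })
      names(layers) <- vapply(layers, function(l) l$layer, character(1))
      list(
        exposome = load_exposome(config$exposome, config$exposome_meta),
        covariates = readr::read_tsv(config$covariates,
          show_col_types = FALSE, progress = FALSE
        ),
        layers = layers
      )
    }
  })

  spec <- exwas_spec(n_svs = config$n_svs %||% "auto")
  records <- stage("exwas", {
    run_exwas(data$exposome, data$layers, data$covariates, spec)
  })
  flagged <- stage("correction", {
    apply_correction(records, data$layers,
      alpha = alpha,
      global_cutoff = global_cutoff
    )
  })
  write_association_table(flagged, file.path(out_dir, "associations.tsv"))
  readr::write_tsv(
    correction_rules(flagged), file.path(out_dir, "correction_rules.tsv"),
    progress = FALSE
  )

  meta <- stage("meta_analysis", {
    sig <- filter(flagged, .data$significant)
    if (nrow(sig) == 0) {
      NULL
    } else {
      sub_expo <- data$exposome
      sub_meta <- filter(sub_expo$meta, .data$exposure %in% sig$exposure)
      sub_expo <- exposome_set(
        data$exposome$data[, c("sample_id", sub_meta$exposure)], sub_meta
      )
      keep_layers <- data$layers[unique(sig$layer)]
      keep_layers <- lapply(keep_layers, function(l) {
        feats <- intersect(colnames(l$values), sig$feature)
        omics_layer(
          l$layer, l$values[, feats, drop = FALSE],
          features = l$features[l$features$feature_id %in% feats, ],
          scale = l$scale,
          technical_covariates = l$technical_covariates
        )
      })
      by_cohort <- run_exwas_by_cohort(
        sub_expo, keep_layers, data$covariates, spec
      )
      by_cohort <- semi_join(
        by_cohort, sig,
        by = c("exposure", "feature", "layer", "period")
      )
      cohort_meta_analysis(by_cohort)
    }
  })
  if (!is.null(meta)) {
    readr::write_tsv(
      select(meta, -"cohorts"), file.path(out_dir, "meta_analysis.tsv"),
      progress = FALSE
    )
    readr::write_tsv(
      forest_table(meta), file.path(out_dir, "forest_table.tsv"),
      progress = FALSE
    )
  }

  stage("multi_exposure", {
    sig <- filter(flagged, .data$significant)
    multi_hit <- sig |>
      count(.data$feature, .data$period, .data$layer) |>
      filter(.data$n > 1)
    if (nrow(multi_hit) > 0) {
      ec <- exposure_correlation(data$exposome)
      sets <- select_multi_exposure_sets(
        flagged, ec, data$exposome$meta,
        cutoff = config$correlation_cutoff %||% 0.8
      )
      if (nrow(sets) > 0) {
        joint <- fit_multi_exposure(
          sets, data$exposome, data$layers, data$covariates, spec
        )
        readr::write_tsv(
          joint, file.path(out_dir, "multi_exposure_models.tsv"),
          progress = FALSE
        )
        readr::write_tsv(
          attr(sets, "exclusions"),
          file.path(out_dir, "multi_exposure_exclusions.tsv"),
          progress = FALSE
        )
      }
    }
  })

  stage("cross_layer", {
    ly <- data$layers
    if (all(c("methylation", "expression") %in% names(ly)) &&
      "position" %in% names(ly$methylation$features)) {
      sig_meth <- filter(
        flagged, .data$significant, .data$layer == "methylation"
      )
      sig_cpgs <- unique(sig_meth$feature)
      if (length(sig_cpgs) > 0) {
        cpg_ann <- filter(
          ly$methylation$features, .data$feature_id %in% sig_cpgs
        )
        pairs <- pair_cis_eqtm(
          cpg_ann, ly$expression$features,
          window = config$cis_window %||% 5e5
        )
        if (nrow(pairs) > 0) {
          eqtm <- fit_eqtm(
            pairs, ly$methylation, ly$expression, data$covariates,
            alpha = alpha
          )
          readr::write_tsv(
            eqtm, file.path(out_dir, "eqtm.tsv"),
            progress = FALSE
          )
        }
      }
    }
    if (!is.null(config$metabolite_map) &&
      all(c("urine_metab", "serum_metab") %in% names(ly))) {
      map <- readr::read_tsv(config$metabolite_map,
        show_col_types = FALSE, progress = FALSE
      )
      disc <- filter(
        flagged, .data$significant, .data$layer == "urine_metab"
      )
      rep_res <- cross_matrix_replication(
        disc, filter(flagged, .data$layer == "serum_metab"), map,
        alpha_nominal = alpha
      )
      readr::write_tsv(
        rep_res$pairs, file.path(out_dir, "replication_urine_serum.tsv"),
        progress = FALSE
      )
    }
  })

  networks <- stage("network", {
    nets <- list()
    for (period in EXPOSURE_PERIODS) {
      sig <- filter(flagged, .data$significant, .data$period == .env$period)
      if (nrow(sig) == 0) next
      net <- build_assoc_network(sig, period)
      if (nrow(net$edges) > 0) net <- detect_communities(net)
      write_network(net, file.path(out_dir, paste0("network_", period)))
      readr::write_tsv(
        network_stats(net),
        file.path(out_dir, sprintf("network_%s_stats.tsv", period)),
        progress = FALSE
      )
      if ("cluster_id" %in% names(net$nodes)) {
        readr::write_tsv(
          cluster_summary(net),
          file.path(out_dir, sprintf("network_%s_clusters.tsv", period)),
          progress = FALSE
        )
      }
      nets[[period]] <- net
    }
    nets
  })

  stage("report", {
    export_catalogue(
      flagged, file.path(out_dir, "catalogue.tsv"),
      p_cutoff = config$catalogue_p_cutoff %||% 0.01
    )
    for (period in EXPOSURE_PERIODS) {
      readr::write_tsv(
        miami_table(flagged, period, seed = config$seed %||% 1),
        file.path(out_dir, sprintf("miami_%s.tsv", period)),
        progress = FALSE
      )
    }
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(
      list.files(out_dir, recursive = TRUE), "manifest.json"
    ))
    m <- list(
      config_hash = rlang::hash(config),
      files = lapply(setNames(files, files), function(f) {
        p <- file.path(out_dir, f)
        rlang::hash(readChar(p, file.info(p)$size, useBytes = TRUE))
      })
    )
    jsonlite::write_json(
      m, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    m
  })
  invisible(list(
    records = flagged, meta = meta, networks = networks, manifest = manifest
  ))
}
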