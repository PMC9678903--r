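#' Pair CpGs with transcript clusters in cis
#'
#' Pairs every transcript cluster with all CpGs on the same chromosome
#' whose position lies strictly closer than `window` base pairs to the
#' transcript's transcription start site. Features without coordinates
#' are skipped and counted.
#'
#' @param cpg_features Annotation tibble for methylation features
#'   (`feature_id`, `chrom`, `position`).
#' @param tc_features Annotation tibble for expression features
#'   (`feature_id`, `chrom`, `position` = strand-resolved TSS).
#' @param window Window size in bp (default 500000; the boundary is
#'   exclusive: a distance of exactly `window` is not paired).
#' @return Tibble with `cpg_id`, `tc_id`, `chrom`, `distance`, plus an
#'   attribute `n_skipped` counting features without coordinates.
#' @export
pair_cis_eqtm <- function(cpg_features, tc_features, window = 5e5) {
  stopifnot_cols(cpg_features, c("feature_id", "chrom", "position"), "CpG annotation")
  stopifnot_cols(tc_features, c("feature_id", "chrom", "position"), "TC annotation")
  cpg <- filter(cpg_features, !is.na(.data$chrom) & !is.na(.data$position))
  tc <- filter(tc_features, !is.na(.data$chrom) & !is.na(.data$position))
  n_skipped <- (nrow(cpg_features) - nrow(cpg)) + (nrow(tc_features) - nrow(tc))
  if (n_skipped > 0) {
    inform(sprintf("%d feature(s) without coordinates skipped", n_skipped))
  }
  pairs <- inner_join(
    select(cpg, cpg_id = "feature_id", "chrom", cpg_pos = "position"),
    select(tc, tc_id = "feature_id", "chrom", tss = "position"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(distance = abs(.data$cpg_pos - .data$tss)) |>
    filter(.data$distance < window) |>
    select("cpg_id", "tc_id", "chrom", "distance") |>
    arrange(.data$tc_id, .data$cpg_id)
  attr(pairs, "n_skipped") <- n_skipped
  pairs
}

#' Fit cis expression-methylation (eQTM) models
#'
#' For every candidate CpG-transcript pair, an ordinary least-squares
#' regression of gene expression on methylation level adjusted for age,
#' sex and cohort; significance is Benjamini-Hochberg FDR across all
#' pairs.
#'
#' @param pairs Candidate pairs from [pair_cis_eqtm()].
#' @param methylation,expression The two [omics_layer()] objects.
#' @param covariates Covariate tibble with `sample_id`.
#' @param covariate_names Adjustment covariates (default age, sex,
#'   cohort).
#' @param alpha FDR level for the `significant` flag.
#' @return Tibble with `cpg_id`, `tc_id`, `distance`, `estimate`, `se`,
#'   `p`, `q`, `significant`, `n`. Zero-variance methylation features are
#'   dropped with a message.
#' @export
fit_eqtm <- function(pairs, methylation, expression, covariates,
                     covariate_names = c("age", "sex", "cohort"),
                     alpha = 0.05) {
  ids <- align_samples(
    rownames(methylation$values), rownames(expression$values),
    covariates$sample_id
  )
  cov <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  base <- build_design(cov, covariate_names)
  meth <- methylation$values[ids, , drop = FALSE]
  expr <- expression$values[ids, , drop = FALSE]
  usable_cpg <- colnames(meth)[apply(meth, 2, sd) > 0]
  dropped <- setdiff(unique(pairs$cpg_id), usable_cpg)
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d pair(s) dropped for zero-variance methylation", sum(pairs$cpg_id %in% dropped)
    ))
  }
  pairs <- filter(
    pairs, .data$cpg_id %in% usable_cpg, .data$tc_id %in% colnames(expr)
  )
  out <- purrr::pmap(
    pairs[, c("cpg_id", "tc_id", "distance")],
    function(cpg_id, tc_id, distance) {
      y <- matrix(expr[, tc_id], ncol = 1, dimnames = list(NULL, tc_id))
      xc <- matrix(meth[, cpg_id],
        ncol = 1,
        dimnames = list(NULL, "methylation")
      )
      fit <- fit_design_block(y, base, xc)
      tibble(
        cpg_id = cpg_id, tc_id = tc_id, distance = distance,
        estimate = fit$effect, se = fit$se, p = fit$p, n = fit$n
      )
    }
  )
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(mutate(res, q = double(), significant = logical()))
  }
  res$q <- bh_fdr(res$p)
  res$significant <- res$q <= alpha
  res
}

#' Concordant miRNA-target associations
#'
#' Given the significant miRNA associations and the full table of
#' transcript-cluster associations, retains each (exposure, miRNA,
#' target gene) triple for which the target transcript is nominally
#' associated (`p < alpha_nominal`) with the same exposure and with the
#' opposite effect sign (higher miRNA, lower target expression).
#'
#' @param mirna_hits Significant miRNA association records.
#' @param tc_records All transcript-cluster association records, with a
#'   `gene` column or accompanied by `tc_genes`.
#' @param target_map Tibble `mirna_id`, `gene`: the externally supplied
#'   experimentally validated target map.
#' @param tc_genes Optional tibble `feature_id`, `gene` annotating the
#'   transcript clusters (used when `tc_records` has no `gene` column).
#' @param alpha_nominal Nominal significance level (default 0.05).
#' @return Tibble of concordant triples: `exposure`, `mirna`, `gene`,
#'   `tc_feature`, effects and p-values of both sides. miRNAs absent from
#'   the map contribute nothing and are counted in the `n_unmapped`
#'   attribute.
#' @export
mirna_target_concordance <- function(mirna_hits, tc_records, target_map,
                                     tc_genes = NULL, alpha_nominal = 0.05) {
  stopifnot_cols(target_map, c("mirna_id", "gene"), "target map")
  if (!"gene" %in% names(tc_records)) {
    if (is.null(tc_genes)) abort("tc_records needs a gene column or tc_genes")
    tc_records <- left_join(
      tc_records, rename(tc_genes, feature = "feature_id"),
      by = "feature"
    )
  }
  unmapped <- setdiff(unique(mirna_hits$feature), unique(target_map$mirna_id))
  if (length(unmapped) > 0) {
    inform(sprintf("%d miRNA(s) absent from the target map", length(unmapped)))
  }
  triples <- mirna_hits |>
    select(
      "exposure", "period",
      mirna = "feature", mirna_effect = "effect", mirna_p = "p"
    ) |>
    inner_join(
      rename(target_map, mirna = "mirna_id"),
      by = "mirna", relationship = "many-to-many"
    ) |>
    inner_join(
      tc_records |>
        select(
          "exposure", "period", "gene",
          tc_feature = "feature", tc_effect = "effect", tc_p = "p"
        ),
      by = c("exposure", "period", "gene"),
      relationship = "many-to-many"
    ) |>
    filter(
      .data$tc_p < alpha_nominal,
      sign(.data$tc_effect) == -sign(.data$mirna_effect)
    ) |>
    arrange(.data$exposure, .data$mirna, .data$gene)
  attr(triples, "n_unmapped") <- length(unmapped)
  triples
}

#' Cross-matrix replication of exposure-metabolite associations
#'
#' Checks whether significant exposure-metabolite associations discovered
#' in one biological matrix (e.g. urine) hold for the matched metabolite
#' in another (e.g. serum): a discovery association replicates when the
#' mapped feature's record for the same exposure is nominally significant
#' and (by default) has the same effect sign. The two directions have
#' different denominators and are therefore asymmetric.
#'
#' @param discovery Significant association records in matrix A.
#' @param lookup All association records in matrix B.
#' @param metabolite_map Tibble `feature_a`, `feature_b` pairing the
#'   metabolites measured in both matrices.
#' @param alpha_nominal Nominal significance level (default 0.05).
#' @param require_sign Also require effect-sign agreement (default TRUE).
#' @return A list with `fraction` (percent of mappable discovery
#'   associations that replicate; `NA` when there are none), `n_discovery`,
#'   `n_replicated`, `n_unmapped`, and `pairs` (the per-association
#'   table).
#' @export
cross_matrix_replication <- function(discovery, lookup, metabolite_map,
                                     alpha_nominal = 0.05,
                                     require_sign = TRUE) {
  stopifnot_cols(metabolite_map, c("feature_a", "feature_b"), "metabolite map")
  mappable <- discovery |>
    inner_join(
      rename(metabolite_map, feature = "feature_a"),
      by = "feature"
    )
  n_unmapped <- nrow(discovery) - nrow(mappable)
  if (n_unmapped > 0) {
    inform(sprintf(
      "%d discovery association(s) excluded: metabolite not measured in both matrices",
      n_unmapped
    ))
  }
  pairs <- mappable |>
    left_join(
      lookup |>
        select(
          "exposure", "period",
          feature_b = "feature", effect_b = "effect", p_b = "p"
        ),
      by = c("exposure", "period", "feature_b")
    ) |>
    mutate(
      replicated = !is.na(.data$p_b) & .data$p_b < alpha_nominal &
        (!require_sign | sign(.data$effect_b) == sign(.data$effect))
    ) |>
    select(
      "exposure", "period", "feature", "feature_b",
      effect_a = "effect", "effect_b", p_a = "p", "p_b", "replicated"
    )
  n_disc <- nrow(pairs)
  n_rep <- sum(pairs$replicated)
  list(
    fraction = if (n_disc == 0) NA_real_ else 100 * n_rep / n_disc,
    n_discovery = n_disc,
    n_replicated = n_rep,
    n_unmapped = n_unmapped,
    pairs = pairs
  )
}
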