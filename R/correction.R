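#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: monotone in rank and capped at
#' one.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of adjusted values (q-values), same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(p) {
  if (length(p) == 0) {
    return(numeric())
  }
  if (any(p <= 0 | p > 1 | is.na(p))) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Effective number of tests of a correlated feature set
#'
#' Estimates how many independent tests a correlated feature panel
#' represents from the eigenvalues of its feature-feature Pearson
#' correlation matrix, using the eigenvalue floor/fraction estimator:
#' each eigenvalue contributes an indicator of exceeding one plus its
#' fractional part,
#' `ENT = sum( 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) )`.
#' Independent features give ENT = M, perfectly duplicated features give
#' ENT = 1. The nominal alpha divided by ENT yields a correlation-aware
#' Bonferroni threshold for targeted omics panels.
#'
#' @param x Sample-by-feature numeric matrix (at least 3 samples and 2
#'   features), or a feature correlation matrix when
#'   `is_correlation = TRUE`.
#' @param is_correlation Interpret `x` as an already-computed correlation
#'   matrix.
#' @return A scalar in \[1, M\].
#' @export
effective_tests <- function(x, is_correlation = FALSE) {
  if (is_correlation) {
    cmat <- x
  } else {
    if (ncol(x) < 2) abort("need at least 2 features")
    if (nrow(x) < 3) abort("need at least 3 samples")
    constant <- apply(x, 2, function(v) sd(v) == 0)
    if (any(constant)) {
      warn(sprintf(
        "excluding constant feature(s) from ENT: %s",
        compact_chr(colnames(x)[constant])
      ))
      x <- x[, !constant, drop = FALSE]
      if (ncol(x) < 2) abort("fewer than 2 non-constant features")
    }
    cmat <- cor(x)
  }
  lambda <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' Apply layered multiple-testing correction to association records
#'
#' Correction is applied independently within each (exposure, layer)
#' stratum. Genome-wide layers (methylation, expression, miRNA) are
#' flagged by Benjamini-Hochberg FDR at `alpha`; targeted layers
#' (proteins, serum and urine metabolites) by the per-test threshold
#' `alpha / ENT(layer)`, where the effective number of tests is computed
#' once per layer on the analysis samples. A stringent global flag marks
#' records with `p < global_cutoff` regardless of layer.
#'
#' @param records An association table from [run_exwas()].
#' @param layers The named list of [omics_layer()] objects the records
#'   were computed on (used for ENT); alternatively supply `ent` directly.
#' @param alpha Nominal level (default 0.05).
#' @param global_cutoff Stringent everything-at-once cutoff (default
#'   1e-9).
#' @param ent Optional named vector of precomputed effective test counts
#'   per targeted layer.
#' @return The records tibble with added columns `q` (BH-adjusted p,
#'   genome-wide strata only), `significant` and `passes_global`, plus a
#'   `"rules"` attribute: one row per layer with the method, ENT and
#'   threshold used (see [correction_rules()]).
#' @export
apply_correction <- function(records, layers = NULL, alpha = 0.05,
                             global_cutoff = 1e-9, ent = NULL) {
  if (nrow(records) == 0) abort("no association records supplied")
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  if (!is.null(layers)) {
    names(layers) <- vapply(layers, function(l) l$layer, character(1))
  }
  rec_layers <- unique(records$layer)
  targeted <- setdiff(rec_layers, GENOME_WIDE_LAYERS)
  ent_vec <- setNames(rep(NA_real_, length(rec_layers)), rec_layers)
  for (ly in targeted) {
    if (!is.null(ent) && ly %in% names(ent)) {
      ent_vec[ly] <- ent[[ly]]
    } else if (!is.null(layers) && ly %in% names(layers)) {
      ent_vec[ly] <- effective_tests(layers[[ly]]$values)
    } else {
      abort(sprintf(
        "targeted layer '%s' needs its omics matrix (or a precomputed ENT)",
        ly
      ))
    }
  }
  records <- records |>
    group_by(.data$exposure, .data$layer) |>
    mutate(
      q = if (.data$layer[1] %in% GENOME_WIDE_LAYERS) {
        bh_fdr(.data$p)
      } else {
        NA_real_
      }
    ) |>
    ungroup() |>
    mutate(
      significant = ifelse(
        .data$layer %in% GENOME_WIDE_LAYERS,
        .data$q <= alpha,
        .data$p < alpha / ent_vec[.data$layer]
      ),
      passes_global = .data$p < global_cutoff
    )
  rules <- tibble(
    layer = rec_layers,
    method = ifelse(
      rec_layers %in% GENOME_WIDE_LAYERS, "bh_fdr", "ent_bonferroni"
    ),
    alpha = alpha,
    ent = unname(ent_vec),
    threshold = ifelse(
      rec_layers %in% GENOME_WIDE_LAYERS, alpha, alpha / unname(ent_vec)
    )
  )
  class(records) <- unique(c("exwas_tbl", class(records)))
  attr(records, "rules") <- rules
  attr(records, "alpha") <- alpha
  attr(records, "global_cutoff") <- global_cutoff
  records
}

#' Correction-rule summary of a flagged association table
#'
#' @param records Output of [apply_correction()].
#' @return Tibble with one row per layer: method, ENT and threshold.
#' @export
correction_rules <- function(records) {
  rules <- attr(records, "rules")
  if (is.null(rules)) abort("records carry no correction rules; run apply_correction() first")
  rules
}
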