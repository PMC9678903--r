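#' Construct an omics layer
#'
#' A sample-by-feature numeric matrix with its layer kind, scale
#' convention and optional feature annotation. Methylation, expression and
#' miRNA layers are genome-wide (FDR correction, surrogate-variable
#' adjustment); proteins and metabolites are targeted panels
#' (effective-number-of-tests Bonferroni).
#'
#' @param layer One of `"methylation"`, `"expression"`, `"mirna"`,
#'   `"protein"`, `"serum_metab"`, `"urine_metab"`.
#' @param values Numeric matrix, samples in rows (rownames = sample IDs),
#'   features in columns (colnames = feature IDs).
#' @param features Optional annotation tibble with columns `feature_id`
#'   and any of `gene`, `chrom`, `position`, `strand`.
#' @param scale `"beta_0_1"` (methylation betas), `"log2"` or `"raw"`.
#' @param technical_covariates Names of layer-specific technical covariate
#'   columns to pull from the covariate table when modelling.
#' @return An object of class `omics_layer`.
#' @export
omics_layer <- function(layer, values,
                        features = NULL,
                        scale = c("log2", "beta_0_1", "raw"),
                        technical_covariates = character()) {
  layer <- match.arg(layer, OMICS_LAYERS)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("values must carry sample rownames and feature colnames")
  }
  if (anyNA(values)) abort(sprintf("layer '%s' contains missing values", layer))
  if (scale == "beta_0_1" && (min(values) < 0 || max(values) > 1)) {
    abort("beta_0_1 values must lie in [0, 1]")
  }
  if (is.null(features)) {
    features <- tibble(feature_id = colnames(values))
  } else {
    stopifnot_cols(features, "feature_id", "feature annotation")
    features <- as_tibble(features)
    missing <- setdiff(colnames(values), features$feature_id)
    if (length(missing) > 0) {
      features <- bind_rows(features, tibble(feature_id = missing))
    }
    features <- features[match(colnames(values), features$feature_id), ]
  }
  structure(
    list(
      layer = layer,
      values = values,
      features = features,
      scale = scale,
      genome_wide = layer %in% GENOME_WIDE_LAYERS,
      technical_covariates = technical_covariates
    ),
    class = "omics_layer"
  )
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf(
    "<omics_layer: %s> %d samples x %d features (%s scale, %s)\n",
    x$layer, nrow(x$values), ncol(x$values), x$scale,
    if (x$genome_wide) "genome-wide" else "targeted"
  ))
  invisible(x)
}

#' Read an omics layer from tab-delimited files
#'
#' @param path Matrix file (first column sample ID, header of feature IDs).
#' @param layer,scale,technical_covariates Passed to [omics_layer()].
#' @param annotation_path Optional feature annotation table
#'   (see [read_feature_annotation()]).
#' @param annotation_format Format of the annotation file.
#' @return An [omics_layer()].
#' @export
load_omics_layer <- function(path, layer, scale = "log2",
                             annotation_path = NULL,
                             annotation_format = c("table", "bed"),
                             technical_covariates = character()) {
  values <- read_matrix_tsv(path)
  features <- NULL
  if (!is.null(annotation_path)) {
    features <- read_feature_annotation(
      annotation_path,
      format = match.arg(annotation_format)
    )
  }
  omics_layer(layer, values,
    features = features, scale = scale,
    technical_covariates = technical_covariates
  )
}

#' Write an omics layer matrix (and annotation) to tab-delimited files
#'
#' @param ol An [omics_layer()].
#' @param path Matrix file path.
#' @param annotation_path Optional annotation file path.
#' @return Invisibly, the paths written.
#' @export
write_omics_layer <- function(ol, path, annotation_path = NULL) {
  write_matrix_tsv(ol$values, path)
  if (!is.null(annotation_path)) {
    readr::write_tsv(ol$features, annotation_path, progress = FALSE)
  }
  invisible(c(path, annotation_path))
}

#' Read feature genomic annotation
#'
#' Two formats are accepted. `"table"`: tab-delimited with columns
#' `feature_id` plus any of `gene`, `chrom`, `position`, `strand`
#' (1-based point position: CpG site or transcription start site).
#' `"bed"`: BED-like 4+ columns (chrom, start, end, feature_id, then
#' optionally score and strand; 0-based half-open). BED intervals are
#' converted to 1-based point positions: `start + 1` for unstranded or
#' plus-strand features, and the interval end for minus-strand features
#' (a strand-aware transcription start site).
#'
#' @param path File path.
#' @param format `"table"` or `"bed"`.
#' @return Annotation tibble with `feature_id`, `chrom`, `position` and,
#'   when available, `strand` and `gene`.
#' @export
read_feature_annotation <- function(path, format = c("table", "bed")) {
  format <- match.arg(format)
  if (format == "table") {
    ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot_cols(ann, "feature_id", "feature annotation")
    return(as_tibble(ann))
  }
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    comment = "#"
  )
  if (ncol(bed) < 4) abort("BED-like annotation needs at least 4 columns")
  names(bed)[1:4] <- c("chrom", "start", "end", "feature_id")
  strand <- if (ncol(bed) >= 6) as.character(bed[[6]]) else
    rep(NA_character_, nrow(bed))
  position <- ifelse(
    !is.na(strand) & strand == "-", bed$end, bed$start + 1
  )
  tibble(
    feature_id = as.character(bed$feature_id),
    chrom = as.character(bed$chrom),
    position = as.numeric(position),
    strand = strand
  )
}

#' Read a pipeline run configuration
#'
#' A YAML key-value file naming input paths, covariate roles, layer scales
#' and analysis thresholds. Missing threshold entries fall back to the
#' package defaults: `alpha` 0.05, `global_cutoff` 1e-9,
#' `correlation_cutoff` 0.8 (applied on the magnitude scale),
#' `cis_window` 500000.
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  config <- yaml::read_yaml(path)
  defaults <- list(
    alpha = 0.05,
    global_cutoff = 1e-9,
    correlation_cutoff = 0.8,
    cis_window = 5e5
  )
  utils::modifyList(defaults, config)
}
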