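#' Exposure metadata table
#'
#' Builds and validates the metadata table that describes each exposure
#' variable: the exposure window (`pregnancy` or `childhood`), the exposure
#' family (e.g. metals, organochlorines, diet), whether the variable is
#' continuous or categorical, its declared level set, and the correlation
#' group used when selecting mutually adjusted multi-exposure models.
#'
#' By convention the correlation group equals the family, except that
#' members of the diet, metals and parabens families each form their own
#' group (they are too internally heterogeneous to be treated as one
#' variable block).
#'
#' @param exposure Character vector of unique exposure identifiers.
#' @param period `"pregnancy"` or `"childhood"`, recycled as needed.
#' @param family Exposure family label.
#' @param vartype `"continuous"` or `"categorical"`.
#' @param levels List of character vectors of ordered level labels
#'   (categorical variables only; first level is the reference). Use
#'   `NULL` entries for continuous variables.
#' @param transform Declared upstream transform, one of `"none"`, `"log"`,
#'   `"categorized"`. Informational only.
#' @param correlation_group Optional explicit group labels; defaults to the
#'   family rule described above.
#'
#' @return A tibble with one row per exposure and columns `exposure`,
#'   `period`, `family`, `vartype`, `levels` (list column), `transform`,
#'   `correlation_group`.
#' @export
exposure_metadata <- function(exposure, period, family,
                              vartype = "continuous",
                              levels = NULL,
                              transform = "none",
                              correlation_group = NULL) {
  n <- length(exposure)
  if (is.null(levels)) levels <- vector("list", n)
  meta <- tibble(
    exposure = as.character(exposure),
    period = rep_len(as.character(period), n),
    family = rep_len(as.character(family), n),
    vartype = rep_len(as.character(vartype), n),
    levels = levels,
    transform = rep_len(as.character(transform), n),
    correlation_group = if (is.null(correlation_group)) NA_character_ else
      rep_len(as.character(correlation_group), n)
  )
  meta$correlation_group <- ifelse(
    is.na(meta$correlation_group),
    ifelse(meta$family %in% OWN_GROUP_FAMILIES,
      paste(meta$family, meta$exposure, sep = ":"),
      meta$family
    ),
    meta$correlation_group
  )
  validate_exposure_metadata(meta)
}

validate_exposure_metadata <- function(meta) {
  stopifnot_cols(
    meta,
    c("exposure", "period", "family", "vartype", "levels", "transform",
      "correlation_group"),
    "exposure metadata"
  )
  if (anyDuplicated(meta$exposure)) {
    abort("exposure identifiers must be unique")
  }
  bad_period <- setdiff(unique(meta$period), EXPOSURE_PERIODS)
  if (length(bad_period) > 0) {
    abort(sprintf("unknown exposure period(s): %s", compact_chr(bad_period)))
  }
  bad_type <- setdiff(unique(meta$vartype), c("continuous", "categorical"))
  if (length(bad_type) > 0) {
    abort(sprintf("unknown vartype(s): %s", compact_chr(bad_type)))
  }
  for (i in seq_len(nrow(meta))) {
    lv <- meta$levels[[i]]
    if (meta$vartype[i] == "categorical") {
      if (length(lv) < 2) {
        abort(sprintf(
          "categorical exposure '%s' must declare at least 2 levels",
          meta$exposure[i]
        ))
      }
    } else if (length(lv) > 0) {
      abort(sprintf(
        "continuous exposure '%s' must not declare levels", meta$exposure[i]
      ))
    }
  }
  if (any(!nzchar(meta$correlation_group) | is.na(meta$correlation_group))) {
    abort("correlation_group must be non-empty for every exposure")
  }
  meta
}

#' Assemble an exposome set
#'
#' Binds a sample-by-exposure data table to its exposure metadata and
#' validates the pairing: every data column must be declared, categorical
#' values must match declared levels, and no missing values are allowed
#' (imputation is an upstream responsibility).
#'
#' @param data Tibble with a `sample_id` column plus one column per
#'   exposure (numeric for continuous, character level codes for
#'   categorical exposures).
#' @param meta Exposure metadata from [exposure_metadata()].
#' @return An object of class `exposome_set`: a list with elements `data`
#'   and `meta`.
#' @export
exposome_set <- function(data, meta) {
  meta <- validate_exposure_metadata(meta)
  stopifnot_cols(data, "sample_id", "exposome data")
  data <- as_tibble(data)
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) abort("duplicated sample_id values")
  vars <- setdiff(names(data), "sample_id")
  undeclared <- setdiff(vars, meta$exposure)
  if (length(undeclared) > 0) {
    abort(sprintf(
      "exposure(s) present in the matrix but missing from metadata: %s",
      compact_chr(undeclared)
    ))
  }
  absent <- setdiff(meta$exposure, vars)
  if (length(absent) > 0) {
    abort(sprintf(
      "exposure(s) declared in metadata but absent from the matrix: %s",
      compact_chr(absent)
    ))
  }
  for (i in seq_len(nrow(meta))) {
    nm <- meta$exposure[i]
    x <- data[[nm]]
    if (anyNA(x)) {
      abort(sprintf(
        "exposure '%s' has missing values (sample %s); impute upstream",
        nm, data$sample_id[which(is.na(x))[1]]
      ))
    }
    if (meta$vartype[i] == "continuous") {
      if (!is.numeric(x)) {
        abort(sprintf("continuous exposure '%s' is not numeric", nm))
      }
    } else {
      x <- as.character(x)
      bad <- !(x %in% meta$levels[[i]])
      if (any(bad)) {
        j <- which(bad)[1]
        abort(sprintf(
          "unknown level \"%s\" for exposure '%s' in sample %s",
          x[j], nm, data$sample_id[j]
        ))
      }
      data[[nm]] <- x
    }
  }
  structure(
    list(data = data[, c("sample_id", meta$exposure)], meta = meta),
    class = "exposome_set"
  )
}

#' @export
print.exposome_set <- function(x, ...) {
  cat(sprintf(
    "<exposome_set> %d samples x %d exposures (%d pregnancy, %d childhood)\n",
    nrow(x$data), nrow(x$meta),
    sum(x$meta$period == "pregnancy"), sum(x$meta$period == "childhood")
  ))
  invisible(x)
}

#' Read an exposome matrix and its metadata from tab-delimited files
#'
#' The matrix file has a header row of exposure names and a first column of
#' sample identifiers. The metadata file has one row per exposure with
#' columns `exposure`, `period`, `family`, `vartype`, `levels`
#' (pipe-separated label list, empty for continuous variables), `transform`
#' and optionally `correlation_group`.
#'
#' @param path Matrix file path.
#' @param metadata_path Metadata file path.
#' @return An [exposome_set()].
#' @export
load_exposome <- function(path, metadata_path) {
  raw_meta <- readr::read_tsv(metadata_path,
    show_col_types = FALSE,
    progress = FALSE
  )
  stopifnot_cols(
    raw_meta, c("exposure", "period", "family", "vartype"),
    "exposure metadata file"
  )
  levels <- lapply(
    if ("levels" %in% names(raw_meta)) raw_meta$levels else
      rep(NA_character_, nrow(raw_meta)),
    function(s) {
      if (is.na(s) || !nzchar(s)) NULL else strsplit(s, "|", fixed = TRUE)[[1]]
    }
  )
  meta <- exposure_metadata(
    exposure = raw_meta$exposure,
    period = raw_meta$period,
    family = raw_meta$family,
    vartype = raw_meta$vartype,
    levels = levels,
    transform = if ("transform" %in% names(raw_meta)) raw_meta$transform else
      "none",
    correlation_group = if ("correlation_group" %in% names(raw_meta)) {
      raw_meta$correlation_group
    } else {
      NULL
    }
  )
  data <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  names(data)[1] <- "sample_id"
  data <- as_tibble(data)
  for (i in seq_len(nrow(meta))) {
    if (meta$vartype[i] == "continuous") {
      nm <- meta$exposure[i]
      if (nm %in% names(data)) data[[nm]] <- as.numeric(data[[nm]])
    }
  }
  exposome_set(data, meta)
}

#' Write an exposome set as tab-delimited files
#'
#' Continuous values are written with 17 significant digits so that a
#' write/read round-trip is bit-exact.
#'
#' @param es An [exposome_set()].
#' @param path Matrix file path.
#' @param metadata_path Metadata file path.
#' @return Invisibly, the paths written.
#' @export
write_exposome <- function(es, path, metadata_path) {
  readr::write_tsv(format_full_precision(es$data), path, progress = FALSE)
  meta_out <- mutate(
    es$meta,
    levels = purrr::map_chr(.data$levels, ~ paste(.x, collapse = "|"))
  )
  readr::write_tsv(meta_out, metadata_path, progress = FALSE)
  invisible(c(path, metadata_path))
}

#' Interquartile range with interpolated quantiles
#'
#' Q3 minus Q1 using the linear-interpolation quantile definition (R type
#' 7), the default of mainstream numeric stacks. Continuous exposures are
#' scaled by this quantity so regression coefficients read as per-IQR
#' effects.
#'
#' @param x Numeric vector, length at least 4, no missing values.
#' @return A non-negative scalar. A constant vector yields 0; downstream
#'   per-IQR scaling rejects such degenerate exposures.
#' @export
#' @examples
#' iqr(1:8) # 3.5
iqr <- function(x) {
  if (!is.numeric(x)) abort("iqr() expects a numeric vector")
  if (anyNA(x)) abort("iqr() does not accept missing values")
  if (length(x) < 4) abort("iqr() needs at least 4 observations")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Mixed-type exposure correlation
#'
#' Pairwise association among exposures using the measure appropriate to
#' each pair: Pearson correlation for two continuous variables, the square
#' root of the linear-model R-squared for a continuous-categorical pair
#' (so all mixed-type magnitudes live in \[0, 1\]), and Cramer's V for two
#' categorical variables.
#'
#' @param es An [exposome_set()] with at least 3 samples.
#' @param periods Optional period filter (default: all exposures).
#' @return A tibble of class `exposure_cor` with columns `var1`, `var2`,
#'   `estimate` and `method`, one row per unordered pair including the
#'   unit diagonal. Use [cor_matrix()] for the symmetric matrix form.
#'   Zero-variance continuous variables yield `NA` entries with a warning.
#' @export
exposure_correlation <- function(es, periods = NULL) {
  meta <- es$meta
  if (!is.null(periods)) meta <- filter(meta, .data$period %in% periods)
  vars <- meta$exposure
  if (nrow(es$data) < 3) abort("need at least 3 samples")
  n <- length(vars)
  is_cont <- meta$vartype == "continuous"
  degenerate <- vapply(seq_len(n), function(i) {
    is_cont[i] && sd(es$data[[vars[i]]]) == 0
  }, logical(1))
  if (any(degenerate)) {
    warn(sprintf(
      "zero-variance continuous exposure(s): %s; correlations set to NA",
      compact_chr(vars[degenerate])
    ))
  }
  out <- vector("list", n * (n + 1) / 2)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- k + 1L
      if (i == j) {
        out[[k]] <- list(
          var1 = vars[i], var2 = vars[j], estimate = 1,
          method = if (is_cont[i]) "pearson" else "cramers_v"
        )
        next
      }
      xi <- es$data[[vars[i]]]
      xj <- es$data[[vars[j]]]
      if (degenerate[i] || degenerate[j]) {
        est <- NA_real_
        method <- "undefined"
      } else if (is_cont[i] && is_cont[j]) {
        est <- cor(xi, xj)
        method <- "pearson"
      } else if (!is_cont[i] && !is_cont[j]) {
        est <- cramers_v(xi, xj)
        method <- "cramers_v"
      } else {
        if (is_cont[i]) {
          est <- sqrt_r2(xi, xj)
        } else {
          est <- sqrt_r2(xj, xi)
        }
        method <- "sqrt_r2"
      }
      out[[k]] <- list(
        var1 = vars[i], var2 = vars[j], estimate = est, method = method
      )
    }
  }
  res <- bind_rows(out)
  class(res) <- c("exposure_cor", class(res))
  res
}

#' Symmetric matrix view of an exposure correlation table
#'
#' @param ec Result of [exposure_correlation()].
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
cor_matrix <- function(ec) {
  vars <- unique(c(ec$var1, ec$var2))
  m <- matrix(NA_real_, length(vars), length(vars),
    dimnames = list(vars, vars)
  )
  m[cbind(ec$var1, ec$var2)] <- ec$estimate
  m[cbind(ec$var2, ec$var1)] <- ec$estimate
  m
}

# Cramer's V from the uncorrected chi-squared statistic.
cramers_v <- function(x, y) {
  tab <- table(as.character(x), as.character(y))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  d <- min(nrow(tab), ncol(tab)) - 1
  if (d == 0) {
    return(NA_real_)
  }
  sqrt(chi2 / (n * d))
}

# sqrt of the R-squared of the linear model of `cont` on `cat` indicators.
sqrt_r2 <- function(cont, cat) {
  cat <- as.character(cat)
  mu <- tapply(cont, cat, mean)
  sst <- sum((cont - mean(cont))^2)
  if (sst == 0) {
    return(NA_real_)
  }
  sse <- sum((cont - mu[cat])^2)
  sqrt(max(0, 1 - sse / sst))
}

# Master sample alignment: intersection of sample IDs in exposome order.
align_samples <- function(exposome_ids, ...) {
  ids <- exposome_ids
  for (other in list(...)) ids <- ids[ids %in% other]
  ids
}
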