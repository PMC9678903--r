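#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association table
#'
#' Association tables are already tidy (one test per row); this method
#' standardises the broom-style column names `estimate`, `std.error`,
#' `p.value`.
#'
#' @param x An `exwas_tbl`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy exwas_tbl
#' @export
tidy.exwas_tbl <- function(x, ...) {
  as_tibble(x) |>
    rename(estimate = "effect", std.error = "se", p.value = "p")
}

#' One-row summary of an association table
#'
#' @param x An `exwas_tbl` (flagged or not).
#' @param ... Unused.
#' @return A one-row tibble: numbers of records, exposures, features,
#'   layers, and (when flagged) significant and globally significant
#'   records.
#' @method glance exwas_tbl
#' @export
glance.exwas_tbl <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    n_exposures = length(unique(x$exposure)),
    n_features = length(unique(x$feature)),
    n_layers = length(unique(x$layer)),
    n_significant = if ("significant" %in% names(x)) {
      sum(x$significant)
    } else {
      NA_integer_
    },
    n_global = if ("passes_global" %in% names(x)) {
      sum(x$passes_global)
    } else {
      NA_integer_
    }
  )
}

#' Tidy a meta-analysis table into per-cohort rows
#'
#' @param x An `exwas_meta` from [cohort_meta_analysis()].
#' @param ... Unused.
#' @return A long tibble with one row per association and cohort.
#' @method tidy exwas_meta
#' @export
tidy.exwas_meta <- function(x, ...) {
  x |>
    select(-any_of(c(
      "beta_fixed", "se_fixed", "beta_random", "se_random",
      "tau2", "q", "i2", "k"
    ))) |>
    tidyr::unnest("cohorts")
}

#' Pooled summary of a meta-analysis table
#'
#' @param x An `exwas_meta`.
#' @param ... Unused.
#' @return The pooled columns, one row per association.
#' @method glance exwas_meta
#' @export
glance.exwas_meta <- function(x, ...) {
  select(as_tibble(x), -"cohorts")
}

#' Tidy an association network into its node table
#'
#' @param x An `assoc_network`.
#' @param ... Unused.
#' @return The nodes tibble.
#' @method tidy assoc_network
#' @export
tidy.assoc_network <- function(x, ...) {
  x$nodes
}

#' One-row topology summary of an association network
#'
#' @param x An `assoc_network`.
#' @param ... Passed to [network_stats()].
#' @return A one-row tibble of topology statistics (plus modularity when
#'   communities have been detected).
#' @method glance assoc_network
#' @export
glance.assoc_network <- function(x, ...) {
  out <- network_stats(x, ...)
  out$modularity <- x$modularity %||% NA_real_
  out
}
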