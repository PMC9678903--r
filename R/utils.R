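# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so library-internal randomness (surrogate
# variable permutations, plot jitter) never perturbs user simulations.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Format numerics with 17 significant digits so text round-trips are
# bit-exact; leaves non-numeric columns untouched.
format_full_precision <- function(df) {
  mutate(df, across(where(is.double), ~ sprintf("%.17g", .x)))
}

write_matrix_tsv <- function(mat, path, id_col = "sample_id") {
  df <- as_tibble(mat, rownames = id_col)
  readr::write_tsv(format_full_precision(df), path, progress = FALSE)
}

read_matrix_tsv <- function(path, id_col = "sample_id") {
  # base R's strtod round-trips %.17g representations bit-exactly
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

compact_chr <- function(x) paste(x, collapse = ", ")

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s", what, compact_chr(missing)
    ))
  }
  invisible(df)
}
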