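test_that("cis pairing applies the strict window on the same chromosome", {
  cpg <- tibble::tibble(
    feature_id = c("cpg_in", "cpg_edge", "cpg_far", "cpg_otherchrom", "cpg_nocoord"),
    chrom = c("chr1", "chr1", "chr1", "chr2", NA),
    position = c(100000, 50000, 1100000, 100000, NA)
  )
  tc <- tibble::tibble(
    feature_id = "tc1", chrom = "chr1", position = 550000
  )
  expect_message(
    pairs <- pair_cis_eqtm(cpg, tc, window = 5e5),
    "without coordinates"
  )
  # 450 kb is in; exactly 500 kb is excluded ("closer than"); 550 kb out
  expect_equal(pairs$cpg_id, "cpg_in")
  expect_equal(pairs$distance, 450000)
  expect_equal(attr(pairs, "n_skipped"), 1L)
})

test_that("cis pairing equals the brute-force double loop on random features", {
  set.seed(88)
  cpg <- tibble::tibble(
    feature_id = sprintf("c%03d", 1:120),
    chrom = sample(paste0("chr", 1:3), 120, replace = TRUE),
    position = round(runif(120, 1, 3e6))
  )
  tc <- tibble::tibble(
    feature_id = sprintf("t%03d", 1:80),
    chrom = sample(paste0("chr", 1:3), 80, replace = TRUE),
    position = round(runif(80, 1, 3e6))
  )
  pairs <- pair_cis_eqtm(cpg, tc, window = 5e5)
  brute <- list()
  for (i in seq_len(nrow(cpg))) {
    for (j in seq_len(nrow(tc))) {
      if (cpg$chrom[i] == tc$chrom[j] &&
        abs(cpg$position[i] - tc$position[j]) < 5e5) {
        brute[[length(brute) + 1]] <- paste(cpg$feature_id[i], tc$feature_id[j])
      }
    }
  }
  expect_setequal(paste(pairs$cpg_id, pairs$tc_id), unlist(brute))
})

# Build matched methylation/expression layers with planted eQTMs.
make_eqtm_fixture <- function(seed, n = 300, n_cpg = 60, n_tc = 30,
                              n_true = 0, slope = 2, noise = 0.3) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  meth <- matrix(plogis(rnorm(n * n_cpg, 0, 1)), n, n_cpg,
    dimnames = list(ids, sprintf("cpg%03d", seq_len(n_cpg)))
  )
  cov <- tibble::tibble(
    sample_id = ids,
    age = runif(n, 6, 11),
    sex = sample(c("female", "male"), n, TRUE),
    cohort = sample(c("c1", "c2"), n, TRUE)
  )
  expr <- matrix(rnorm(n * n_tc, 5, 1), n, n_tc,
    dimnames = list(ids, sprintf("tc%03d", seq_len(n_tc)))
  )
  truth <- character()
  if (n_true > 0) {
    for (k in seq_len(n_true)) {
      expr[, k] <- slope * meth[, k] + rnorm(n, 0, noise)
      truth <- c(truth, paste(colnames(meth)[k], colnames(expr)[k]))
    }
  }
  list(
    methylation = omics_layer("methylation", meth, scale = "beta_0_1"),
    expression = omics_layer("expression", expr, scale = "log2"),
    covariates = cov,
    truth = truth
  )
}

test_that("a noiseless eQTM slope is recovered exactly", {
  fx <- make_eqtm_fixture(1, n = 100, n_cpg = 3, n_tc = 3, n_true = 1, noise = 0)
  pairs <- tibble::tibble(cpg_id = "cpg001", tc_id = "tc001", distance = 1000)
  res <- fit_eqtm(pairs, fx$methylation, fx$expression, fx$covariates)
  expect_equal(res$estimate, 2, tolerance = 1e-10)
})

test_that("eQTM p-values are calibrated under the null", {
  fx <- make_eqtm_fixture(2, n = 300, n_cpg = 60, n_tc = 30)
  pairs <- tidyr::expand_grid(
    cpg_id = colnames(fx$methylation$values)[1:50],
    tc_id = colnames(fx$expression$values)[1:10]
  )
  pairs$distance <- 1000
  res <- fit_eqtm(pairs, fx$methylation, fx$expression, fx$covariates)
  frac <- mean(res$p < 0.05)
  band <- 2.576 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), band + 0.01)
  expect_false(any(res$significant))
})

test_that("true eQTMs are recovered at FDR 0.05 across seeds", {
  # 10 planted pairs among 500 candidates, n = 800, moderate effect
  recovered <- sapply(1:10, function(s) {
    fx <- make_eqtm_fixture(100 + s,
      n = 800, n_cpg = 100, n_tc = 50,
      n_true = 10, slope = 0.7, noise = 0.55
    )
    pairs <- tidyr::expand_grid(
      cpg_id = colnames(fx$methylation$values),
      tc_id = colnames(fx$expression$values)[1:5]
    )
    extra <- tibble::tibble(
      cpg_id = sprintf("cpg%03d", 6:10), tc_id = sprintf("tc%03d", 6:10)
    )
    pairs <- dplyr::bind_rows(pairs, extra)
    pairs$distance <- 1000
    res <- fit_eqtm(pairs, fx$methylation, fx$expression, fx$covariates)
    sig <- res[res$significant, ]
    sum(paste(sig$cpg_id, sig$tc_id) %in% fx$truth)
  })
  expect_true(all(recovered >= 8))
})

test_that("miRNA-target concordance applies the direction and p rules", {
  hits <- make_records("expo1", "mir1",
    effect = 0.4, p = 1e-5,
    layer = "mirna", significant = TRUE
  )
  map <- tibble::tibble(mirna_id = "mir1", gene = c("G1", "G2", "G3"))
  tcs <- dplyr::bind_rows(
    make_records("expo1", "tcA", effect = -0.2, p = 0.01, layer = "expression"),
    make_records("expo1", "tcB", effect = 0.2, p = 0.01, layer = "expression"),
    make_records("expo1", "tcC", effect = -0.2, p = 0.30, layer = "expression")
  )
  tcs$gene <- c("G1", "G2", "G3")
  out <- mirna_target_concordance(hits, tcs, map)
  # G1: opposite sign, nominal -> kept; G2: same sign -> out;
  # G3: not nominal -> out
  expect_equal(out$gene, "G1")
  # unmapped miRNA contributes nothing
  hits2 <- make_records("expo1", "mir_unknown",
    effect = 0.4, p = 1e-5,
    layer = "mirna", significant = TRUE
  )
  expect_message(
    out2 <- mirna_target_concordance(hits2, tcs, map),
    "absent from the target map"
  )
  expect_equal(nrow(out2), 0L)
})

test_that("a simulated exposure-miRNA-target cascade is detected concordantly", {
  found <- sapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 300
    x <- rnorm(n)
    mirna <- 0.8 * x / iqr(x) + rnorm(n, 0, 0.5)
    target <- -0.8 * mirna + rnorm(n, 0, 0.5)
    rec_m <- fit_association(x, mirna,
      exposure = "expo", feature = "mir1",
      layer = "mirna", period = "childhood"
    )
    rec_t <- fit_association(x, target,
      exposure = "expo", feature = "tc1",
      layer = "expression", period = "childhood"
    )
    rec_t$gene <- "G1"
    out <- mirna_target_concordance(
      rec_m, rec_t, tibble::tibble(mirna_id = "mir1", gene = "G1")
    )
    nrow(out) == 1
  })
  expect_gte(sum(found), 18)
})

test_that("replication fractions follow the rule and its degenerate cases", {
  disc <- make_records("e1", paste0("u", 1:4),
    effect = 0.3, p = 0.001,
    layer = "urine_metab", significant = TRUE
  )
  lookup <- make_records("e1", paste0("s", 1:4),
    effect = c(0.2, -0.2, 0.1, 0.1),
    p = c(0.01, 0.01, 0.5, 0.9), layer = "serum_metab"
  )
  map <- tibble::tibble(feature_a = paste0("u", 1:4), feature_b = paste0("s", 1:4))
  out <- cross_matrix_replication(disc, lookup, map)
  # only u1 replicates (s2 has the wrong sign, s3/s4 not nominal)
  expect_equal(out$fraction, 25)
  expect_equal(out$n_replicated, 1L)
  # sign requirement off: u2 also counts
  out2 <- cross_matrix_replication(disc, lookup, map, require_sign = FALSE)
  expect_equal(out2$fraction, 50)
  # empty discovery set: undefined, not zero
  empty <- cross_matrix_replication(disc[0, ], lookup, map)
  expect_true(is.na(empty$fraction))
})

test_that("correlated matrices replicate more than uncorrelated ones", {
  sim_two_matrix <- function(seed, between_cor) {
    set.seed(seed)
    n <- 400
    x <- rnorm(n)
    latent <- 0.6 * x / iqr(x) + rnorm(n, 0, 0.6)
    urine <- latent + rnorm(n, 0, 0.5)
    serum <- if (between_cor > 0) {
      latent + rnorm(n, 0, 0.5)
    } else {
      rnorm(n)
    }
    ru <- fit_association(x, urine,
      exposure = "e1", feature = "u1",
      layer = "urine_metab", period = "childhood"
    )
    ru$significant <- TRUE
    rs <- fit_association(x, serum,
      exposure = "e1", feature = "s1",
      layer = "serum_metab", period = "childhood"
    )
    map <- tibble::tibble(feature_a = "u1", feature_b = "s1")
    cross_matrix_replication(ru, rs, map)$n_replicated
  }
  rep_cor <- sum(sapply(1:15, function(s) sim_two_matrix(s, 0.7)))
  rep_null <- sum(sapply(1:15, function(s) sim_two_matrix(50 + s, 0)))
  expect_gt(rep_cor, rep_null)
})
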