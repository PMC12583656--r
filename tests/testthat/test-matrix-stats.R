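test_that("symmetrize takes the per-pair orientation maximum and drops low-cell wells", {
  m <- rbind(
    meas_row("A", "B", "N_A_C_B", 820),
    meas_row("A", "B", "N_B_C_A", 640),
    meas_row("A", "C", "N_A_C_B", 500),              # single orientation
    meas_row("B", "C", "N_A_C_B", 900, n_cells = 500),   # discarded
    meas_row("B", "C", "N_B_C_A", 700, n_cells = 500)    # discarded
  )
  mat <- symmetrize_measurements(m, min_cells = 10000)
  expect_true(mat$symmetric)
  expect_equal(mat$values["A", "B"], 820)
  expect_equal(mat$values["B", "A"], 820)
  expect_equal(mat$values["A", "C"], 500)
  expect_true(mat$missing["B", "C"])
  expect_true(mat$missing["C", "B"])
})

test_that("symmetrize matches a brute-force elementwise max on a random table", {
  set.seed(31)
  pr <- LETTERS[1:6]
  pairs <- t(combn(pr, 2))
  tab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    rbind(meas_row(pairs[k, 1], pairs[k, 2], "N_A_C_B", runif(1, 0, 2000),
                   n_cells = sample(c(500, 20000), 1)),
          meas_row(pairs[k, 2], pairs[k, 1], "N_A_C_B", runif(1, 0, 2000),
                   n_cells = sample(c(500, 20000), 1)))
  }))
  mat <- symmetrize_measurements(tab, min_cells = 10000, proteins = pr)
  # brute-force oracle
  expected <- matrix(NA_real_, 6, 6, dimnames = list(pr, pr))
  for (r in seq_len(nrow(tab))) {
    if (tab$n_cells[r] < 10000) next
    i <- tab$protein_a[r]; j <- tab$protein_b[r]
    expected[i, j] <- max(expected[i, j], tab$mfi[r], na.rm = TRUE)
    expected[j, i] <- expected[i, j]
  }
  expect_equal(mat$values, expected)
})

test_that("symmetrize is idempotent on its induced measurement set", {
  spec <- mfi_generator_spec(n_proteins = 8, seed = 5)
  mat <- symmetrize_measurements(synth_mfi(spec))
  # re-feed the symmetric matrix as single-orientation measurements
  pairs <- which(upper.tri(mat$values, diag = TRUE) & !mat$missing,
                 arr.ind = TRUE)
  m2 <- data.frame(protein_a = mat$proteins[pairs[, 1]],
                   protein_b = mat$proteins[pairs[, 2]],
                   orientation = "N_A_C_B",
                   mfi = mat$values[pairs], n_cells = 20000)
  mat2 <- symmetrize_measurements(m2, proteins = mat$proteins)
  expect_equal(mat2$values, mat$values)
})

test_that("duplicate (pair, orientation) records are rejected with row report", {
  m <- rbind(meas_row("A", "B", "N_A_C_B", 100),
             meas_row("B", "A", "N_B_C_A", 200))  # same record, flipped
  expect_error(symmetrize_measurements(m), "duplicate")
})

test_that("classification respects printed examples and partitions [0, Inf)", {
  expect_equal(as.character(classify_mfi(1002)), "moderate")
  expect_equal(as.character(classify_mfi(641)), "none")
  expect_equal(as.character(classify_mfi(750)), "weak")
  expect_equal(as.character(classify_mfi(c(0, 749.99, 900, 1099.9, 1100, 5000))),
               c("none", "none", "moderate", "moderate", "strong", "strong"))
  # every value classifies to exactly one class
  x <- seq(0, 2000, by = 0.5)
  cl <- classify_mfi(x)
  expect_false(anyNA(cl))
  expect_error(classify_mfi(-1), ">= 0")
})

test_that("permutation p follows the (count+1)/(N+1) rule with floor and ceiling", {
  mat <- six_protein_matrix(seed = 2)
  v <- mat$values
  # diagonal (homomer) pairs sit outside the off-diagonal null pool: raise
  # them above every other entry and the null can never reach the statistic
  v2 <- v
  diag(v2) <- max(v) + 1:6
  mat2 <- ppi_matrix(v2, proteins = mat$proteins, symmetric = TRUE)
  hom <- cbind(mat2$proteins[1:3], mat2$proteins[1:3])
  r <- cluster_permutation_test(mat2, hom, perm_spec(n_perm = 1000, seed = 9))
  expect_equal(r$p, 1 / 1001)
  # pairs holding the smallest values -> every null draw >= s_obs -> p = 1
  ord <- order(v[upper.tri(v)], decreasing = TRUE)
  up <- which(upper.tri(v), arr.ind = TRUE)[ord, ]
  bot <- cbind(mat$proteins[up[13:15, 1]], mat$proteins[up[13:15, 2]])
  r2 <- cluster_permutation_test(mat, bot, perm_spec(n_perm = 1000, seed = 9))
  expect_equal(r2$p, 1)
  # formula invariant on the stored sample
  expect_equal(r$p, (sum(r$null_sample >= r$s_obs) + 1) / (r$n_perm + 1))
  expect_true(r$p >= 1 / (r$n_perm + 1) && r$p <= 1)
})

test_that("p is deterministic given a seed and s_obs ignores n_perm", {
  mat <- six_protein_matrix(seed = 3)
  pairs <- cbind(c("A", "B"), c("C", "D"))
  r1 <- cluster_permutation_test(mat, pairs, perm_spec(n_perm = 500, seed = 4))
  r2 <- cluster_permutation_test(mat, pairs, perm_spec(n_perm = 500, seed = 4))
  r3 <- cluster_permutation_test(mat, pairs, perm_spec(n_perm = 1000, seed = 4))
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null_sample, r2$null_sample)
  expect_identical(r1$s_obs, r3$s_obs)
})

test_that("pair sets touching missing entries or exceeding the pool error", {
  v <- matrix(c(0, 100, NA, 100, 0, 200, NA, 200, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  mat <- ppi_matrix(v, symmetric = TRUE)
  expect_error(
    cluster_permutation_test(mat, cbind("A", "C"), perm_spec(seed = 1)),
    "A/C")
  expect_error(
    cluster_permutation_test(mat, rbind(c("A", "B"), c("B", "C"), c("A", "B")),
                             perm_spec(seed = 1)),
    "exceeds")
})

test_that("empirical null matches the exhaustive subset distribution (6 proteins)", {
  mat <- six_protein_matrix(seed = 7)
  pool <- mat$values[upper.tri(mat$values)]
  k <- 3
  exhaustive <- combn(pool, k, median)
  pairs <- cbind(c("A", "B", "C"), c("B", "C", "D"))
  r <- cluster_permutation_test(mat, pairs,
                                perm_spec(n_perm = 20000, seed = 12))
  ks <- suppressWarnings(stats::ks.test(r$null_sample, exhaustive))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("planted-cluster recovery: synthetic cluster yields p <= 0.001", {
  cl <- folate_like_cluster()
  spec <- mfi_generator_spec(clusters = list(cl), seed = 42)
  mat <- symmetrize_measurements(synth_mfi(spec))
  pairs <- t(combn(cl, 2))
  pairs <- pairs[!mat$missing[pairs], , drop = FALSE]
  r <- cluster_permutation_test(mat, pairs, perm_spec(n_perm = 10000, seed = 1))
  expect_lte(r$p, 0.001)
})

test_that("null calibration: random pair sets give uniform p over seeds", {
  mat <- symmetrize_measurements(synth_mfi(mfi_generator_spec(seed = 8)))
  pool <- which(upper.tri(mat$values) & !mat$missing, arr.ind = TRUE)
  n_rep <- 300
  ps <- vapply(seq_len(n_rep), function(i) {
    set.seed(1000 + i)
    sel <- pool[sample.int(nrow(pool), 6), , drop = FALSE]
    pairs <- cbind(mat$proteins[sel[, 1]], mat$proteins[sel[, 2]])
    cluster_permutation_test(mat, pairs,
                             perm_spec(n_perm = 199, seed = 2000 + i))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional cross test selects by predicate and detects coupling", {
  cl <- folate_like_cluster()
  spec <- mfi_generator_spec(clusters = list(cl), seed = 21)
  mfi <- symmetrize_measurements(synth_mfi(spec))
  tm <- synth_tm(spec, coupling = 1)
  # identity-like TM matrix: nothing above 0.5 off-diagonal
  tm_id <- synth_tm(mfi_generator_spec(seed = 3), coupling = 0)
  expect_error(
    conditional_cross_test(tm_id, mfi, function(v) v > 0.95,
                           spec = perm_spec(seed = 1)),
    "no \\(measurable\\) pairs")
  r <- conditional_cross_test(tm, mfi, function(v) v > 0.5,
                              spec = perm_spec(n_perm = 5000, seed = 5))
  expect_lte(r$p, 0.01)
  sel <- attr(r, "pairs")
  expect_true(all(sel$a %in% cl) && all(sel$b %in% cl))
})

test_that("cross test p is uniform when matrices are uncoupled", {
  ps <- vapply(1:200, function(i) {
    spec <- mfi_generator_spec(n_proteins = 12, seed = 5000 + i,
                               missing_fraction = 0)
    mfi <- symmetrize_measurements(synth_mfi(spec))
    tm <- synth_tm(spec, coupling = 0, seed = 9000 + i)
    # select an arbitrary TM band; values are independent of MFI
    conditional_cross_test(tm, mfi, function(v) v > 0.35,
                           spec = perm_spec(n_perm = 199, seed = i))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("protein propensity test flags a dominant row and errors on singletons", {
  # 20 proteins; A's 19 pairs dominate the remaining 171, so a null median
  # reaching the observed one would need 10 of 19 draws from A's own row --
  # vanishingly unlikely, pinning p at the floor
  pr <- c("A", sprintf("X%02d", 1:19))
  v <- matrix(500, 20, 20, dimnames = list(pr, pr))
  v["A", ] <- v[, "A"] <- 1900
  diag(v) <- 100
  mat <- ppi_matrix(v, symmetric = TRUE)
  r <- protein_propensity_test(mat, "A", perm_spec(n_perm = 999, seed = 2))
  expect_equal(r$p, 1 / 1000)
  one <- ppi_matrix(matrix(100, 1, 1), proteins = "Z", symmetric = TRUE)
  expect_gt(r$s_obs, 1000)
  expect_error(protein_propensity_test(one, "Z"))
  expect_error(protein_propensity_test(mat, "Q"), "unknown protein")
})

test_that("propensity p is roughly uniform across exchangeable proteins", {
  ps <- vapply(1:150, function(i) {
    spec <- mfi_generator_spec(n_proteins = 10, seed = 300 + i,
                               missing_fraction = 0)
    mat <- symmetrize_measurements(synth_mfi(spec))
    protein_propensity_test(mat, sample(mat$proteins, 1),
                            perm_spec(n_perm = 199, seed = 700 + i))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Welch comparison matches the textbook formula and conventions", {
  set.seed(99)
  x <- rnorm(20, 0, 2); y <- rnorm(25, 1, 0.5)
  r <- welch_two_sample(x, y)
  # independent oracle: Welch-Satterthwaite by hand
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(r$t, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p, p_hand)
  # identical samples -> t = 0, p = 1
  z <- rep(c(1, 2, 3), 2)
  expect_equal(welch_two_sample(z, z)$t, 0)
  expect_equal(welch_two_sample(z, z)$p, 1)
  expect_equal(welch_two_sample(c(1, 1), c(1, 1))$p, 1)
  # strong separation
  set.seed(1)
  r2 <- welch_two_sample(rnorm(200), rnorm(200, 1))
  expect_lt(r2$p, 1e-10)
})

test_that("welch p is uniform under the null", {
  ps <- vapply(1:400, function(i) {
    set.seed(i)
    welch_two_sample(rnorm(15), rnorm(15))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("interaction graph recovers a planted clique and handles extremes", {
  cl <- folate_like_cluster()
  spec <- mfi_generator_spec(clusters = list(cl), seed = 17,
                             missing_fraction = 0)
  mat <- symmetrize_measurements(synth_mfi(spec))
  g <- interaction_graph(mat, threshold = 1000)
  comp_with_cl <- Filter(function(x) any(cl %in% x), g$components)
  expect_true(all(cl %in% unlist(comp_with_cl)))
  expect_true(all(cl %in% g$core_nodes))
  # threshold above the global max -> edgeless
  g0 <- interaction_graph(mat, threshold = max(mat$values, na.rm = TRUE) + 1)
  expect_equal(nrow(g0$edges), 0)
  # threshold 0 -> complete graph on non-missing pairs
  gc <- interaction_graph(mat, threshold = 0)
  expect_equal(nrow(gc$edges), sum(upper.tri(mat$values) & !mat$missing))
  # no self loops anywhere
  expect_true(all(gc$edges$a != gc$edges$b))
})

test_that("matrix TSV round trip is value-exact and validation catches defects", {
  mat <- symmetrize_measurements(synth_mfi(mfi_generator_spec(
    n_proteins = 8, seed = 4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_matrix(mat, path)
  back <- read_ppi_matrix(path, symmetric = TRUE)
  expect_identical(back$values, mat$values)
  expect_identical(back$missing, mat$missing)
  expect_true(validate_ppi_matrix_file(path, expect_symmetric = TRUE)$ok)
  # corrupt an off-diagonal cell -> asymmetric file flagged
  tab <- readLines(path)
  tab[2] <- sub("^(\\S+\t\\S+\t)\\S+", "\\19999", tab[2])
  writeLines(tab, path)
  rep <- validate_ppi_matrix_file(path, expect_symmetric = TRUE)
  expect_false(rep$ok)
  expect_match(paste(rep$problems, collapse = " "), "asymmetric")
})

test_that("prediction concordance scores planted and null relationships sanely", {
  mat <- symmetrize_measurements(synth_mfi(mfi_generator_spec(
    clusters = list(folate_like_cluster()), seed = 33, missing_fraction = 0)))
  pool <- which(upper.tri(mat$values), arr.ind = TRUE)
  pairs <- data.frame(a = mat$proteins[pool[, 1]], b = mat$proteins[pool[, 2]])
  mfi <- mat$values[pool]
  # planted concordance: binders are exactly the high-MFI pairs
  dg_planted <- transform(pairs, dg = ifelse(mfi > 670, -5, -1))
  r <- prediction_concordance(dg_planted, mat, n_perm = 2000, seed = 3)
  expect_equal(r$fraction_true, 1.0)
  expect_lte(r$p, 0.01)
  # independent free energies: fraction near the base rate
  set.seed(11)
  dg_null <- transform(pairs, dg = runif(nrow(pairs), -6, 0))
  r0 <- prediction_concordance(dg_null, mat, n_perm = 2000, seed = 3)
  base_rate <- mean(mfi > 670)
  expect_lt(abs(r0$fraction_true - base_rate), 0.15)
  # no predicted binders -> explicit error
  dg_none <- transform(pairs, dg = 0)
  expect_error(prediction_concordance(dg_none, mat), "undefined")
})

test_that("concordance p is roughly uniform when free energies carry no signal", {
  mat <- symmetrize_measurements(synth_mfi(mfi_generator_spec(
    n_proteins = 15, seed = 44, missing_fraction = 0)))
  pool <- which(upper.tri(mat$values), arr.ind = TRUE)
  pairs <- data.frame(a = mat$proteins[pool[, 1]], b = mat$proteins[pool[, 2]])
  ps <- vapply(1:150, function(i) {
    set.seed(i)
    dg <- transform(pairs, dg = runif(nrow(pairs), -6, 0))
    prediction_concordance(dg, mat, n_perm = 199, seed = i)$p
  }, numeric(1))
  # discrete statistic -> compare against uniform loosely
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 0)
})
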