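#' Concordance of predicted binders with fluorescence
#'
#' Scores precomputed binding free energies (e.g. from metadynamics on
#' predicted dimers) against the measured interaction matrix.  A pair is a
#' *predicted binder* when its binding free energy is at most `dg_threshold`
#' (kcal/mol, default -3), and a *true prediction* when, in addition, its MFI
#' exceeds `mfi_threshold` (default 670).  Significance is assessed against a
#' null that relabels predicted-binder status uniformly over the evaluated
#' pairs, keeping the number of predicted binders fixed: the null fraction of
#' true predictions is recomputed for each relabelling and the one-sided
#' empirical p-value uses the `(count + 1)/(N + 1)` rule.
#'
#' @param dg data.frame with columns `a`, `b`, `dg` (binding free energy,
#'   kcal/mol); every pair must be present and non-missing in `mat`.
#' @param mat symmetric [ppi_matrix()] of MFI values.
#' @param dg_threshold predicted-binder bound (default -3 kcal/mol).
#' @param mfi_threshold fluorescence bound for a true prediction (default 670).
#' @param n_perm number of relabelling draws (default 10000).
#' @param seed integer RNG seed.
#' @return list with `fraction_true`, `p`, `n_predicted`, `n_true`,
#'   `n_evaluated`, and the per-pair table `detail`.
#' @export
prediction_concordance <- function(dg, mat, dg_threshold = -3,
                                   mfi_threshold = 670, n_perm = 10000,
                                   seed = 1L) {
  req <- c("a", "b", "dg")
  if (!all(req %in% names(dg))) {
    stop("dg must have columns: ", paste(req, collapse = ", "))
  }
  mfi <- pair_values(mat, dg[, c("a", "b")])
  predicted <- dg$dg <= dg_threshold
  n_pred <- sum(predicted)
  if (n_pred == 0) {
    stop("no predicted binders at dg_threshold = ", dg_threshold,
         "; fraction of true predictions is undefined")
  }
  high <- mfi > mfi_threshold
  n_true <- sum(predicted & high)
  frac <- n_true / n_pred
  n <- length(mfi)
  null_frac <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample.int(n, n_pred)
      sum(high[lab]) / n_pred
    }, numeric(1))
  })
  p <- (sum(null_frac >= frac) + 1) / (n_perm + 1)
  list(
    fraction_true = frac, p = p,
    n_predicted = n_pred, n_true = n_true, n_evaluated = n,
    dg_threshold = dg_threshold, mfi_threshold = mfi_threshold,
    n_perm = n_perm, seed = seed,
    detail = data.frame(a = dg$a, b = dg$b, dg = dg$dg, mfi = mfi,
                        predicted = predicted, true_prediction = predicted & high,
                        stringsAsFactors = FALSE)
  )
}
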