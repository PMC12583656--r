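#' Permutation-test configuration
#'
#' @param statistic summary statistic of the pair values, `"median"` (default)
#'   or `"mean"`.
#' @param n_perm number of null draws N (default 10000).
#' @param seed integer RNG seed; required so every result is reproducible.
#' @param include_diagonal logical; include diagonal (homomer) entries in the
#'   null pool (default `FALSE`: the tested clusters are heterodimeric pairs).
#' @return object of class `perm_spec`.
#' @export
perm_spec <- function(statistic = c("median", "mean"), n_perm = 10000,
                      seed = 1L, include_diagonal = FALSE) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(statistic = statistic, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 include_diagonal = isTRUE(include_diagonal)),
            class = "perm_spec")
}

stat_fun <- function(spec) switch(spec$statistic, median = stats::median,
                                  mean = mean)

# Core engine shared by the cluster / cross / propensity tests: observed
# statistic over `obs_values`, null draws of `k` distinct pairs (without
# replacement within a draw, independent across draws) from `pool_values`.
perm_engine <- function(obs_values, pool_values, spec) {
  k <- length(obs_values)
  if (k < 1) stop("pair set must contain at least one pair")
  if (k > length(pool_values)) {
    stop("pair set size (", k, ") exceeds available null pool (",
         length(pool_values), ")")
  }
  f <- stat_fun(spec)
  s_obs <- f(obs_values)
  null_sample <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_perm),
           function(i) f(sample(pool_values, k, replace = FALSE)),
           numeric(1))
  })
  p <- (sum(null_sample >= s_obs) + 1) / (spec$n_perm + 1)
  structure(
    list(s_obs = s_obs, null_sample = null_sample, p = p,
         n_perm = spec$n_perm, statistic = spec$statistic,
         n_pairs = k, seed = spec$seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed %s = %.6g over %d pairs\n",
              x$statistic, x$s_obs, x$n_pairs))
  cat(sprintf("  null: N = %d draws, median %.6g [IQR %.6g, %.6g]\n",
              x$n_perm, stats::median(x$null_sample),
              stats::quantile(x$null_sample, 0.25),
              stats::quantile(x$null_sample, 0.75)))
  cat(sprintf("  one-sided (greater) p = %.6g\n", x$p))
  invisible(x)
}

#' Cluster permutation test on a PPI matrix
#'
#' Tests whether the interaction strengths within a stated set of protein
#' pairs (e.g. a candidate pathway cluster) are collectively higher than
#' expected by chance.  The observed statistic (median by default) of the pair
#' values is compared to an empirical null built by repeatedly sampling the
#' same number of distinct non-missing off-diagonal pairs uniformly from the
#' matrix.  The one-sided empirical p-value is
#' `(#(S_null >= S_obs) + 1) / (N + 1)`, which is bounded in
#' `[1/(N+1), 1]` and needs no distributional assumption.
#'
#' @param mat a symmetric [ppi_matrix()].
#' @param pairs two-column matrix or data.frame of protein identifiers; every
#'   pair must be present and non-missing.
#' @param spec a [perm_spec()].
#' @return A `permutation_result` with elements `s_obs`, `null_sample`, `p`.
#' @export
cluster_permutation_test <- function(mat, pairs, spec = perm_spec()) {
  obs <- pair_values(mat, pairs)
  pool <- offdiag_values(mat, include_diagonal = spec$include_diagonal)
  perm_engine(obs, pool, spec)
}

#' Conditional cross-matrix permutation test
#'
#' Selects pairs by a predicate on one matrix (e.g. structural similarity
#' TM > 0.5) and tests the statistic of those pairs' values in a second
#' matrix (e.g. MFI) against the permutation null of the second matrix.
#'
#' @param select_mat matrix used for selection (shares the protein list with
#'   `value_mat`).
#' @param value_mat matrix whose values are tested.
#' @param predicate function mapping a numeric vector of `select_mat` values
#'   to a logical vector, e.g. `function(v) v > 0.5`.
#' @param subset optional character vector of proteins; when given, selection
#'   is restricted to pairs with both members in `subset` (the null pool
#'   stays whole-matrix by default).
#' @param spec a [perm_spec()].
#' @return A `permutation_result`; the selected pairs are attached as
#'   attribute `"pairs"`.
#' @export
conditional_cross_test <- function(select_mat, value_mat, predicate,
                                   subset = NULL, spec = perm_spec()) {
  if (!identical(select_mat$proteins, value_mat$proteins)) {
    stop("matrices must share the same protein list")
  }
  cand <- offdiag_pairs(select_mat)
  if (!is.null(subset)) {
    cand <- cand[cand$a %in% subset & cand$b %in% subset, , drop = FALSE]
  }
  sel <- predicate(cand$value)
  if (!is.logical(sel) || length(sel) != nrow(cand)) {
    stop("predicate must return one logical per candidate pair")
  }
  cand <- cand[which(sel), , drop = FALSE]
  # restrict to pairs measurable in the value matrix
  i <- match(cand$a, value_mat$proteins)
  j <- match(cand$b, value_mat$proteins)
  cand <- cand[!value_mat$missing[cbind(i, j)], , drop = FALSE]
  if (nrow(cand) == 0) stop("predicate selected no (measurable) pairs")
  res <- cluster_permutation_test(value_mat, cand[, c("a", "b")], spec)
  attr(res, "pairs") <- cand[, c("a", "b")]
  res
}

#' Per-protein interaction-propensity test
#'
#' Tests whether one protein's row of interactions is collectively stronger
#' than random pairs from the matrix: the cluster permutation test applied to
#' all non-missing off-diagonal pairs involving the protein.
#'
#' @param mat symmetric [ppi_matrix()].
#' @param protein protein identifier.
#' @param spec a [perm_spec()].
#' @return A `permutation_result`.
#' @export
protein_propensity_test <- function(mat, protein, spec = perm_spec()) {
  if (!protein %in% mat$proteins) stop("unknown protein: ", protein)
  others <- setdiff(mat$proteins, protein)
  keep <- !mat$missing[protein, others]
  if (!any(keep)) stop("all off-diagonal entries missing for ", protein)
  pairs <- cbind(protein, others[keep])
  cluster_permutation_test(mat, pairs, spec)
}

#' Welch two-sample comparison
#'
#' Unpaired Welch t test (unequal variances, Welch-Satterthwaite degrees of
#' freedom, two-sided).  Degenerate samples with zero variance on both sides
#' and equal means return `t = 0, p = 1` by convention.
#'
#' @param x,y numeric vectors of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Interaction graph of strong pairs
#'
#' Builds the undirected simple graph whose nodes are the proteins and whose
#' edges are non-missing off-diagonal pairs with value >= `threshold`
#' (self-loops excluded), and summarises its connected components and "core"
#' nodes (members of at least one triangle, i.e. a clique of size >= 3).
#'
#' @param mat symmetric [ppi_matrix()].
#' @param threshold edge threshold (default 1100 MFI, the strong-interaction
#'   band).
#' @return list with `graph` (an [igraph::graph] object), `edges`
#'   (data.frame a, b, value), `components` (membership list) and
#'   `core_nodes` (character vector).
#' @export
interaction_graph <- function(mat, threshold = 1100) {
  if (!mat$symmetric) stop("interaction_graph requires a symmetric matrix")
  ed <- offdiag_pairs(mat)
  ed <- ed[ed$value >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = mat$proteins)
  )
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  tri <- igraph::count_triangles(g)
  core <- igraph::V(g)$name[tri > 0]
  list(graph = g, edges = ed, components = membership, core_nodes = core)
}

#' Export graph edges as TSV
#' @param graph_result result of [interaction_graph()].
#' @param path output file.
#' @export
write_edge_list <- function(graph_result, path) {
  utils::write.table(graph_result$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
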