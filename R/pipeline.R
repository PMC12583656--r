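#' Run one of the headline analyses end to end
#'
#' Orchestrates the three standard workflows on a self-contained configuration
#' and writes every result, together with a run manifest (package version,
#' seeds, parameter digest, timestamps, output paths), to `out_dir`.  All
#' randomness derives from the single `seed` via per-stage child seeds, so a
#' rerun with an identical config and seed reproduces identical result files.
#'
#' Recipes:
#' \describe{
#'   \item{`cluster_analysis`}{generate (or load) a two-orientation MFI table,
#'     symmetrise, classify, run the cluster permutation test for each
#'     configured cluster and build the strong-interaction graph.}
#'   \item{`overlap_analysis`}{generate a synthetic chain with planted
#'     surfaces and compute the interface-overlap significance.}
#'   \item{`flux_analysis`}{paired interacting / monomeric reaction-diffusion
#'     runs and the per-reaction flux ratios.}
#' }
#'
#' @param recipe one of `"cluster_analysis"`, `"overlap_analysis"`,
#'   `"flux_analysis"`.
#' @param config named list of recipe parameters; unknown keys are an error.
#'   See the vignette for the accepted keys of each recipe.
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @return the result list, invisibly; side effect: JSON results and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(recipe = c("cluster_analysis", "overlap_analysis",
                                    "flux_analysis"),
                         config = list(), out_dir, seed = 1L) {
  recipe <- match.arg(recipe)
  allowed <- switch(recipe,
    cluster_analysis = c("n_proteins", "clusters", "n_perm", "graph_threshold",
                         "missing_fraction"),
    overlap_analysis = c("chain_length", "n_surfaces", "surface_radius",
                         "shared_fraction", "n_r", "n_sets"),
    flux_analysis = c("copies_per_type", "concentration", "viscosity",
                      "n_steps", "n_replicas", "mfi_strong")
  )
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s) for recipe '", recipe, "': ",
         paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 8)

  result <- switch(recipe,
    cluster_analysis = {
      n_proteins <- config$n_proteins %||% 35
      clusters <- config$clusters %||%
        list(sprintf("P%02d", 1:5))
      n_perm <- config$n_perm %||% 10000
      spec <- mfi_generator_spec(
        n_proteins = n_proteins, clusters = clusters,
        missing_fraction = config$missing_fraction %||% 0.03,
        seed = seeds[1])
      meas <- synth_mfi(spec)
      mat <- symmetrize_measurements(meas)
      tests <- lapply(clusters, function(cl) {
        pairs <- t(utils::combn(cl, 2))
        pairs <- pairs[!mat$missing[pairs], , drop = FALSE]
        r <- cluster_permutation_test(mat, pairs,
                                      perm_spec(n_perm = n_perm,
                                                seed = seeds[2]))
        list(cluster = cl, n_pairs = r$n_pairs, s_obs = r$s_obs, p = r$p,
             statistic = r$statistic, n_perm = r$n_perm, seed = r$seed)
      })
      graph <- interaction_graph(mat,
                                 threshold = config$graph_threshold %||% 1100)
      write_ppi_matrix(mat, file.path(out_dir, "matrix.tsv"))
      write_edge_list(graph, file.path(out_dir, "graph_edges.tsv"))
      list(cluster_tests = tests,
           classes = table(classify_mfi(offdiag_values(mat))),
           components = graph$components, core_nodes = graph$core_nodes)
    },
    overlap_analysis = {
      syn <- synth_structure(
        length = config$chain_length %||% 60,
        surfaces = data.frame(
          center = round(seq(10, (config$chain_length %||% 60) - 10,
                             length.out = config$n_surfaces %||% 4)),
          radius = config$surface_radius %||% 10),
        shared_fraction = config$shared_fraction %||% 1,
        seed = seeds[1])
      ov <- overlap_significance(
        syn$surfaces, syn$structure,
        n_r = config$n_r %||% 20, n_sets = config$n_sets %||% 500,
        seed = seeds[2])
      write_surfaces(syn$surfaces, file.path(out_dir, "surfaces.tsv"))
      list(misc_o = ov$misc_o, misc_r_mean = ov$misc_r_mean,
           misc_r_sd = ov$misc_r_sd, z = ov$z, p = ov$p,
           significant = ov$significant, n_r = ov$n_r, n_sets = ov$n_sets,
           probe_radius = ov$probe_radius)
    },
    flux_analysis = {
      cfg <- patchy_config(
        copies_per_type = config$copies_per_type %||% 4,
        concentration = config$concentration %||% 2e-3,
        viscosity = config$viscosity %||% 1e-4,
        integrator = "brownian",
        n_steps = config$n_steps %||% 20000,
        record_every = 1000)
      scheme <- reaction_scheme(n_steps = cfg$n_types, efficiency = "equal",
                                p_scale = 1e3, seed = seeds[1])
      mfi <- matrix(config$mfi_strong %||% 1200, cfg$n_types, cfg$n_types,
                    dimnames = list(paste0("E", 1:cfg$n_types),
                                    paste0("E", 1:cfg$n_types)))
      energy <- ppi_energy_map(ppi_matrix(mfi, symmetric = TRUE))
      on <- run_patchy(cfg, scheme, energy, mode = "ppi_on", seed = seeds[2])
      off <- run_patchy(cfg, scheme, energy, mode = "ppi_off", seed = seeds[2])
      fr <- flux_ratio(on, off)
      list(ratio = as.list(fr$ratio), counts_on = as.list(fr$counts_on),
           counts_off = as.list(fr$counts_off),
           p_scale = scheme$p_scale,
           mean_cluster_size_on = weighted_mean_cluster(on),
           mean_cluster_size_off = weighted_mean_cluster(off))
    }
  )

  res_path <- file.path(out_dir, "result.json")
  jsonlite::write_json(result, res_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest <- list(
    package = "metabolon",
    version = as.character(utils::packageVersion("metabolon")),
    recipe = recipe,
    seed = seed,
    child_seeds = seeds,
    config = config,
    config_digest = config_digest(list(recipe = recipe, config = config,
                                       seed = seed)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean cluster size weighted by the per-frame cluster-size histogram.
weighted_mean_cluster <- function(traj) {
  h <- traj$cluster_size_hist
  sizes <- seq_along(h)
  if (sum(h) == 0) return(1)
  sum(sizes * h) / sum(h)
}

# Order-independent digest of a config: serialised canonical text -> sum of
# character codes (no external digest dependency; collision resistance is not
# a goal, reproducibility labelling is).
config_digest <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}
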