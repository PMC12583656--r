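#' Specification for synthetic two-orientation fluorescence data
#'
#' The generator emulates the structure of a split-fluorophore screening
#' matrix: a background of weak signal, one or more planted clusters of
#' strongly interacting proteins, homo-oligomer signal on the diagonal, one
#' orientation attenuated by a random factor (fusion-geometry dropout), and a
#' small fraction of pairs lost to poor growth (encoded as wells with too few
#' analysed cells).
#'
#' @param n_proteins number of proteins (default 35).
#' @param background_mean,background_sd background MFI distribution,
#'   truncated at 0 (defaults 600, 60).
#' @param clusters list of character vectors of protein names; all pairs
#'   within a cluster are drawn from the cluster distribution.
#' @param cluster_mean,cluster_sd cluster MFI distribution (defaults 1150, 80).
#' @param diagonal_mean,diagonal_sd homodimer MFI distribution (defaults 900,
#'   300, truncated at 0).
#' @param attenuation_range one orientation of every pair is multiplied by a
#'   factor drawn uniformly from this interval (default c(0.5, 1)).
#' @param missing_fraction fraction of pairs marked unanalysable (default
#'   0.03).
#' @param min_cells_mean mean analysed-cell count of retained wells (default
#'   30000); discarded wells get counts below the 10000-cell threshold.
#' @param seed integer RNG seed.
#' @return object of class `mfi_generator_spec`.
#' @export
mfi_generator_spec <- function(n_proteins = 35, background_mean = 600,
                               background_sd = 60, clusters = list(),
                               cluster_mean = 1150, cluster_sd = 80,
                               diagonal_mean = 900, diagonal_sd = 300,
                               attenuation_range = c(0.5, 1),
                               missing_fraction = 0.03,
                               min_cells_mean = 30000, seed = 1L) {
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  for (cl in clusters) {
    if (!all(cl %in% proteins)) {
      stop("cluster member(s) outside the protein list: ",
           paste(setdiff(cl, proteins), collapse = ", "))
    }
  }
  structure(list(
    n_proteins = n_proteins, proteins = proteins,
    background_mean = background_mean, background_sd = background_sd,
    clusters = clusters, cluster_mean = cluster_mean, cluster_sd = cluster_sd,
    diagonal_mean = diagonal_mean, diagonal_sd = diagonal_sd,
    attenuation_range = attenuation_range,
    missing_fraction = missing_fraction, min_cells_mean = min_cells_mean,
    seed = as.integer(seed)
  ), class = "mfi_generator_spec")
}

rtruncnorm0 <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

#' Generate a synthetic two-orientation measurement table
#'
#' @param spec an [mfi_generator_spec()].
#' @return data.frame with columns `protein_a`, `protein_b`, `orientation`,
#'   `mfi`, `n_cells` (two rows per unordered pair, diagonal included), with
#'   the generator spec and seed attached as attribute `"provenance"`.
#' @export
synth_mfi <- function(spec = mfi_generator_spec()) {
  with_seed(spec$seed, {
    pr <- spec$proteins
    pairs <- expand.grid(i = seq_along(pr), j = seq_along(pr))
    pairs <- pairs[pairs$i <= pairs$j, ]
    in_cluster <- rep(FALSE, nrow(pairs))
    for (cl in spec$clusters) {
      ci <- match(cl, pr)
      in_cluster <- in_cluster |
        (pairs$i %in% ci & pairs$j %in% ci & pairs$i != pairs$j)
    }
    on_diag <- pairs$i == pairs$j
    base <- numeric(nrow(pairs))
    base[!in_cluster & !on_diag] <-
      rtruncnorm0(sum(!in_cluster & !on_diag), spec$background_mean,
                  spec$background_sd)
    base[in_cluster] <- rtruncnorm0(sum(in_cluster), spec$cluster_mean,
                                    spec$cluster_sd)
    base[on_diag] <- rtruncnorm0(sum(on_diag), spec$diagonal_mean,
                                 spec$diagonal_sd)
    # orientation attenuation: one orientation (random which) gets the full
    # value, the other an attenuated copy
    att <- stats::runif(nrow(pairs), spec$attenuation_range[1],
                        spec$attenuation_range[2])
    full_first <- stats::runif(nrow(pairs)) < 0.5
    mfi1 <- ifelse(full_first, base, base * att)
    mfi2 <- ifelse(full_first, base * att, base)
    # missing pairs: both orientations fail cell-count QC
    miss <- stats::runif(nrow(pairs)) < spec$missing_fraction
    cells <- function(ok) {
      ifelse(ok, round(rtruncnorm0(nrow(pairs), spec$min_cells_mean,
                                   spec$min_cells_mean / 6)) + 10000,
             round(stats::runif(nrow(pairs), 0, 9999)))
    }
    out <- rbind(
      data.frame(protein_a = pr[pairs$i], protein_b = pr[pairs$j],
                 orientation = "N_A_C_B", mfi = mfi1, n_cells = cells(!miss),
                 stringsAsFactors = FALSE),
      data.frame(protein_a = pr[pairs$i], protein_b = pr[pairs$j],
                 orientation = "N_B_C_A", mfi = mfi2, n_cells = cells(!miss),
                 stringsAsFactors = FALSE)
    )
    rownames(out) <- NULL
    attr(out, "provenance") <- list(spec = spec, seed = spec$seed)
    out
  })
}

#' Generate a synthetic structural-similarity (TM-like) matrix
#'
#' Symmetric matrix of values in [0, 1].  With coupling `c`, each planted
#' cluster pair receives a high score from Uniform(0.5, 0.9) with probability
#' `c` and a background score otherwise; background pairs always draw from
#' Uniform(0.1, 0.45).
#'
#' @param spec an [mfi_generator_spec()] (re-used for the protein list and
#'   planted clusters).
#' @param coupling probability in [0, 1] that a planted pair is scored
#'   structurally similar.
#' @param seed RNG seed (defaults to `spec$seed + 1` so MFI and TM noise are
#'   independent).
#' @return a symmetric [ppi_matrix()] of TM-like scores.
#' @export
synth_tm <- function(spec = mfi_generator_spec(), coupling = 1,
                     seed = spec$seed + 1L) {
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  with_seed(seed, {
    pr <- spec$proteins
    n <- length(pr)
    v <- matrix(0, n, n, dimnames = list(pr, pr))
    bg <- function(k) stats::runif(k, 0.1, 0.45)
    hi <- function(k) stats::runif(k, 0.5, 0.9)
    up <- which(upper.tri(v, diag = FALSE), arr.ind = TRUE)
    vals <- bg(nrow(up))
    in_cluster <- rep(FALSE, nrow(up))
    for (cl in spec$clusters) {
      ci <- match(cl, pr)
      in_cluster <- in_cluster | (up[, 1] %in% ci & up[, 2] %in% ci)
    }
    coupled <- in_cluster & stats::runif(nrow(up)) < coupling
    vals[coupled] <- hi(sum(coupled))
    v[up] <- vals
    v <- v + t(v)
    diag(v) <- 1
    ppi_matrix(v, proteins = pr, symmetric = TRUE)
  })
}

#' Generate a synthetic Calpha chain with planted interaction surfaces
#'
#' Builds a compact self-avoiding virtual-Calpha chain (3.8 A bonds) or an
#' ideal alpha-helix, assigns relative solvent accessibilities such that a
#' requested fraction of residues is exposed, and realises planted surfaces as
#' balls of given radius around chosen centre residues, with a controllable
#' shared fraction between consecutive surfaces.
#'
#' @param length chain length in residues (default 60).
#' @param geometry `"walk"` (compact self-avoiding walk, default) or
#'   `"helix"`.
#' @param exposed_fraction fraction of residues assigned RSA above 0.25
#'   (default 0.6).
#' @param surfaces optional data.frame with columns `center` (residue number)
#'   and `radius` (Angstrom); each row plants one surface consisting of all
#'   residues within the radius of the centre residue.
#' @param shared_fraction optional value in [0, 1]: when given with >= 2
#'   surfaces, surfaces after the first are rebuilt to share this fraction of
#'   the first surface's residues (the remainder drawn from residues outside
#'   it), enabling overlap-recovery sweeps.
#' @param seed integer RNG seed.
#' @return list with `structure` (a [ca_structure()] with RSA) and `surfaces`
#'   (list of [interaction_surface()]s), provenance attached.
#' @export
synth_structure <- function(length = 60, geometry = c("walk", "helix"),
                            exposed_fraction = 0.6, surfaces = NULL,
                            shared_fraction = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  with_seed(seed, {
    xyz <- if (geometry == "helix") {
      t <- seq_len(length)
      cbind(2.3 * cos(t * 100 * pi / 180), 2.3 * sin(t * 100 * pi / 180),
            1.5 * t)
    } else {
      # compact self-avoiding walk: biased random steps of 3.8 A rejected on
      # close approach, with a weak pull to the origin for compactness
      x <- matrix(0, length, 3)
      for (i in 2:length) {
        for (attempt in 1:500) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          pull <- -x[i - 1, ]
          np <- sqrt(sum(pull^2))
          if (np > 1e-9) dir <- dir + 0.25 * pull / np
          dir <- dir / sqrt(sum(dir^2))
          cand <- x[i - 1, ] + 3.8 * dir
          prev <- x[seq_len(max(1, i - 2)), , drop = FALSE]
          d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
          if (all(d2 > 3.5^2)) { x[i, ] <- cand; break }
          if (attempt == 500) stop("self-avoiding walk failed to extend")
        }
      }
      x
    }
    # small jitter so consecutive bonds are 3.8 +/- <0.1 A after perturbation
    xyz <- xyz + matrix(stats::rnorm(3 * length, 0, 0.02), length, 3)
    resno <- seq_len(length)
    n_exposed <- max(1, round(exposed_fraction * length))
    rsa <- stats::runif(length, 0, 0.2)
    exposed_idx <- sample.int(length, n_exposed)
    rsa[exposed_idx] <- stats::runif(n_exposed, 0.3, 1)
    st <- ca_structure(resno, xyz, rsa = rsa)

    surf_list <- list()
    if (!is.null(surfaces)) {
      surf_list <- lapply(seq_len(nrow(surfaces)), function(k) {
        ctr <- surfaces$center[k]
        rad <- surfaces$radius[k]
        ci <- match(ctr, resno)
        if (is.na(ci)) stop("surface centre outside the chain: ", ctr)
        d2 <- rowSums((xyz - matrix(xyz[ci, ], length, 3, byrow = TRUE))^2)
        interaction_surface("synthetic", paste0("partner", k),
                            resno[d2 <= rad^2])
      })
      if (!is.null(shared_fraction) && base::length(surf_list) >= 2) {
        ref <- surf_list[[1]]$residues
        m <- base::length(ref)
        n_shared <- round(shared_fraction * m)
        pool <- setdiff(resno, ref)
        surf_list[2:base::length(surf_list)] <-
          lapply(2:base::length(surf_list), function(k) {
            keep <- if (n_shared > 0) sample(ref, n_shared) else integer()
            fill <- if (m - n_shared > 0) sample(pool, m - n_shared) else integer()
            interaction_surface("synthetic", paste0("partner", k),
                                c(keep, fill))
          })
      }
    }
    out <- list(structure = st, surfaces = surf_list)
    attr(out, "provenance") <- list(length = length, geometry = geometry,
                                    exposed_fraction = exposed_fraction,
                                    shared_fraction = shared_fraction,
                                    seed = seed)
    out
  })
}

#' Generate a synthetic two-chain complex
#'
#' Places two synthetic chains so that their minimal inter-chain Calpha
#' distance equals `gap` (the second chain is translated along the axis
#' joining the closest approach).  Useful for exercising interface
#' extraction: `gap` above the contact cutoff yields empty interfaces.
#'
#' @param length_a,length_b chain lengths (defaults 40).
#' @param gap minimal inter-chain Calpha distance, Angstrom (>= 0).
#' @param mirror logical; build chain B as a mirror copy of chain A (a
#'   symmetric dimer whose interfaces are identical residue sets).
#' @param seed RNG seed.
#' @return list with `chain_a`, `chain_b` ([ca_structure()]s, chains "A" and
#'   "B") and the realised `gap`.
#' @export
synth_dimer <- function(length_a = 40, length_b = 40, gap = 5,
                        mirror = FALSE, seed = 1L) {
  if (gap < 0) stop("gap must be >= 0")
  a <- synth_structure(length = length_a, seed = seed)$structure
  b <- if (mirror) {
    xyz_b <- a$xyz
    xyz_b[, 1] <- -xyz_b[, 1]   # reflect through the yz plane
    ca_structure(a$resno, xyz_b, rsa = a$rsa, chain = "B")
  } else {
    st <- synth_structure(length = length_b, seed = seed + 1L)$structure
    ca_structure(st$resno, st$xyz, rsa = st$rsa, chain = "B")
  }
  a <- ca_structure(a$resno, a$xyz, rsa = a$rsa, chain = "A")
  # shift B along x until the minimal inter-chain distance equals gap
  shift0 <- max(a$xyz[, 1]) - min(b$xyz[, 1])
  xyz_b <- b$xyz
  xyz_b[, 1] <- xyz_b[, 1] + shift0
  mind <- function(xb) {
    d2 <- outer(rowSums(a$xyz^2), rowSums(xb^2), "+") - 2 * a$xyz %*% t(xb)
    sqrt(max(min(d2), 0))
  }
  # the minimal distance as a function of the extra x-offset is V-shaped;
  # locate the increasing branch with a coarse scan, then bisect on it
  offs <- seq(-100, 400, by = 1)
  md <- vapply(offs, function(m) {
    xb <- xyz_b; xb[, 1] <- xb[, 1] + m; mind(xb)
  }, numeric(1))
  i_min <- which.min(md)
  branch <- offs[i_min:length(offs)]
  below <- branch[vapply(branch, function(m) {
    xb <- xyz_b; xb[, 1] <- xb[, 1] + m; mind(xb) < gap
  }, logical(1))]
  lo <- if (length(below) > 0) max(below) else offs[i_min]
  hi <- lo + 1
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    xb <- xyz_b; xb[, 1] <- xb[, 1] + mid
    if (mind(xb) < gap) lo <- mid else hi <- mid
  }
  xyz_b[, 1] <- xyz_b[, 1] + hi
  b <- ca_structure(b$resno, xyz_b, rsa = b$rsa, chain = "B")
  list(chain_a = a, chain_b = b, gap = mind(xyz_b))
}
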