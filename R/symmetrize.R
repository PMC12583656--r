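#' Symmetrise two-orientation fluorescence measurements
#'
#' In the split-fluorophore assay every protein pair X/Y is measured in two
#' fusion orientations (N-half on X with C-half on Y, and the reverse).  A
#' fusion that is suboptimal in one orientation can abolish signal there, so
#' the symmetric interaction matrix takes, for each pair, the maximum MFI over
#' the orientations that passed quality control.  Wells with fewer analysed
#' cells than `min_cells` are discarded; a pair with no retained orientation is
#' marked missing.
#'
#' @param measurements data.frame with columns `protein_a`, `protein_b`,
#'   `orientation` (one of `"N_A_C_B"`, `"N_B_C_A"`), `mfi` (non-negative) and
#'   `n_cells` (non-negative count).
#' @param min_cells minimum number of analysed cells for a well to be retained
#'   (default 10000).
#' @param proteins optional character vector fixing the identity and order of
#'   the matrix rows; defaults to the sorted union of proteins seen in
#'   `measurements`.
#'
#' @return A symmetric [ppi_matrix()].  Pairs never measured, or whose every
#'   orientation fell below `min_cells`, are missing.
#' @export
symmetrize_measurements <- function(measurements, min_cells = 10000,
                                    proteins = NULL) {
  req <- c("protein_a", "protein_b", "orientation", "mfi", "n_cells")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  }
  if (min_cells < 0) stop("min_cells must be >= 0")
  ok_orient <- measurements$orientation %in% c("N_A_C_B", "N_B_C_A")
  if (!all(ok_orient)) {
    stop("invalid orientation value(s): ",
         paste(unique(measurements$orientation[!ok_orient]), collapse = ", "))
  }
  if (any(measurements$mfi < 0, na.rm = TRUE)) stop("mfi must be >= 0")
  if (any(measurements$n_cells < 0, na.rm = TRUE)) stop("n_cells must be >= 0")

  # canonical unordered pair + canonical orientation (orientation is defined
  # relative to the *sorted* pair so that duplicates are detected regardless
  # of how the row writes the pair)
  a <- as.character(measurements$protein_a)
  b <- as.character(measurements$protein_b)
  flip <- a > b
  orient <- as.character(measurements$orientation)
  orient[flip] <- ifelse(orient[flip] == "N_A_C_B", "N_B_C_A", "N_A_C_B")
  pa <- ifelse(flip, b, a)
  pb <- ifelse(flip, a, b)
  key <- paste(pa, pb, orient, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    rows <- which(dup)
    stop("duplicate (pair, orientation) records at rows: ",
         paste(rows, collapse = ", "), " [",
         paste(unique(paste0(pa[dup], "/", pb[dup], ":", orient[dup])),
               collapse = ", "), "]")
  }

  if (is.null(proteins)) proteins <- sort(unique(c(pa, pb)))
  vals <- matrix(NA_real_, length(proteins), length(proteins),
                 dimnames = list(proteins, proteins))
  keep <- measurements$n_cells >= min_cells
  i <- match(pa[keep], proteins)
  j <- match(pb[keep], proteins)
  if (anyNA(i) || anyNA(j)) stop("measurements contain proteins not in 'proteins'")
  for (k in seq_along(i)) {
    v <- measurements$mfi[keep][k]
    cur <- vals[i[k], j[k]]
    if (is.na(cur) || v > cur) {
      vals[i[k], j[k]] <- v
      vals[j[k], i[k]] <- v
    }
  }
  ppi_matrix(vals, proteins = proteins, symmetric = TRUE)
}

#' Classify an interaction strength from MFI
#'
#' Thresholds follow the colour code of the interaction heat map: below
#' `none_below` no interaction, then weak, moderate and strong bands.  The
#' source bands are written with strict inequalities on both sides, which
#' leaves exact threshold values unassigned; this implementation adopts
#' half-open intervals `[none_below, weak_upper)`, `[weak_upper,
#' moderate_upper)` and `[moderate_upper, Inf)` so that every non-negative MFI
#' maps to exactly one class.
#'
#' @param mfi numeric vector of non-negative MFI values.
#' @param scheme a [classification_scheme()].
#' @return factor with levels `none`, `weak`, `moderate`, `strong`.
#' @export
classify_mfi <- function(mfi, scheme = classification_scheme()) {
  if (any(mfi < 0, na.rm = TRUE)) stop("mfi must be >= 0")
  cut(mfi,
      breaks = c(-Inf, scheme$none_below, scheme$weak_upper,
                 scheme$moderate_upper, Inf),
      labels = c("none", "weak", "moderate", "strong"),
      right = FALSE)
}

#' @rdname classify_mfi
#' @param none_below,weak_upper,moderate_upper class boundaries (defaults 750,
#'   900, 1100 MFI).
#' @export
classification_scheme <- function(none_below = 750, weak_upper = 900,
                                  moderate_upper = 1100) {
  if (!(none_below < weak_upper && weak_upper < moderate_upper)) {
    stop("require none_below < weak_upper < moderate_upper")
  }
  structure(list(none_below = none_below, weak_upper = weak_upper,
                 moderate_upper = moderate_upper),
            class = "classification_scheme")
}
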