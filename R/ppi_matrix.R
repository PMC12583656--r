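#' Labelled protein-protein interaction matrix
#'
#' Container for a square matrix of mean-fluorescence-intensity (MFI) or
#' TM-score values indexed by protein identifiers, with an explicit missing
#' mask.  Missing entries (e.g. pairs whose co-transformed cultures grew too
#' poorly to analyse) are carried as `NA` in `values` and `TRUE` in `missing`.
#' Diagonal entries are permitted and represent homo-oligomer signal.
#'
#' @param values numeric square matrix; `NA` marks a missing measurement.
#'   Row/column names, if present, are used as protein identifiers.
#' @param proteins character vector of protein identifiers (defaults to
#'   rownames of `values`, or `P1..Pn`).
#' @param symmetric logical flag; if `TRUE` the matrix is checked for symmetry
#'   (values and missingness).
#'
#' @return An object of class `ppi_matrix`: a list with elements `proteins`,
#'   `values` (with dimnames set), `missing`, and `symmetric`.
#' @export
ppi_matrix <- function(values, proteins = NULL, symmetric = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("'values' must be a square matrix, got ", nrow(values), "x", ncol(values))
  }
  if (is.null(proteins)) {
    proteins <- rownames(values)
    if (is.null(proteins)) proteins <- paste0("P", seq_len(nrow(values)))
  }
  proteins <- as.character(proteins)
  if (length(proteins) != nrow(values)) {
    stop("length(proteins) must equal nrow(values)")
  }
  if (anyDuplicated(proteins)) stop("protein identifiers must be unique")
  dimnames(values) <- list(proteins, proteins)
  if (any(values < 0, na.rm = TRUE)) {
    stop("non-missing matrix values must be >= 0")
  }
  missing <- is.na(values)
  if (symmetric) {
    bad_v <- which(!is.na(values) & !is.na(t(values)) & values != t(values),
                   arr.ind = TRUE)
    bad_m <- which(missing != t(missing), arr.ind = TRUE)
    if (nrow(bad_v) > 0 || nrow(bad_m) > 0) {
      cells <- rbind(bad_v, bad_m)
      stop("matrix flagged symmetric but is not; offending cells: ",
           paste(proteins[cells[, 1]], proteins[cells[, 2]],
                 sep = "/", collapse = ", "))
    }
  }
  structure(
    list(proteins = proteins, values = values, missing = missing,
         symmetric = isTRUE(symmetric)),
    class = "ppi_matrix"
  )
}

#' @export
print.ppi_matrix <- function(x, ...) {
  p <- length(x$proteins)
  n_miss <- sum(x$missing)
  cat(sprintf("ppi_matrix: %d x %d (%s), %d missing entr%s\n",
              p, p, if (x$symmetric) "symmetric" else "asymmetric",
              n_miss, if (n_miss == 1) "y" else "ies"))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
summary.ppi_matrix <- function(object, ...) {
  v <- offdiag_values(object)
  out <- list(
    n_proteins = length(object$proteins),
    n_missing = sum(object$missing),
    offdiag_summary = summary(v),
    diag_summary = summary(diag(object$values))
  )
  class(out) <- "summary.ppi_matrix"
  out
}

#' @export
print.summary.ppi_matrix <- function(x, ...) {
  cat("proteins:", x$n_proteins, " missing entries:", x$n_missing, "\n")
  cat("off-diagonal values:\n"); print(x$offdiag_summary)
  cat("diagonal values:\n"); print(x$diag_summary)
  invisible(x)
}

# Unique unordered off-diagonal pairs with non-missing values (the permutation
# null pool).  Returns a data.frame with columns a, b (protein ids) and value.
offdiag_pairs <- function(mat, include_diagonal = FALSE) {
  stopifnot(inherits(mat, "ppi_matrix"))
  p <- length(mat$proteins)
  idx <- which(upper.tri(mat$values, diag = include_diagonal) & !mat$missing,
               arr.ind = TRUE)
  data.frame(
    a = mat$proteins[idx[, 1]],
    b = mat$proteins[idx[, 2]],
    value = mat$values[idx],
    stringsAsFactors = FALSE
  )
}

offdiag_values <- function(mat, include_diagonal = FALSE) {
  offdiag_pairs(mat, include_diagonal)$value
}

# Look up values for a 2-column pair specification, erroring on pairs that are
# absent or missing.  `pairs` is a matrix/data.frame of protein identifiers.
pair_values <- function(mat, pairs) {
  stopifnot(inherits(mat, "ppi_matrix"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("'pairs' must have two columns")
  unknown <- setdiff(unique(c(pairs)), mat$proteins)
  if (length(unknown) > 0) {
    stop("unknown protein(s): ", paste(unknown, collapse = ", "))
  }
  i <- match(pairs[, 1], mat$proteins)
  j <- match(pairs[, 2], mat$proteins)
  miss <- mat$missing[cbind(i, j)]
  if (any(miss)) {
    bad <- paste(pairs[miss, 1], pairs[miss, 2], sep = "/")
    stop("pair(s) with missing values: ", paste(bad, collapse = ", "))
  }
  mat$values[cbind(i, j)]
}

#' Read / write a labelled matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first row and first
#' column hold protein identifiers and whose cells hold values, with missing
#' entries written as `NA`.  The round trip is value-exact (values are written
#' with full precision).
#'
#' @param path file path.
#' @param symmetric logical, passed to [ppi_matrix()].
#' @return `read_ppi_matrix` returns a [ppi_matrix()]; `write_ppi_matrix`
#'   returns `path` invisibly.
#' @export
read_ppi_matrix <- function(path, symmetric = FALSE) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ppi_matrix(as.matrix(tab), symmetric = symmetric)
}

#' @rdname read_ppi_matrix
#' @param mat a [ppi_matrix()].
#' @export
write_ppi_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "ppi_matrix"))
  df <- as.data.frame(format(mat$values, digits = 17, trim = TRUE),
                      check.names = FALSE)
  df[is.na(mat$values)] <- NA
  utils::write.table(cbind(protein = mat$proteins, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a matrix file
#'
#' Checks a TSV matrix file for squareness, label consistency, symmetry (when
#' claimed), `NA` coding and value ranges.  Returns a report rather than
#' stopping, so callers can surface all problems at once.
#'
#' @param path file path to a TSV matrix.
#' @param expect_symmetric logical; if `TRUE`, asymmetric cells are reported
#'   as failures.
#' @return A list with elements `ok` (logical) and `problems` (character
#'   vector, empty when `ok`).
#' @export
validate_ppi_matrix_file <- function(path, expect_symmetric = FALSE) {
  problems <- character()
  if (!file.exists(path)) {
    return(list(ok = FALSE, problems = paste("file not found:", path)))
  }
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) e
  )
  if (inherits(tab, "error")) {
    return(list(ok = FALSE, problems = paste("unreadable:", conditionMessage(tab))))
  }
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    problems <- c(problems, sprintf("not square: %d rows, %d columns",
                                    nrow(m), ncol(m)))
  } else {
    if (!identical(rownames(m), colnames(m))) {
      problems <- c(problems, "row labels do not match column labels")
    }
    if (!is.numeric(m)) {
      problems <- c(problems, "non-numeric cells present")
    } else {
      if (any(m < 0, na.rm = TRUE)) {
        bad <- which(m < 0, arr.ind = TRUE)
        problems <- c(problems, paste0("negative values at: ",
          paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]], sep = "/",
                collapse = ", ")))
      }
      if (expect_symmetric) {
        asym <- which((is.na(m) != is.na(t(m))) |
                        (!is.na(m) & !is.na(t(m)) & m != t(m)), arr.ind = TRUE)
        if (nrow(asym) > 0) {
          problems <- c(problems, paste0("asymmetric cells: ",
            paste(rownames(m)[asym[, 1]], colnames(m)[asym[, 2]], sep = "/",
                  collapse = ", ")))
        }
      }
    }
  }
  list(ok = length(problems) == 0, problems = problems)
}
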