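#' Calpha-level protein structure
#'
#' Minimal structure representation used by the interface statistics: per
#' residue a source-numbering residue id, a Calpha coordinate in Angstrom and
#' (optionally) a relative solvent accessibility in [0, 1].
#'
#' @param resno integer vector of unique residue numbers (source numbering,
#'   1-based, preserved as given).
#' @param xyz numeric matrix, one row per residue, columns x, y, z (Angstrom).
#' @param rsa optional numeric vector of relative solvent accessibilities in
#'   [0, 1].
#' @param chain optional chain identifier (single string) kept as metadata.
#' @return object of class `ca_structure`.
#' @export
ca_structure <- function(resno, xyz, rsa = NULL, chain = "A") {
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  if (nrow(xyz) != length(resno)) stop("resno and xyz disagree in length")
  if (anyDuplicated(resno)) stop("residue numbers must be unique")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!is.null(rsa)) {
    if (length(rsa) != length(resno)) stop("rsa length mismatch")
    if (any(rsa < 0 | rsa > 1, na.rm = TRUE)) stop("rsa must lie in [0, 1]")
  }
  structure(list(resno = resno, xyz = xyz, rsa = rsa, chain = chain),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("ca_structure: chain %s, %d residues%s\n", x$chain,
              length(x$resno), if (is.null(x$rsa)) " (no RSA)" else ""))
  invisible(x)
}

#' Read Calpha records from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` keeping only Calpha atoms of the
#' requested chain.  Relative solvent accessibility is not present in PDB
#' files; attach it afterwards via [attach_rsa()].
#'
#' @param path PDB file.
#' @param chain chain identifier (default: first chain in the file).
#' @return a [ca_structure()].
#' @export
read_ca_pdb <- function(path, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (is.null(chain)) chain <- ca$chain[1]
  ca <- ca[ca$chain == chain, , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms for chain ", chain, " in ", path)
  ca_structure(ca$resno, as.matrix(ca[, c("x", "y", "z")]), chain = chain)
}

# Theoretical maximum accessible surface areas (A^2) per residue, Tien et al.
# (2013), used to normalise raw areas to relative accessibility.
MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

#' Attach relative solvent accessibility to a structure
#'
#' Reads a sidecar TSV with columns `resno` and either `rsa` (already
#' relative, in [0,1]) or `asa` plus `aa` (raw area in A^2 and one-letter
#' residue code, normalised by the Tien et al. theoretical maxima).
#'
#' @param structure a [ca_structure()].
#' @param path TSV file path.
#' @return the structure with `$rsa` filled in.
#' @export
attach_rsa <- function(structure, path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"resno" %in% names(tab)) stop("RSA table needs a 'resno' column")
  if ("rsa" %in% names(tab)) {
    rsa_tab <- tab$rsa
  } else if (all(c("asa", "aa") %in% names(tab))) {
    mx <- MAX_ASA[tab$aa]
    if (anyNA(mx)) stop("unknown residue code(s): ",
                        paste(unique(tab$aa[is.na(mx)]), collapse = ", "))
    rsa_tab <- pmin(tab$asa / mx, 1)
  } else {
    stop("RSA table needs 'rsa', or 'asa' plus 'aa', columns")
  }
  idx <- match(structure$resno, tab$resno)
  if (anyNA(idx)) {
    stop("RSA table lacks residue(s): ",
         paste(structure$resno[is.na(idx)], collapse = ", "))
  }
  structure$rsa <- rsa_tab[idx]
  if (any(structure$rsa < 0 | structure$rsa > 1)) stop("rsa must lie in [0, 1]")
  structure
}

#' Solvent-exposed residues
#'
#' Residues with relative solvent accessibility strictly above the threshold
#' (default 0.25) are considered exposed; only these seed random surfaces.
#'
#' @param structure a [ca_structure()] carrying RSA.
#' @param rsa_threshold exposure threshold (default 0.25).
#' @return integer vector of exposed residue numbers.
#' @export
exposed_residues <- function(structure, rsa_threshold = 0.25) {
  if (is.null(structure$rsa)) stop("structure carries no RSA values")
  out <- structure$resno[structure$rsa > rsa_threshold]
  if (length(out) == 0) {
    stop("no residue exceeds RSA threshold ", rsa_threshold)
  }
  out
}
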