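#' Expand a degenerate codon and size the mutagenesis library
#'
#' Enumerates all concrete codons encoded by an IUPAC degenerate triplet
#' (e.g. `"VDS"` = [ACG][AGT][GC]), translates them with the standard genetic
#' code, and reports the arithmetic of a site-saturation library built by
#' placing the degenerate codon at `n_positions` independent positions:
#' the amino-acid library size is `n_positions * (distinct amino acids)` and
#' the total codon-variant count is `n_positions * (codon count)`.
#'
#' @param code three-letter IUPAC degenerate codon (case-insensitive).
#' @param n_positions number of positions mutagenised (default 1).
#' @return list with `codons` (character vector), `n_codons`, `amino_acids`
#'   (distinct amino acids encoded, stops excluded), `n_amino_acids`,
#'   `has_stop`, `library_size`, `n_codon_variants`.
#' @export
expand_degenerate_codon <- function(code, n_positions = 1) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("expand_degenerate_codon requires the 'Biostrings' package")
  }
  code <- toupper(code)
  if (nchar(code) != 3) stop("a codon has exactly 3 letters, got: ", code)
  if (n_positions < 1) stop("n_positions must be >= 1")
  iupac <- Biostrings::IUPAC_CODE_MAP
  letters3 <- strsplit(code, "")[[1]]
  bad <- !letters3 %in% names(iupac)
  if (any(bad)) {
    stop("invalid IUPAC letter(s): ", paste(letters3[bad], collapse = ", "))
  }
  bases <- lapply(letters3, function(l) strsplit(iupac[[l]], "")[[1]])
  grid <- expand.grid(bases[[3]], bases[[2]], bases[[1]],
                      stringsAsFactors = FALSE)
  codons <- sort(paste0(grid[[3]], grid[[2]], grid[[1]]))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  has_stop <- any(aa == "*")
  aas <- sort(unique(aa[aa != "*"]))
  list(
    codons = codons,
    n_codons = length(codons),
    amino_acids = aas,
    n_amino_acids = length(aas),
    has_stop = has_stop,
    library_size = as.integer(n_positions) * length(aas),
    n_codon_variants = as.integer(n_positions) * length(codons)
  )
}
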