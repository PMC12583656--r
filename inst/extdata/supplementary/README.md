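# Published supplementary matrices (not redistributed)

The comparisons against the published cluster statistics need the study's
supplementary interaction matrices, which are distributed with the original
article and are not redistributable here.  To enable them, place in this
directory before installing:

- `mfi_two_orientation.tsv` — columns `protein_a`, `protein_b`,
  `orientation` (`N_A_C_B` / `N_B_C_A`), `mfi`, `n_cells`
- `mfi_symmetric.tsv` — 35x35 symmetric MFI matrix, first row/column protein
  identifiers, missing cells `NA`
- `tm_scores.tsv` — 35x35 symmetric TM-score matrix, same layout

The corresponding acceptance test (`test-acceptance.R`, "cluster statistics
on the published screening matrices") reports failure while these files are
absent.
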