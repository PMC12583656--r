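# Shared fixtures, built in code.

folate_like_cluster <- function() sprintf("P%02d", 1:5)

# Small symmetric matrix from explicit values (NA = missing).
toy_matrix <- function(values, symmetric = TRUE) {
  ppi_matrix(values, symmetric = symmetric)
}

# 6-protein matrix with distinct off-diagonal values, handy for exhaustive
# permutation-null checks.
six_protein_matrix <- function(seed = 1) {
  set.seed(seed)
  n <- 6
  v <- matrix(0, n, n)
  vals <- sample(100:2000, n * (n - 1) / 2)
  v[upper.tri(v)] <- vals
  v <- v + t(v)
  diag(v) <- sample(100:2000, n)
  ppi_matrix(v, proteins = LETTERS[1:n], symmetric = TRUE)
}

# Minimal measurement table builder.
meas_row <- function(a, b, orientation, mfi, n_cells = 20000) {
  data.frame(protein_a = a, protein_b = b, orientation = orientation,
             mfi = mfi, n_cells = n_cells, stringsAsFactors = FALSE)
}

# Tiny straight-line chain with explicit spacing and full exposure.
line_structure <- function(n = 10, spacing = 3.8, rsa = 1) {
  ca_structure(seq_len(n), cbind(seq_len(n) * spacing, 0, 0),
               rsa = rep(rsa, n))
}

# Small simulation configs used across simulator tests.
tiny_sim_config <- function(...) {
  args <- modifyList(
    list(n_types = 2, copies_per_type = 3, concentration = 1e-3,
         ligand_factor = 2, n_steps = 2000, record_every = 200,
         confine_frac = 0.1, integrator = "brownian", viscosity = 1e-4),
    list(...))
  do.call(patchy_config, args)
}

strong_energy_map <- function(n_types, mfi = 1200) {
  m <- matrix(mfi, n_types, n_types)
  ppi_energy_map(ppi_matrix(m, symmetric = TRUE))
}
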