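#' Map fluorescence to dissociation constant
#'
#' Step map from measured MFI to an effective dissociation constant for the
#' coarse-grained interaction model: MFI > 1000 -> 10 uM; 800 < MFI <= 1000 ->
#' 200 uM; 650 < MFI <= 800 -> 500 uM; MFI <= 650 -> 100 mM.
#'
#' @param mfi numeric vector of non-negative MFI values.
#' @return numeric vector of K_D values in molar.
#' @export
kd_from_mfi <- function(mfi) {
  if (any(mfi < 0, na.rm = TRUE)) stop("mfi must be >= 0")
  out <- rep(0.1, length(mfi))
  out[mfi > 650] <- 5e-4
  out[mfi > 800] <- 2e-4
  out[mfi > 1000] <- 1e-5
  out[is.na(mfi)] <- NA_real_
  out
}

#' Morse well depth from a dissociation constant
#'
#' `D_e = |ln(K_D / 1 M)|` in units of k_B T: stronger binding (smaller K_D)
#' gives a deeper attractive well.  The Morse potential already carries the
#' attractive sign, so the depth is reported as a magnitude.
#'
#' @param kd dissociation constant(s), molar, > 0.
#' @param reference reference concentration (default 1 M).
#' @return well depth(s) in k_B T.
#' @export
de_from_kd <- function(kd, reference = 1) {
  if (any(kd <= 0, na.rm = TRUE)) stop("kd must be > 0")
  abs(log(kd / reference))
}

#' Truncated-and-shifted Lennard-Jones energy
#'
#' `U(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ]`, truncated at `r_c` and (by
#' default) shifted so the energy is continuous at the cutoff.
#'
#' @param r distance(s), Angstrom, > 0.
#' @param epsilon well depth (k_B T).
#' @param sigma contact distance = sum of the two particle radii (Angstrom).
#' @param r_c cutoff (default `2.5 * sigma`).
#' @param shifted logical; subtract the cutoff energy (default TRUE).
#' @return energy in k_B T (0 beyond the cutoff).
#' @export
lj_energy <- function(r, epsilon, sigma, r_c = 2.5 * sigma, shifted = TRUE) {
  if (any(r <= 0)) stop("r must be > 0")
  s6 <- (sigma / r)^6
  u <- 4 * epsilon * (s6^2 - s6)
  if (shifted) {
    s6c <- (sigma / r_c)^6
    u <- u - 4 * epsilon * (s6c^2 - s6c)
  }
  u[r > r_c] <- 0
  u
}

#' Morse energy
#'
#' `U(r) = D_e [ exp(-2 a (r - r0)) - 2 exp(-a (r - r0)) ]`, truncated at the
#' cutoff (untruncated when `cutoff = Inf`).
#'
#' @param r distance(s), Angstrom, >= 0.
#' @param de well depth (k_B T).
#' @param alpha stiffness (1/Angstrom).
#' @param r0 equilibrium distance (Angstrom).
#' @param cutoff truncation distance (default `Inf`).
#' @return energy in k_B T.
#' @export
morse_energy <- function(r, de, alpha, r0, cutoff = Inf) {
  if (any(r < 0)) stop("r must be >= 0")
  e <- exp(-alpha * (r - r0))
  u <- de * (e^2 - 2 * e)
  u[r > cutoff] <- 0
  u
}

#' Pairwise interaction energetics from a fluorescence matrix
#'
#' Converts a symmetric MFI matrix for the simulated enzyme types into the
#' pairwise Morse well depths of the specific interaction patches, via
#' [kd_from_mfi()] and [de_from_kd()].  Missing MFI entries fall to the
#' weakest band (K_D = 100 mM).
#'
#' @param mat symmetric [ppi_matrix()] whose proteins are the enzyme types,
#'   in pathway order.
#' @return list of class `ppi_energy_map` with `types`, `kd` (molar, matrix)
#'   and `de` (k_B T, matrix, symmetric).
#' @export
ppi_energy_map <- function(mat) {
  stopifnot(inherits(mat, "ppi_matrix"))
  if (!mat$symmetric) stop("energy map needs a symmetric matrix")
  v <- mat$values
  v[mat$missing] <- 0  # unmeasured -> weakest band
  kd <- matrix(kd_from_mfi(v), nrow(v), dimnames = dimnames(v))
  de <- matrix(de_from_kd(kd), nrow(v), dimnames = dimnames(v))
  structure(list(types = mat$proteins, kd = kd, de = de),
            class = "ppi_energy_map")
}

#' Reaction scheme of the sequential pathway
#'
#' A linear cascade `S_0 -> S_1 -> ... -> S_{n-1} -> P` in which enzyme k
#' (1-based) converts state `S_{k-1}` to `S_k` (the last step producing the
#' absorbing product P).  Per-attempt reaction probabilities derive from
#' catalytic efficiencies: `log10(kcat/KM) ~ Normal(mean_log10, sd_log10)`,
#' normalised by the diffusion limit `10^8 M^-1 s^-1` to give a dimensionless
#' efficiency `eta = (kcat/KM) / 1e8`, capped at 1.  `efficiency = "equal"`
#' gives every step the same efficiency, useful for controlled desk-scale
#' runs; `p_scale` rescales all probabilities uniformly (capped at 1) and is
#' recorded in the scheme so outputs can report it.
#'
#' @param n_steps number of reactions (default 10).
#' @param efficiency `"lognormal"` (default) or `"equal"`.
#' @param mean_log10,sd_log10 parameters of the log10 efficiency distribution
#'   (defaults 5 and 1).
#' @param p_scale uniform rescale factor applied to the per-attempt
#'   probabilities (default 1).
#' @param seed integer RNG seed for the efficiency draw.
#' @return object of class `reaction_scheme` with `n_steps`, `eta`, `p_react`,
#'   `p_scale`, `seed`.
#' @export
reaction_scheme <- function(n_steps = 10,
                            efficiency = c("lognormal", "equal"),
                            mean_log10 = 5, sd_log10 = 1, p_scale = 1,
                            seed = 1L) {
  efficiency <- match.arg(efficiency)
  eta <- switch(efficiency,
    lognormal = with_seed(seed, 10^stats::rnorm(n_steps, mean_log10, sd_log10) / 1e8),
    equal = rep(10^mean_log10 / 1e8, n_steps)
  )
  eta <- pmin(eta, 1)
  p_react <- pmin(eta * p_scale, 1)
  structure(list(n_steps = as.integer(n_steps), efficiency = efficiency,
                 eta = eta, p_react = p_react, p_scale = p_scale,
                 seed = as.integer(seed)),
            class = "reaction_scheme")
}

#' Simulation configuration
#'
#' All tunable parameters of the patchy-particle reaction-diffusion model.
#' The physical defaults follow the coarse-grained model of the ten-enzyme
#' folate pathway: enzyme cores of diameter 20 A with two rigid patches (one
#' specific protein-interaction patch, one active-site patch), ligands of
#' diameter 8 A, non-specific Lennard-Jones attractions of 0.8 k_B T, Morse
#' protein-interaction patches (`alpha` 2.2 /A, `r0` 17.056 A, cutoff 20 A,
#' capture range 2.8 A beyond r0) and cognate active-site binding (depth
#' 5 k_B T, `alpha` 1 /A, `r0` 12.7 A, capture range 2.5 A).
#'
#' The box side derives from the copy number and the per-type molar
#' concentration.  Enzymes start confined in a sphere (default radius 400 A,
#' shrunk to fit the box when necessary) for the first `confine_frac` of the
#' steps; ligands (all in state S_0) fill the box.
#'
#' Patch centres sit at rigid antipodal offsets from the core centre:
#' the interaction-patch offset (default 2.697 A) places two bonded cores at
#' their mutual Lennard-Jones minimum (2^(1/6) * 20 A) when the patches sit at
#' the Morse equilibrium distance; the active-site offset (default 3.01 A)
#' does the same for a bound ligand.
#'
#' @param n_types number of enzyme types (default 10).
#' @param copies_per_type enzyme copies per type (default 300; desk-scale runs
#'   use far fewer).
#' @param concentration per-type molar concentration setting the box volume
#'   (default 50e-6 M).
#' @param ligand_factor ligand count as a multiple of the total enzyme count
#'   (default 3).
#' @param temperature kelvin (default 300).
#' @param viscosity solvent viscosity, Pa s (default 1e-3).
#' @param dt_fs integration timestep, femtoseconds (default 30).
#' @param n_steps number of timesteps (default 2e6).
#' @param confine_frac fraction of steps with the enzyme confinement sphere
#'   active (default 0.1).
#' @param confine_radius confinement sphere radius, Angstrom (default 400,
#'   capped at 45% of the box side).
#' @param integrator `"langevin"` (inertial BAOAB, supports equipartition and
#'   microcanonical checks) or `"brownian"` (overdamped, faster desk-scale
#'   alternative).
#' @param enzyme_mass,ligand_mass particle masses, atomic mass units
#'   (defaults 30000 and 300).
#' @param epsilon_pp,epsilon_pl,epsilon_nc Lennard-Jones well depths, k_B T
#'   (defaults 0.8).
#' @param ppi_alpha,ppi_r0,ppi_cutoff,ppi_capture Morse parameters of the
#'   interaction patches (defaults 2.2 /A, 17.056 A, 20 A, 2.8 A).
#' @param co_de,co_alpha,co_r0,co_capture Morse parameters of cognate
#'   active-site binding (defaults 5 k_B T, 1 /A, 12.7 A, 2.5 A).
#' @param ppi_offset,active_offset rigid patch offsets from the core centre,
#'   Angstrom.
#' @param record_every record reaction counters / frames every this many steps
#'   (default 1000).
#' @param enzyme_radius,ligand_radius core and ligand radii, Angstrom
#'   (defaults 10 and 4).
#' @param force_cap per-pair force clamp, k_B T / Angstrom (default 100):
#'   steeply repulsive walls are capped so a specific bond formed
#'   off-equilibrium relaxes smoothly; equilibrated configurations never
#'   reach the cap.
#' @return object of class `patchy_config`.
#' @export
patchy_config <- function(n_types = 10, copies_per_type = 300,
                          concentration = 50e-6, ligand_factor = 3,
                          temperature = 300, viscosity = 1e-3, dt_fs = 30,
                          n_steps = 2e6, confine_frac = 0.1,
                          confine_radius = 400,
                          integrator = c("langevin", "brownian"),
                          enzyme_mass = 30000, ligand_mass = 300,
                          epsilon_pp = 0.8, epsilon_pl = 0.8, epsilon_nc = 0.8,
                          ppi_alpha = 2.2, ppi_r0 = 17.056, ppi_cutoff = 20,
                          ppi_capture = 2.8,
                          co_de = 5, co_alpha = 1, co_r0 = 12.7,
                          co_capture = 2.5,
                          ppi_offset = 2.697, active_offset = 3.01,
                          record_every = 1000,
                          enzyme_radius = 10, ligand_radius = 4,
                          force_cap = 100) {
  integrator <- match.arg(integrator)
  if (dt_fs <= 0) stop("dt_fs must be > 0")
  if (concentration <= 0) stop("concentration must be > 0")
  n_enzymes <- n_types * copies_per_type
  box_side <- box_side_from_concentration(copies_per_type, concentration)
  cfg <- list(
    n_types = as.integer(n_types),
    copies_per_type = as.integer(copies_per_type),
    n_enzymes = as.integer(n_enzymes),
    n_ligands = as.integer(round(ligand_factor * n_enzymes)),
    concentration = concentration, box_side = box_side,
    temperature = temperature, viscosity = viscosity, dt_fs = dt_fs,
    n_steps = as.integer(n_steps), confine_frac = confine_frac,
    confine_radius = min(confine_radius, 0.45 * box_side),
    integrator = integrator,
    enzyme_mass = enzyme_mass, ligand_mass = ligand_mass,
    epsilon_pp = epsilon_pp, epsilon_pl = epsilon_pl, epsilon_nc = epsilon_nc,
    ppi_alpha = ppi_alpha, ppi_r0 = ppi_r0, ppi_cutoff = ppi_cutoff,
    ppi_capture = ppi_capture,
    co_de = co_de, co_alpha = co_alpha, co_r0 = co_r0, co_capture = co_capture,
    co_cutoff = co_r0 + co_capture,
    ppi_offset = ppi_offset, active_offset = active_offset,
    record_every = as.integer(record_every),
    enzyme_radius = enzyme_radius, ligand_radius = ligand_radius,
    force_cap = force_cap
  )
  class(cfg) <- "patchy_config"
  cfg
}

#' Box side from copy number and concentration
#'
#' Side of the cubic box (Angstrom) that holds `copies` particles of one
#' species at molar concentration `conc`: `(copies / (N_A * conc * 1e-27))^(1/3)`
#' with volume bookkeeping in cubic Angstrom (1 litre = 1e27 A^3).
#'
#' @param copies particle count of the reference species.
#' @param conc molar concentration of that species.
#' @return box side in Angstrom.
#' @export
box_side_from_concentration <- function(copies, conc) {
  avogadro <- 6.02214076e23
  (copies / (avogadro * conc * 1e-27))^(1 / 3)
}
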