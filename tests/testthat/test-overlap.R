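test_that("exposed residue selection matches elementwise comparison", {
  set.seed(2)
  rsa <- runif(30)
  st <- ca_structure(1:30, matrix(rnorm(90), 30, 3) * 10, rsa = rsa)
  expect_equal(exposed_residues(st, 0.25), which(rsa > 0.25))
  all_buried <- ca_structure(1:5, matrix(rnorm(15), 5, 3), rsa = rep(0, 5))
  expect_error(exposed_residues(all_buried), "no residue")
  all_out <- ca_structure(1:5, matrix(rnorm(15), 5, 3), rsa = rep(1, 5))
  expect_equal(exposed_residues(all_out), 1:5)
})

test_that("surface contact equals the brute-force double loop and is bounded", {
  set.seed(7)
  st <- ca_structure(1:30, matrix(rnorm(90, sd = 6), 30, 3), rsa = rep(1, 30))
  for (rep in 1:5) {
    si <- interaction_surface("X", "p1", sample(1:30, sample(3:10, 1)))
    sj <- interaction_surface("X", "p2", sample(1:30, sample(3:10, 1)))
    # oracle: explicit O(mi*mj) loop
    cnt <- 0
    for (a in si$residues) for (b in sj$residues) {
      d <- sqrt(sum((st$xyz[a, ] - st$xyz[b, ])^2))
      if (d <= 7) cnt <- cnt + 1
    }
    oracle <- cnt / (si$m * sj$m)
    got <- surface_contact(si, sj, st)
    expect_equal(got, oracle)
    expect_gte(got, 0); expect_lte(got, 1)
    # symmetry
    expect_equal(surface_contact(sj, si, st), got)
  }
})

test_that("identical compact surfaces give C = 1; distant singletons give 0", {
  st <- line_structure(10, spacing = 3)   # everything within 7 A of neighbours
  s1 <- interaction_surface("X", "a", 4:6)
  expect_equal(surface_contact(s1, s1, st), 1)
  far <- line_structure(2, spacing = 8)
  a <- interaction_surface("X", "a", 1)
  b <- interaction_surface("X", "b", 2)
  expect_equal(surface_contact(a, b, far), 0)
})

test_that("observed MISC averages pairwise contacts and is order-invariant", {
  set.seed(12)
  st <- ca_structure(1:25, matrix(rnorm(75, sd = 5), 25, 3), rsa = rep(1, 25))
  surfs <- lapply(1:4, function(i)
    interaction_surface("X", paste0("p", i), sample(1:25, 6)))
  # oracle: direct sum over the 6 unordered pairs
  tot <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    tot <- tot + surface_contact(surfs[[i]], surfs[[j]], st)
  }
  expect_equal(misc_observed(surfs, st), tot / 6)
  expect_equal(misc_observed(rev(surfs), st), misc_observed(surfs, st))
  expect_equal(misc_observed(surfs[1:2], st),
               surface_contact(surfs[[1]], surfs[[2]], st))
  expect_error(misc_observed(surfs[1], st), "at least 2")
})

test_that("random surfaces seed uniformly over the exposed set and honour the radius", {
  syn <- synth_structure(length = 40, exposed_fraction = 0.5, seed = 9)
  st <- syn$structure
  exp_res <- exposed_residues(st)
  # radius covering the whole chain -> all exposed residues
  set.seed(1)
  big <- random_surface(st, probe_radius = 1e4)
  expect_setequal(big$residues, exp_res)
  # radius below the minimal spacing -> singleton
  set.seed(2)
  tiny <- random_surface(st, probe_radius = 0.5)
  expect_equal(tiny$m, 1)
  expect_error(random_surface(st, probe_radius = 0), "positive")
  # seed residue uniformity: chi-square over many draws
  set.seed(3)
  seeds <- replicate(5000, {
    s <- random_surface(st, probe_radius = 0.5)
    s$residues
  })
  tab <- table(factor(seeds, levels = exp_res))
  chi <- stats::chisq.test(tab)
  expect_gt(chi$p.value, 0.01)
})

test_that("null MISC sample is reproducible and degenerates as expected", {
  # all exposed residues mutually within 7 A -> every sample is 1, sd 0
  st <- line_structure(5, spacing = 1.5)
  nul <- misc_null(st, n_r = 3, n_sets = 5, probe_radius = 50, seed = 1)
  expect_equal(nul$samples, rep(1, 5))
  expect_equal(nul$sd, 0)
  # fixed seed reproducibility on a nontrivial chain
  syn <- synth_structure(length = 40, seed = 5)
  n1 <- misc_null(syn$structure, n_r = 5, n_sets = 20, probe_radius = 8,
                  seed = 7)
  n2 <- misc_null(syn$structure, n_r = 5, n_sets = 20, probe_radius = 8,
                  seed = 7)
  expect_identical(n1$samples, n2$samples)
  expect_equal(length(n1$samples), 20)
  # minimal run returns exactly n_sets samples
  n3 <- misc_null(syn$structure, n_r = 2, n_sets = 2, probe_radius = 8,
                  seed = 1)
  expect_equal(length(n3$samples), 2)
})

test_that("overlap significance: planted identical surfaces are detected", {
  syn <- synth_structure(length = 50,
                         surfaces = data.frame(center = c(20, 20, 20),
                                               radius = 8),
                         seed = 4)
  ov <- overlap_significance(syn$surfaces, syn$structure, n_r = 10,
                             n_sets = 300, seed = 11)
  expect_lt(ov$p, 1e-4)
  expect_gt(ov$z, 0)
  expect_equal(ov$standard_error, ov$misc_r_sd / sqrt(300))
  expect_equal(ov$z, (ov$misc_o - ov$misc_r_mean) / ov$standard_error)
})

test_that("overlap Z is invariant to rigid rotation and translation", {
  syn <- synth_structure(length = 40,
                         surfaces = data.frame(center = c(12, 30), radius = 8),
                         seed = 6)
  st <- syn$structure
  ov1 <- overlap_significance(syn$surfaces, st, n_r = 8, n_sets = 50, seed = 3)
  # random rotation + translation
  set.seed(10)
  ang <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  xyz2 <- st$xyz %*% (Rx %*% Rz) +
    matrix(c(12, -40, 7), nrow(st$xyz), 3, byrow = TRUE)
  st2 <- ca_structure(st$resno, xyz2, rsa = st$rsa)
  ov2 <- overlap_significance(syn$surfaces, st2, n_r = 8, n_sets = 50, seed = 3)
  expect_equal(ov2$z, ov1$z, tolerance = 1e-10)
})

test_that("Z increases monotonically with the planted shared fraction", {
  zs <- vapply(c(0, 0.25, 0.5, 1.0), function(f) {
    syn <- synth_structure(
      length = 60,
      surfaces = data.frame(center = c(15, 45, 30), radius = 9),
      shared_fraction = f, seed = 101)
    overlap_significance(syn$surfaces, syn$structure, n_r = 10, n_sets = 100,
                         seed = 13)$z
  }, numeric(1))
  expect_equal(cor(zs, c(0, 0.25, 0.5, 1.0), method = "spearman"), 1)
})

test_that("null calibration: random 'observed' surfaces are rarely significant", {
  # the empirical tail probability is the calibrated quantity; the
  # normal-theory z inherits the sigma/sqrt(n) convention and is
  # anticonservative by construction for a single observed draw
  syn <- synth_structure(length = 40, exposed_fraction = 0.7, seed = 55)
  st <- syn$structure
  rej <- vapply(1:100, function(i) {
    set.seed(400 + i)
    obs <- replicate(8, random_surface(st, probe_radius = 8),
                     simplify = FALSE)
    ov <- overlap_significance(obs, st, n_r = 8, n_sets = 60,
                               probe_radius = 8, seed = 800 + i)
    ov$p_empirical <= 0.05
  }, logical(1))
  expect_gte(mean(!rej), 0.90)
})

test_that("interface extraction matches a brute-force loop and handles gaps", {
  d <- synth_dimer(gap = 5, seed = 2)
  iface <- extract_interface(d$chain_a, d$chain_b, cutoff = 7)
  # oracle: brute-force double loop
  res_a <- c(); res_b <- c()
  for (i in seq_along(d$chain_a$resno)) {
    for (j in seq_along(d$chain_b$resno)) {
      dd <- sqrt(sum((d$chain_a$xyz[i, ] - d$chain_b$xyz[j, ])^2))
      if (dd <= 7) {
        res_a <- c(res_a, d$chain_a$resno[i])
        res_b <- c(res_b, d$chain_b$resno[j])
      }
    }
  }
  expect_setequal(iface$residues_a, unique(res_a))
  expect_setequal(iface$residues_b, unique(res_b))
  expect_gt(length(iface$residues_a), 0)
  # far-apart chains -> empty surfaces with a warning
  d20 <- synth_dimer(gap = 20, seed = 2)
  expect_warning(i20 <- extract_interface(d20$chain_a, d20$chain_b, cutoff = 7),
                 "no inter-chain contact")
  expect_length(i20$residues_a, 0)
  expect_length(i20$residues_b, 0)
})

test_that("a symmetric dimer yields mirror-identical interface residue sets", {
  d <- synth_dimer(gap = 5, mirror = TRUE, seed = 8)
  iface <- extract_interface(d$chain_a, d$chain_b, cutoff = 7)
  expect_setequal(iface$residues_a, iface$residues_b)
})

test_that("interface surfaces of a contacting dimer touch under surface_contact", {
  d <- synth_dimer(gap = 4, seed = 12)
  iface <- extract_interface(d$chain_a, d$chain_b, cutoff = 7)
  # evaluate both interface surfaces on a merged structure
  n_a <- length(d$chain_a$resno)
  merged <- ca_structure(
    c(d$chain_a$resno, d$chain_b$resno + 1000),
    rbind(d$chain_a$xyz, d$chain_b$xyz),
    rsa = c(d$chain_a$rsa, d$chain_b$rsa))
  sa <- interaction_surface("AB", "a", iface$residues_a)
  sb <- interaction_surface("AB", "b", iface$residues_b + 1000)
  expect_gt(surface_contact(sa, sb, merged), 0)
})

test_that("residue frequencies count surface membership", {
  surfs <- list(
    interaction_surface("X", "p1", c(1, 2, 3)),
    interaction_surface("X", "p2", c(2, 3, 4)),
    interaction_surface("X", "p3", c(3, 9))
  )
  fr <- residue_frequency(surfs)
  expect_equal(unname(fr[as.character(3)]), 1.0)
  expect_equal(unname(fr[as.character(1)]), 1 / 3)
  st <- line_structure(10)
  fr2 <- residue_frequency(surfs, st)
  expect_equal(unname(fr2[as.character(10)]), 0)
  # counting oracle on random surfaces
  set.seed(5)
  rs <- lapply(1:6, function(i) interaction_surface("X", i, sample(1:20, 5)))
  fr3 <- residue_frequency(rs)
  for (r in names(fr3)) {
    cnt <- sum(vapply(rs, function(s) as.integer(r) %in% s$residues,
                      logical(1)))
    expect_equal(unname(fr3[r]), cnt / 6)
  }
  expect_error(residue_frequency(list()), "at least one")
})

test_that("surface TSV round trip preserves residue sets", {
  surfs <- list(interaction_surface("FolA", "FolK", c(3, 7, 9)),
                interaction_surface("FolA", "MetF", c(7, 9, 21)))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_surfaces(surfs, path)
  back <- read_surfaces(path)
  expect_equal(back[[1]]$residues, surfs[[1]]$residues)
  expect_equal(back[[2]]$partner, "MetF")
})
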