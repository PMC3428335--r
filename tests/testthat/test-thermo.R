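test_that("isotherm inversion matches independent numeric root finding", {
  p <- core_params()
  mnda <- p[p$gene_id == "MNDA", ]
  c_impl <- intensity_to_concentration(1000, mnda)
  # independent oracle: invert the forward isotherm by root finding
  c_root <- uniroot(
    function(cc) concentration_to_intensity(cc, mnda) - 1000,
    interval = c(1e-9, 1e9), tol = 1e-12
  )$root
  expect_lt(abs(c_impl - c_root) / c_root, 1e-9)
})

test_that("isotherm limits and monotonicity hold", {
  p <- core_params()
  mnda <- p[1, ]
  expect_lt(intensity_to_concentration(1e-8, mnda), 1e-8)
  expect_equal(concentration_to_intensity(0, mnda), 0)
  # saturation limit
  expect_lt(abs(concentration_to_intensity(1e12, mnda) - mnda$saturation), 1e-2)
  ii <- seq(1, mnda$saturation - 1, length.out = 50)
  expect_true(all(diff(intensity_to_concentration(ii, mnda)) > 0))
  cc <- seq(0, 5000, length.out = 50)
  expect_true(all(diff(concentration_to_intensity(cc, mnda)) > 0))
})

test_that("intensity and concentration maps are mutual inverses", {
  p <- core_params()
  set.seed(11)
  for (i in seq_len(nrow(p))) {
    pi <- p[i, ]
    ii <- runif(250, 1e-3, pi$saturation * (1 - 1e-6))
    back <- concentration_to_intensity(intensity_to_concentration(ii, pi), pi)
    expect_lt(max(abs(back - ii) / ii), 1e-9)
    cc <- runif(250, 0.01, 1e5)
    back_c <- intensity_to_concentration(concentration_to_intensity(cc, pi), pi)
    expect_lt(max(abs(back_c - cc) / cc), 1e-9)
  }
})

test_that("isotherm domain errors are raised", {
  p <- core_params()[1, ]
  expect_error(intensity_to_concentration(-1, p), "intensity")
  expect_error(intensity_to_concentration(0, p), "intensity")
  expect_error(intensity_to_concentration(p$saturation, p), "saturation")
  expect_error(concentration_to_intensity(-0.1, p), "concentration")
})

test_that("chemical potential is zero at saturation and changes sign exactly once", {
  p <- core_params()
  for (i in seq_len(nrow(p))) {
    pi <- p[i, ]
    expect_lt(abs(chemical_potential(pi$saturation, pi)), 1e-9)
    # bisection-style scan over the admissible domain: exactly one crossing
    ii <- seq(pi$saturation * 1e-6, pi$saturation * 2, length.out = 4001)
    mu <- chemical_potential(ii, pi)
    expect_equal(sum(diff(sign(mu)) != 0), 1L)
    expect_true(all(mu[ii < pi$saturation * 0.999] > 0))
    expect_true(all(mu[ii > pi$saturation * 1.001] < 0))
  }
})

test_that("chemical potential at half saturation matches independent evaluation", {
  p <- core_params()
  mef2c <- p[p$gene_id == "MEF2C", ]
  mu <- chemical_potential(mef2c$saturation / 2, mef2c)
  expect_gt(mu, 0)
  # independent stepwise evaluation of the closed form
  occupancy <- (mef2c$saturation / 2) / mef2c$saturation
  expect_equal(mu, mef2c$delta_g_hyb * (1 - occupancy), tolerance = 1e-12)
  expect_equal(mu, 472.81 / 2, tolerance = 1e-9)
})

test_that("affinity decouples under diagonal coupling", {
  p <- core_params()
  solo <- transcriptional_affinity(c(MNDA = 1000), p)
  multi <- transcriptional_affinity(
    c(MNDA = 1000, MEF2C = 2000, SMAD3 = 1500), p,
    coupling = diag(3)
  )
  expect_equal(unname(solo["MNDA"]), unname(multi["MNDA"]), tolerance = 1e-12)
  # finite and continuous over the admissible intensity range
  grid <- seq(1, p$saturation[1] * (1 - 1e-4), length.out = 200)
  vals <- vapply(grid, function(i) transcriptional_affinity(c(MNDA = i), p), numeric(1))
  expect_true(all(is.finite(vals)))
})

test_that("off-diagonal coupling matches the hand-expanded two-gene form", {
  p <- core_params()
  lam <- matrix(c(1, 0.3, 0, 1), 2, 2, byrow = TRUE)
  ii <- c(MNDA = 900, SMAD3 = 2100)
  a <- transcriptional_affinity(ii, p, coupling = lam)
  # independent expansion: A_1 = mu_1 c1' + 0.3 mu_2 c2'; A_2 = mu_2 c2'
  k1 <- 433.97 / (0.0019872 * 310.15)
  k2 <- 465.08 / (0.0019872 * 310.15)
  mu1 <- 433.97 * (1 - 900 / 3105)
  mu2 <- 465.08 * (1 - 2100 / 4497)
  d1 <- k1 * 3105 / (3105 - 900)^2
  d2 <- k2 * 4497 / (4497 - 2100)^2
  expect_equal(unname(a["MNDA"]), mu1 * d1 + 0.3 * mu2 * d2, tolerance = 1e-10)
  expect_equal(unname(a["SMAD3"]), mu2 * d2, tolerance = 1e-10)
})

test_that("affinity input validation catches misalignment", {
  p <- core_params()
  expect_error(transcriptional_affinity(c(1000, 2000), p), "named")
  expect_error(
    transcriptional_affinity(c(MNDA = 1000, NOPE = 5), p),
    "no hybridization parameters"
  )
  expect_error(
    transcriptional_affinity(c(MNDA = 1000, SMAD3 = 10), p, coupling = diag(3)),
    "matrix"
  )
})

test_that("thermo_profile has correct shapes, summaries and exclusions", {
  sim <- simulate_expression(synthetic_config(
    n_targets_per_tf = 2, n_background = 3,
    n_tumor = 8, n_control = 8, seed = 2
  ))
  prof <- thermo_profile(sim$matrix, core_params())
  expect_s3_class(prof, "thermo_profile")
  expect_equal(dim(prof$concentration), c(4, 16))
  expect_equal(dim(prof$chemical_potential), c(4, 16))
  expect_setequal(attr(prof, "excluded"), setdiff(sim$matrix$gene_ids, core_params()$gene_id))
  # constant gene has zero variance in every derived quantity
  lx <- matrix(5, 2, 6, dimnames = list(c("MNDA", "SMAD3"), sprintf("s%d", 1:6)))
  prof2 <- thermo_profile(expression_matrix(2^lx), core_params())
  expect_equal(prof2$summary$var_concentration, c(0, 0))
  expect_equal(prof2$summary$var_affinity, c(0, 0))
  expect_equal(prof2$summary$var_mu, c(0, 0))
})

test_that("thermo_profile recovers generator concentrations exactly without noise", {
  sim <- simulate_expression(synthetic_config(
    noise_sd = 0, n_background = 10,
    n_tumor = 10, n_control = 10, seed = 3
  ))
  prof <- thermo_profile(sim$matrix, sim$params)
  truth <- sim$truth$per_gene_concentration[
    rownames(prof$concentration), colnames(prof$concentration)
  ]
  expect_lt(max(abs(prof$concentration - truth) / pmax(truth, 1e-12)), 1e-9)
})

test_that("thermo quantities are invariant under sample reordering", {
  sim <- simulate_expression(synthetic_config(
    n_targets_per_tf = 0, n_background = 0,
    n_tumor = 6, n_control = 6, seed = 4
  ))
  prof <- thermo_profile(sim$matrix, core_params())
  perm <- rev(sim$matrix$sample_ids)
  prof_p <- thermo_profile(sim$matrix[, perm], core_params())
  expect_equal(
    prof$concentration[, perm], prof_p$concentration,
    tolerance = 1e-12
  )
  expect_equal(prof$summary, prof_p$summary, tolerance = 1e-12)
})

test_that("intensities at saturation are clamped with a warning", {
  lx <- matrix(log2(c(3200, 1000, 900, 800)), 2, 2,
    dimnames = list(c("MNDA", "SMAD3"), c("a", "b"))
  )
  expect_warning(prof <- thermo_profile(expression_matrix(2^lx), core_params()), "clamped")
  expect_true(all(prof$intensity["MNDA", ] < 3105))
})

test_that("chemical-potential ranking is ascending with lexicographic ties", {
  lx <- matrix(log2(c(1000, 1000, 2000, 2000)), 2, 2,
    byrow = TRUE, dimnames = list(c("MNDA", "SMAD3"), c("a", "b"))
  )
  prof <- thermo_profile(expression_matrix(2^lx), core_params())
  rk <- rank_by_chemical_potential(prof)
  expect_equal(rk$gene_id[1], "SMAD3") # higher occupancy at same DG-ish scale
  expect_true(all(diff(rk$mean_mu) >= 0))
  # exact ties fall back to lexicographic gene order
  two <- hyb_params(c("b_gene", "a_gene"), delta_g_hyb = 400, saturation = 4000)
  lx2 <- matrix(log2(1000), 2, 2, dimnames = list(c("b_gene", "a_gene"), c("x", "y")))
  rk2 <- rank_by_chemical_potential(thermo_profile(expression_matrix(2^lx2), two))
  expect_equal(rk2$gene_id, c("a_gene", "b_gene"))
})

test_that("regulators at high occupancy attain the lowest chemical potentials", {
  sim <- simulate_expression(synthetic_config(seed = 5))
  rk <- rank_by_chemical_potential(thermo_profile(sim$matrix, sim$params))
  expect_equal(sort(rk$gene_id[1:4]), sort(core_params()$gene_id))
})

test_that("parameter table round-trips through the packaged fixture format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hyb_params(core_params(), path)
  back <- read_hyb_params(path)
  expect_equal(as.data.frame(back), as.data.frame(core_params()), tolerance = 1e-12)
  shipped <- read_hyb_params(
    system.file("extdata", "hybridization_params.tsv", package = "thermoreg")
  )
  expect_equal(shipped$delta_g_hyb, c(433.97, 473.5, 472.81, 465.08))
  expect_equal(shipped$saturation, c(3105, 4684, 5110, 4497))
})
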