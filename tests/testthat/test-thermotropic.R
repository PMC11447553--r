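test_that("nematic order reaches 1 for aligned chains and ~0 for isotropic", {
  U <- matrix(rep(c(0, 0, 1), 100), ncol = 3, byrow = TRUE)
  expect_equal(nematic_s2(U), 1, tolerance = 1e-12)
  set.seed(1)
  V <- matrix(rnorm(3e4), ncol = 3)
  V <- V / sqrt(rowSums(V^2))
  expect_lt(nematic_s2(V), 0.05)
})

test_that("two orthogonal chains match a direct nematic-tensor oracle", {
  # independent oracle: average Q of u = z and u = x, largest eigenvalue
  Qz <- (3 * tcrossprod(c(0, 0, 1)) - diag(3)) / 2
  Qx <- (3 * tcrossprod(c(1, 0, 0)) - diag(3)) / 2
  oracle <- max(eigen((Qz + Qx) / 2, symmetric = TRUE)$values)
  expect_equal(oracle, 0.25)
  U <- rbind(c(0, 0, 1), c(1, 0, 0))
  expect_equal(nematic_s2(U), oracle, tolerance = 1e-12)
})

test_that("S2 is invariant to rotation about z and to chain relabeling", {
  set.seed(2)
  U <- sclamellar:::sample_vmf_z(500, 20)
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(nematic_s2(U %*% t(R)), nematic_s2(U), tolerance = 1e-10)
  expect_equal(nematic_s2(U[sample(nrow(U)), ]), nematic_s2(U),
               tolerance = 1e-12)
})

test_that("per-class S2 tracks the generator's orientation concentration", {
  spec <- synthetic_spec(n_lipids = 150, water_per_lipid = 5,
                         resolution = "atomistic", orientation_kappa = 30,
                         seed = 4)
  sys <- make_multilayer(spec)
  lf <- assign_leaflets(sys$frames[[1]], sys$topology)
  s2 <- s2_by_class(sys$frames[[1]], sys$topology, lf)
  expect_true(all(abs(s2 - kappa_to_s2(30)) < 0.08))
  # short chains fall back to the full chain with a warning
  cg <- make_multilayer(synthetic_spec(n_lipids = 60, water_per_lipid = 2,
                                       seed = 5))
  lfc <- assign_leaflets(cg$frames[[1]], cg$topology)
  expect_warning(s2_by_class(cg$frames[[1]], cg$topology, lfc),
                 "shorter than the requested section")
})

test_that("S_CH limits and magic angle follow the order-parameter formula", {
  mkh <- function(hz) data.frame(lipid_id = 1, chain_role = "fatty",
                                 tail_type = "FFA", carbon_index = 2, h = 1,
                                 hx = sqrt(1 - hz^2), hy = 0, hz = hz,
                                 px = 0, py = 0, pz = 0)
  expect_equal(sch_profile(mkh(1))$s_ch, 1)
  expect_equal(sch_profile(mkh(0))$s_ch, -0.5)
  expect_equal(sch_profile(mkh(sqrt(1 / 3)))$s_ch, 0, tolerance = 1e-12)
  expect_error(sch_profile(mkh(NaN)), "missing H")
})

test_that("S_CH of constructed all-trans chains is perpendicular-limit", {
  up <- straight_chain_system(n_chains = 8, axis = c(0, 0, 1))
  prof <- sch_profile(attach_pseudo_hydrogens(up$frame, up$topology))
  expect_true(all(abs(prof$s_ch + 0.5) < 1e-9))
  # bounds are never violated on disordered generator chains
  sys <- make_multilayer(synthetic_spec(n_lipids = 40, water_per_lipid = 2,
                                        resolution = "atomistic",
                                        orientation_kappa = 2, seed = 6))
  p <- sch_profile(attach_pseudo_hydrogens(sys$frames[[1]], sys$topology))
  expect_true(all(p$s_ch >= -0.5 - 1e-9 & p$s_ch <= 1 + 1e-9))
})

test_that("normalized lipid area applies the 1.9 CHOL weight", {
  tails <- rep(c("CER_acyl", "FFA", "CHOL"), c(10, 10, 10))
  res <- normalized_lipid_area(tails, lx = 6, ly = 5)
  expect_equal(res$nla, (10 + 10 + 1.9 * 10) / 30)
  expect_equal(res$area_per_tail, 1 / res$nla)
  noch <- normalized_lipid_area(rep("FFA", 12), 4, 3)
  expect_equal(noch$nla, 1)
  # intensive under duplication
  dbl <- normalized_lipid_area(rep(tails, 2), lx = 12, ly = 5)
  expect_equal(dbl$nla, res$nla)
})

test_that("membrane thickness interpolates half-bulk water interfaces", {
  z <- seq(0.05, 22, by = 0.1)
  d <- ifelse(z < 2 | z > 20, 1, 0)
  expect_equal(membrane_thickness(data.frame(z = z, density = d)), 18,
               tolerance = 1e-9)
  # linear ramps: half-height midpoints recovered exactly
  ramp <- pmin(1, pmax(0, (2.5 - z) / 1)) + pmin(1, pmax(0, (z - 19.5) / 1))
  expect_equal(membrane_thickness(data.frame(z = z, density = ramp)), 18,
               tolerance = 1e-9)
  # one-sided water is an error
  d1 <- ifelse(z < 2, 1, 0)
  expect_error(membrane_thickness(data.frame(z = z, density = d1)))
  # generated stack: thickness within one bin of the construction span
  sys <- make_multilayer(synthetic_spec(n_lipids = 200, water_per_lipid = 15,
                                        resolution = "atomistic", seed = 3))
  th <- membrane_thickness(water_density_profile(sys$frames[[1]],
                                                 sys$topology))
  expect_equal(th, ground_truth(sys)$membrane_span, tolerance = 0.1 / 17.8)
})

test_that("block averaging uses half-open 5-degree blocks", {
  df <- data.frame(T = c(31, 33, 36), m = c(1, 3, 5))
  b <- block_average(df)
  expect_equal(b$block_T, c(32.5, 37.5))
  expect_equal(b$n_frames, c(2L, 1L))
  expect_equal(b$m, c(2, 5))
  const <- block_average(data.frame(T = seq(30, 60, 2), m = 7))
  expect_true(all(const$m == 7))
  lin <- block_average(data.frame(T = seq(30, 59.9, 0.5), m = seq(30, 59.9, 0.5)))
  expect_equal(lin$m, lin$block_T, tolerance = 0.01)
})

test_that("two-regime fit recovers breakpoints and flags degenerate inputs", {
  x <- seq(32.5, 97.5, by = 5)
  hinge <- function(t) ifelse(t < 65, 0.91 - 4e-4 * (t - 30),
                              0.896 - 1.2e-2 * (t - 65))
  fit0 <- two_regime_fit(x, hinge(x))
  expect_equal(fit0$breakpoint, 65)
  expect_equal(unname(fit0$slopes["below"]), -4e-4, tolerance = 1e-6)
  expect_equal(unname(fit0$slopes["above"]), -1.2e-2, tolerance = 1e-6)
  # 1% noise: breakpoint within half a block
  set.seed(9)
  hits <- vapply(1:10, function(i) {
    y <- hinge(x) + rnorm(length(x), 0, 0.009)
    two_regime_fit(x, y)$breakpoint
  }, numeric(1))
  expect_true(all(abs(hits - 65) <= 2.5 + 1e-9))
  # pure line: no transition flag
  lin <- two_regime_fit(x, 2 + 0.01 * x)
  expect_true(lin$no_transition)
  expect_error(two_regime_fit(x[1:5], hinge(x[1:5])), "at least 6 blocks")
})

test_that("a synthetic sweep recovers its transition in the S2 series", {
  spec <- synthetic_spec(n_lipids = 120, water_per_lipid = 12,
                         resolution = "atomistic", seed = 5)
  sw <- make_temperature_sweep(spec, seq(32.5, 97.5, by = 5))
  ser <- thermo_series(sw)
  expect_true(all(diff(ser$block_T) == 5))
  # averaging the three chain classes beats per-class estimator noise
  s2_mean <- rowMeans(ser[, c("S2_FFA", "S2_acyl", "S2_sph")])
  fit <- two_regime_fit(ser$block_T, s2_mean)
  expect_false(fit$no_transition)
  expect_lte(abs(fit$breakpoint - 65), 2.5)
  # ordered phase below the transition, fluid above it
  expect_gt(mean(s2_mean[ser$block_T < 65]), 0.8)
  expect_lt(min(s2_mean[ser$block_T > 80]), 0.8)
  # thickness stays near the construction span throughout
  expect_true(all(abs(ser$thickness - 17.8) < 0.3))
})
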