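test_that("compiled engine reproduces the pure-R reference loop", {
  p <- bone_params()
  site <- init_site(0.6, p)
  n <- 250
  tt <- seq(-4, by = 1 / 365, length.out = n)
  kfbio <- kappa(tt, kappa_params(1.3, 2e-4, t1 = -3.9))
  kfbb <- kappa(tt, kappa_params(0.9, -5e-5, t1 = -3.9))
  loadf <- ifelse(tt >= -3.8, 1.2, 1)
  a <- osteosim:::.run_site_cpp(site, p, kfbio, kfbb, loadf)
  b <- osteosim:::.run_site_r(site, p, kfbio, kfbb, loadf)
  expect_lt(max(abs(a - b) / (abs(b) + 1e-12)), 1e-9)
})

test_that("identical configurations give bit-identical results", {
  s1 <- simulate_remodeling(menopause_schedule("combined"),
                            ensemble = tiny_ensemble(), t_end = 0)
  s2 <- simulate_remodeling(menopause_schedule("combined"),
                            ensemble = tiny_ensemble(), t_end = 0)
  expect_identical(s1$femur, s2$femur)
  expect_identical(s1$sites, s2$sites)
})

test_that("sites hold equilibrium under premenopausal conditions", {
  for (vb in c(0.9, 0.5, 0.25)) {
    site <- equilibrate_site(vb, n_days = 365)
    expect_lt(attr(site, "drift"), 1e-7)
    expect_lt(attr(site, "stimulus_error"), bone_params()$w)
  }
})

test_that("a site displaced above equilibrium relaxes back toward it", {
  p <- bone_params()
  site <- init_site(0.5, p, v_b_start = 0.55)
  n <- 6 * 365
  ones <- rep(1, n)
  s <- osteosim:::.run_site_cpp(site, p, ones, ones, ones)
  vb <- s[, "v_b"]
  # resorbs back toward the solved equilibrium ...
  expect_lt(vb[n], vb[1] - 0.003)
  expect_lt(abs(vb[n] - 0.5), abs(vb[1] - 0.5))
  # ... one-directionally after the delay windows fill ...
  expect_true(all(diff(vb[150:n]) < 1e-6))
  # ... until the stimulus error re-enters the dead zone, where remodeling
  # re-balances (the mechanostat equilibrium is a band, not a point)
  x_end <- s[n, "zeta"] - s[n, "zeta_ref"]
  expect_gt(x_end, -(p$w + p$v))
  expect_lt(abs(s[n, "v_f_dot"] - s[n, "v_r_dot"]),
            0.2 * s[n, "v_r_dot"])
})

test_that("a depressed focal balance produces sustained bone loss", {
  p <- bone_params()
  site <- init_site(0.6, p)
  n <- 400
  kfbb <- rep(0.9, n)
  ones <- rep(1, n)
  s <- osteosim:::.run_site_cpp(site, p, ones, kfbb, ones)
  vb <- s[, "v_b"]
  # strictly decreasing once the full remodeling cycle reflects the deficit
  warm <- p$T_R + p$T_I + p$T_F
  expect_true(all(diff(vb[warm:n]) < 0))
  expect_lt(vb[n], vb[1])
})

test_that("an overload step raises the stimulus and feeds back on formation", {
  p <- bone_params()
  site <- init_site(0.6, p)
  n <- 3 * 365
  ones <- rep(1, n)
  loadf <- c(rep(1, 100), rep(1.3, n - 100))
  s <- osteosim:::.run_site_cpp(site, p, ones, ones, loadf)
  x <- s[, "zeta"] - s[, "zeta_ref"]
  expect_lt(max(abs(x[1:100])), p$w)        # dead zone before the step
  expect_gt(max(x[101:n]), p$w)             # stimulus error escapes it
  expect_gt(s[n, "v_b"], s[100, "v_b"])     # net formation follows
  # adaptation shrinks the error again as bone is added
  expect_lt(x[n], max(x[101:n]))
})

test_that("femur averaging is a weighted mean with aligned series", {
  expect_equal(femur_average(list(c(1, 2, 3)), 2), c(1, 2, 3))
  expect_equal(femur_average(list(c(1, 1), c(3, 3)), c(1, 1)), c(2, 2))
  expect_equal(femur_average(list(1, 4), c(2, 1)), 2)
  expect_error(femur_average(list(c(1, 2), c(1, 2, 3)), c(1, 1)))
})

test_that("turnover rises with free surface in depleting cortical bone", {
  # under the combined schedule a cortical site gains free surface as its
  # porosity grows (positive feedback: loss begets remodeling begets loss),
  # while a trabecular site sits past the peak of the surface curve and its
  # activity shrinks as it rarefies
  sim <- simulate_remodeling(menopause_schedule("combined"),
                             ensemble = bone_ensemble(v_b = c(0.95, 0.2),
                                                      weight = c(0.5, 0.5)))
  cort <- sim$sites[[1]]
  trab <- sim$sites[[2]]
  n <- nrow(cort)
  sv_cort <- specific_surface(1 - cort[, "v_b"])
  sv_trab <- specific_surface(1 - trab[, "v_b"])
  expect_gt(sv_cort[n], sv_cort[1])
  expect_lt(sv_trab[n], sv_trab[1])
  # the feedback makes cortical loss accelerate: the second half of the run
  # loses more bone than the first
  half <- floor(n / 2)
  expect_gt(cort[half, "v_b"] - cort[n, "v_b"],
            cort[1, "v_b"] - cort[half, "v_b"])
})

test_that("simulation object exposes tidy views and summaries", {
  sim <- simulate_remodeling(menopause_schedule("combined"),
                             ensemble = tiny_ensemble(), t_end = 0)
  expect_s3_class(sim, "bone_sim")
  expect_equal(sim$femur$bmd_rel[1], 1)
  expect_equal(sim$femur$porosity, 1 - sim$femur$v_b)
  expect_equal(nrow(sim$femur), length(sim$time))
  df <- as.data.frame(sim)
  expect_setequal(unique(df$site), sim$ensemble$label)
  expect_true(all(c("t_years", "site", "variable", "value") %in% names(df)))
  sm <- summary(sim, at = c(-4, 0))
  expect_equal(nrow(sm), 2)
  expect_output(print(sim), "combined")
})

test_that("configuration round-trips through JSON", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  params <- bone_params(f_bio = 4.2e-3, lifo_fraction = 0.65)
  sch <- menopause_schedule("fbb_only")
  write_config(path, params = params, schedule = sch,
               loads = load_schedule(1.3, 2),
               ensemble = tiny_ensemble(), t_start = -4, t_end = 10)
  cfg <- read_config(path)
  expect_equal(cfg$params$f_bio, 4.2e-3)
  expect_equal(cfg$params$lifo_fraction, 0.65)
  expect_equal(cfg$schedule$fbb$kappa_perm, 0.793)
  expect_equal(cfg$loads$factor, 1.3)
  expect_equal(cfg$ensemble$v_b, tiny_ensemble()$v_b)
  expect_equal(cfg$t_end, 10)
})
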