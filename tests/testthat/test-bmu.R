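test_that("activation frequency is inhibited by the stimulus", {
  expect_equal(activation_frequency(0, 1e-3, 5e-3), 5e-3)
  expect_equal(activation_frequency(2e-3, 2e-3, 5e-3), 2.5e-3)
  expect_lt(activation_frequency(1, 1e-3, 5e-3), 1e-5)
  z <- seq(0, 0.02, length.out = 11)
  expect_true(all(diff(activation_frequency(z, 8e-3, 5e-3)) < 0))
  expect_error(activation_frequency(1e-3, 0, 5e-3), "zeta_ref")
})

test_that("origination rate is activation times free surface", {
  expect_equal(origination_rate(5e-3, 4), 0.02)
  expect_equal(origination_rate(5e-3, 0), 0)
  expect_equal(origination_rate(0, 4), 0)
})

test_that("focal balance curve is continuous, monotone and kappa-scaled", {
  p <- bone_params()
  w <- p$w; v <- p$v
  expect_equal(focal_balance(0), 1)
  expect_equal(focal_balance(1), 1.15)
  expect_equal(focal_balance(-1), 0.85)
  expect_equal(focal_balance(0, kappa_fbb = 0.903), 0.903)
  expect_equal(focal_balance(1, kappa_fbb = 0.903), 0.903 * 1.15)
  # midpoints of the linear zones
  expect_equal(focal_balance(w + v / 2), (1 + 1.15) / 2)
  expect_equal(focal_balance(-(w + v / 2)), (1 + 0.85) / 2)
  # continuity at all four breakpoints
  for (x0 in c(-(w + v), -w, w, w + v)) {
    expect_equal(focal_balance(x0 - 1e-12), focal_balance(x0 + 1e-12),
                 tolerance = 1e-6)
  }
  x <- seq(-5e-3, 5e-3, length.out = 101)
  expect_true(all(diff(focal_balance(x)) >= 0))
  expect_equal(focal_balance(x, 0.7), 0.7 * focal_balance(x))
})

test_that("windowed rates reduce to closed forms for constant histories", {
  p <- bone_params()
  h0 <- bmu_history(p, n_bmu_eq = 0)
  expect_equal(formation_rate(h0, p), 0)
  expect_equal(resorption_rate(h0, p), 0)

  cc <- 0.012
  h1 <- bmu_history(p, n_bmu_eq = cc)
  expect_equal(formation_rate(h1, p), p$a_bmu * p$v_bmu * cc)
  expect_equal(resorption_rate(h1, p), p$a_bmu * p$v_bmu * cc)
  expect_equal(net_rate(formation_rate(h1, p), resorption_rate(h1, p)), 0)

  h2 <- bmu_history(p, n_bmu_eq = cc, f_bb_eq = 0.9)
  expect_equal(formation_rate(h2, p), 0.9 * p$a_bmu * p$v_bmu * cc)

  # a single pulse older than the resorption window does not resorb
  h3 <- bmu_history(p, n_bmu_eq = 0)
  h3 <- push_history(h3, 1, 1)
  for (i in seq_len(p$T_R)) h3 <- push_history(h3, 0, 1)
  expect_equal(resorption_rate(h3, p), 0)
  # ... but reaches the formation window T_R + T_I days after origination
  for (i in seq_len(p$T_I)) h3 <- push_history(h3, 0, 1)
  expect_gt(formation_rate(h3, p), 0)

  expect_error(formation_rate(structure(list(n_bmu = rep(1, 10), f_bb = rep(1, 10),
                                             T_R = 24, T_I = 18, T_F = 64),
                                        class = "bmu_history"), p),
               "warm-up")
})

test_that("incremental window sums track naive re-summation over random steps", {
  p <- bone_params()
  set.seed(11)
  h <- bmu_history(p, n_bmu_eq = 0.01)
  len <- p$T_R + p$T_I + p$T_F
  for (step in 1:500) {
    h <- push_history(h, runif(1, 0, 0.05), runif(1, 0.5, 1.2))
    naive_r <- 0
    for (i in (len - p$T_R + 1):len) naive_r <- naive_r + h$n_bmu[i]
    naive_f <- 0
    for (i in 1:p$T_F) naive_f <- naive_f + h$n_bmu[i] * h$f_bb[i]
    if (abs(h$sum_r - naive_r) > 1e-10 || abs(h$sum_f - naive_f) > 1e-10) {
      fail(sprintf("window sums diverged at step %d", step))
    }
    # the rate operations agree with the running sums
    expect_equal(resorption_rate(h, p), p$a_bmu * p$v_bmu / p$T_R * naive_r)
    expect_equal(formation_rate(h, p), p$a_bmu * p$v_bmu / p$T_F * naive_f)
  }
  succeed()
})

test_that("mineralization law has the documented asymptotics", {
  p <- bone_params()
  expect_equal(layer_mineral(0, p), p$alpha_0)
  expect_equal(layer_mineral(1e9, p), p$alpha_max)
  expect_equal(layer_mineral(p$tau_sec, p),
               p$alpha_max - (p$alpha_max - p$alpha_0) / exp(1))
  expect_true(all(diff(layer_mineral(seq(0, 9000, by = 300), p)) > 0))
})

test_that("pure youngest-first turnover consumes layers from the surface", {
  p <- bone_params(lifo_fraction = 1)  # pure LIFO for transparent bookkeeping
  st <- layer_stack(thickness = c(0.01, 0.02, 0.5), age = c(10, 50, 4000))
  # conservation when rates balance
  st1 <- apply_turnover(st, 1e-3, 1e-3, dt = 1, params = p)
  expect_equal(sum(st1$thickness), 0.53)
  # pure aging
  st2 <- apply_turnover(st, 0, 0, dt = 1, params = p)
  expect_equal(st2$thickness, st$thickness)
  expect_equal(st2$age, st$age + 1)
  # resorption eats the two young layers and bites the core
  st3 <- apply_turnover(st, 0, 0.04, dt = 1, params = p)
  expect_equal(length(st3$thickness), 1)
  expect_equal(st3$thickness, 0.53 - 0.04)
  expect_equal(st3$age, 4001)
  # formation goes on top at age zero
  st4 <- apply_turnover(st, 2e-3, 0, dt = 1, params = p)
  expect_equal(st4$thickness[1], 2e-3)
  expect_equal(st4$age[1], 0)
  expect_warning(apply_turnover(st, 0, 1, dt = 1, params = p), "depleted")
})

test_that("tunneling resorption removes a proportional cross-section", {
  p <- bone_params(lifo_fraction = 0)  # fully proportional
  st <- layer_stack(thickness = c(0.1, 0.2, 0.3), age = c(10, 100, 1000))
  st1 <- apply_turnover(st, 0, 0.06, dt = 1, params = p)
  expect_equal(st1$thickness, c(0.1, 0.2, 0.3) * 0.9)
  expect_equal(st1$age, c(11, 101, 1001))
})

test_that("stack volume bookkeeping is exact over random turnover sequences", {
  set.seed(7)
  p <- bone_params()  # mixed resorption
  st <- layer_stack(thickness = 0.6, age = 5000)
  total <- 0.6
  for (i in 1:300) {
    vf <- runif(1, 0, 4e-4)
    vr <- runif(1, 0, 4e-4)
    st <- apply_turnover(st, vf, vr, dt = 1, params = p)
    total <- total + vf - vr
  }
  expect_lt(abs(sum(st$thickness) - total), 1e-10)
  expect_false(is.unsorted(st$age))
})

test_that("stack summary aggregates thickness-weighted mineral content", {
  p <- bone_params()
  s1 <- stack_summary(layer_stack(0.4, 800), p)
  expect_equal(s1$v_b, 0.4)
  expect_equal(s1$alpha_mean, layer_mineral(800, p))
  s2 <- stack_summary(layer_stack(c(0.2, 0.2), c(100, 3000)), p)
  expect_equal(s2$alpha_mean, (layer_mineral(100, p) + layer_mineral(3000, p)) / 2)
  expect_equal(s2$v_m_mean,
               mean(mineral_fraction_from_ash(layer_mineral(c(100, 3000), p))))
  s0 <- stack_summary(layer_stack(), p)
  expect_equal(unlist(s0), c(v_b = 0, alpha_mean = 0, v_m_mean = 0))
})

test_that("coalescing merges near-age neighbours thickness-weighted", {
  st <- layer_stack(thickness = c(0.1, 0.1, 0.2), age = c(0, 10, 500))
  cs <- coalesce_stack(st, window = 30)
  expect_equal(length(cs$thickness), 2)
  expect_equal(cs$thickness[1], 0.2)
  expect_equal(cs$age[1], 5)
  expect_equal(sum(cs$thickness), sum(st$thickness))
  expect_identical(coalesce_stack(st, window = 0), st)
})
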