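test_that("input function is zero at origin and nonnegative on its support", {
  cp <- fix_input()
  expect_equal(eval_input(cp, 0), 0)
  tt <- seq(0, 90, by = 0.1)
  expect_true(all(eval_input(cp, tt) > -1e-12))
  expect_error(input_function(l1 = 0.1, l2 = 0.35, l3 = 0.009),
               "l1 > l2 > l3")
})

test_that("1TC forward model matches a stiff ODE oracle and its limits", {
  cp <- fix_input()
  sched <- fix_schedule()

  # K1 = 0 gives the zero curve
  expect_equal(onetc_forward(cp, 0, 0.1, sched)$values,
               rep(0, n_frames(sched)))

  # constant plasma input approaches the steady state c * K1 / k2
  cp_const <- structure(list(A1 = 0, A2 = 0, A3 = 2, l1 = 3, l2 = 2,
                             l3 = 1e-9, t_max = 1e5),
                        class = "input_function")
  long <- frame_schedule(c(0, 4000), c(4000, 5000))
  out <- onetc_forward(cp_const, 0.3, 0.05, long)
  expect_equal(out$values[2], 2 * 0.3 / 0.05, tolerance = 1e-3)

  # trapezoidal convolution vs lsoda on default parameters
  skip_if_not_installed("deSolve")
  K1 <- 0.45; k2 <- 0.03
  sim <- onetc_forward(cp, K1, k2, sched)
  ode <- deSolve::ode(y = c(C = 0), times = seq(0, 90, 0.01),
                      func = function(t, y, p)
                        list(K1 * eval_input(cp, t) - k2 * y),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  oracle <- petsuvr:::frame_average(ode[, 1], ode[, 2], sched)
  expect_lt(max(abs(sim$values - oracle) / oracle), 0.005)

  expect_error(onetc_forward(cp, 0.3, 0.05,
                             frame_schedule(c(0, 100), c(100, 130))),
               "support")
})

test_that("SRTM forward model reduces to identity and is monotone in bp", {
  ref <- fix_ref()
  # R1 = 1, bp = 0 reproduces the reference exactly
  same <- srtm_forward(ref, R1 = 1, k2 = 0.2, bp = 0)
  expect_equal(same$values, ref$values, tolerance = 1e-10)

  # late-time target/reference ratio grows with bp
  late <- n_frames(ref$schedule)
  ratios <- sapply(c(0.5, 1, 2), function(bp)
    srtm_forward(ref, R1 = 0.9, k2 = 0.2, bp = bp)$values[late] /
      ref$values[late])
  expect_true(all(diff(ratios) > 0))

  expect_error(srtm_forward(ref, 1, 0.2, -1.2), "exceed -1")
})

test_that("frame noise is seed-deterministic with the prescribed variance", {
  tc <- fix_ref()
  expect_identical(add_frame_noise(tc, 0), tc)
  n1 <- add_frame_noise(tc, 0.002, seed = 99)
  n2 <- add_frame_noise(tc, 0.002, seed = 99)
  expect_identical(n1$values, n2$values)
  expect_true(n1$noisy)

  # empirical per-frame variance matches sigma^2(i) = a C e^(lambda t) / dur
  alpha <- 0.0015
  reps <- vapply(seq_len(10000), function(i)
    add_frame_noise(tc, alpha, seed = 100000 + i)$values,
    numeric(n_frames(tc$schedule)))
  emp <- apply(reps, 1, var)
  theo <- alpha * tc$values * exp(log(2) / 109.77 * tc$schedule$mid) /
    tc$schedule$dur
  expect_lt(max(abs(emp - theo) / theo), 0.05)
})

test_that("cohort simulation is reproducible and honors degenerate settings", {
  cfg0 <- cohort_config(n_per_group = 2, reduction = numeric(0), cv = 0,
                        alpha = 0)
  scans <- simulate_cohort(cfg0)
  # no genotype effect, no variability, no noise: all animals identical
  vals <- lapply(scans, function(s) s$tacs$HC$values)
  for (v in vals[-1]) expect_equal(v, vals[[1]])

  # bit-reproducibility under a fixed seed
  cfg <- cohort_config(n_per_group = 3, seed = 123L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(lapply(s1, function(s) s$tacs$HC$values),
                   lapply(s2, function(s) s$tacs$HC$values))

  # reference region true DVR is exactly 1 in every subject
  expect_true(all(vapply(s1, function(s) attr(s, "dvr_true")[["BS"]] == 1,
                         logical(1))))

  # noiseless TACs are nonnegative
  s3 <- simulate_cohort(cohort_config(n_per_group = 2, alpha = 0))
  expect_true(all(unlist(lapply(s3, function(s)
    lapply(s$tacs, function(t) t$values))) >= 0))

  expect_error(simulate_cohort(cohort_config(reduction = c(XX = 0.1))),
               "invalid region")
  expect_error(cohort_config(n_per_group = 1), "at least 2")
  expect_error(cohort_config(reduction = c(HC = 1.2)), "\\[0, 1\\)")
})

test_that("group-mean DVR ratio tracks the configured genotype reduction", {
  red <- 0.10
  cfg <- cohort_config(n_per_group = 100, reduction = c(HC = red),
                       cv = c("WT" = 0.05, "APP/PS1" = 0.05), alpha = 0,
                       seed = 77L)
  scans <- simulate_cohort(cfg)
  gt <- vapply(scans, function(s) s$genotype, character(1))
  hc <- vapply(scans, function(s) attr(s, "dvr_true")[["HC"]], numeric(1))
  ratio <- mean(hc[gt == "APP/PS1"]) / mean(hc[gt == "WT"])
  expect_lt(abs(ratio - (1 - red)), 0.02)
})

test_that("default calibration reproduces the wild-type hippocampal SUVR level", {
  # sample mean of WT hippocampal SUVR(60-90) within 0.05 of 1.47 at n = 200
  scans <- simulate_cohort(cohort_config(n_per_group = 200, seed = 2024L))
  wt <- Filter(function(s) s$genotype == "WT", scans)
  suvr <- vapply(wt, function(s)
    compute_suvr(s, pet_window(60, 90))$suvr[["HC"]], numeric(1))
  expect_lt(abs(mean(suvr) - 1.47), 0.05)
  # peak SUV of the highest-binding region lands near 2.4 after 30 min
  tic <- scans[[1]]$tacs$IC
  expect_gt(max(tic$values), 2.0)
  expect_lt(max(tic$values), 2.8)
  expect_gt(mid_times(tic$schedule)[which.max(tic$values)], 30)
  # brain stem lowest, inferior colliculi highest late uptake
  late <- vapply(scans[[1]]$tacs[c("BS", "CB", "HC", "IC")],
                 function(t) t$values[n_frames(t$schedule)], numeric(1))
  expect_true(which.min(late) == 1L && which.max(late) == 4L)
})
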