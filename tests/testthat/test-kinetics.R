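test_that("SRTM fit of the reference against itself is the identity fit", {
  ref <- fix_ref()
  fit <- suppressWarnings(fit_srtm(ref, ref))
  expect_equal(fit$R1, 1, tolerance = 1e-8)
  expect_equal(fit$bp, 0, tolerance = 1e-8)
  expect_equal(fit$dvr, 1, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)
})

test_that("SRTM recovers forward-model parameters on noiseless fixtures", {
  ref <- fix_ref()
  cases <- list(c(R1 = 0.9, k2 = 0.25, bp = 0.8),
                c(R1 = 1.1, k2 = 0.15, bp = 0.4),
                c(R1 = 0.8, k2 = 0.30, bp = 1.5))
  for (p in cases) {
    tgt <- srtm_forward(ref, p[["R1"]], p[["k2"]], p[["bp"]], region = "X")
    bfm <- fit_srtm(tgt, ref)
    expect_equal(bfm$dvr, 1 + p[["bp"]], tolerance = 1e-3)
    expect_equal(bfm$R1, p[["R1"]], tolerance = 1e-2)
    expect_false(bfm$boundary)
    # NLS refinement agrees with BFM on clean data; the residual gap is
    # bounded by the k2a grid spacing of the BFM estimate
    nls <- fit_srtm(tgt, ref, method = "nls")
    expect_equal(nls$dvr, bfm$dvr, tolerance = 1e-3)
    expect_equal(nls$dvr, 1 + p[["bp"]], tolerance = 1e-4)
  }
  expect_error(fit_srtm(tac(ref$schedule, rep(0, n_frames(ref$schedule)),
                            "Z"), ref), NA)
  zero <- tac(ref$schedule, rep(0, n_frames(ref$schedule)), "BS")
  expect_error(fit_srtm(ref, zero), "identically zero")
})

test_that("srtm_fit behaves like a standard R model object", {
  ref <- fix_ref()
  tgt <- srtm_forward(ref, 0.95, 0.2, 0.6, region = "HC")
  fit <- fit_srtm(tgt, ref)
  expect_s3_class(fit, "srtm_fit")
  expect_named(coef(fit), c("R1", "k2", "BP_ND", "DVR"))
  expect_length(fitted(fit), n_frames(ref$schedule))
  expect_equal(unname(residuals(fit)), unname(tgt$values - fitted(fit)))
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "DVR")
  expect_output(print(summary(fit)), "residual sigma")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("BFM grid refinement changes DVR by less than 0.1%", {
  ref <- fix_ref()
  tgt <- srtm_forward(ref, 0.9, 0.22, 0.55, region = "X")
  coarse <- fit_srtm(tgt, ref)   # 200-point default grid
  fine <- fit_srtm(tgt, ref,
                   k2a_grid = exp(seq(log(0.006), log(0.6),
                                      length.out = 2000)))
  expect_lt(abs(fine$dvr - coarse$dvr) / coarse$dvr, 1e-3)
})

test_that("reference Logan recovers slope on proportional and 1TC targets", {
  ref <- fix_ref()
  # exactly proportional curves: slope = c, intercept = 0
  prop <- tac(ref$schedule, 1.7 * ref$values, "P", units = ref$units)
  fit <- fit_ref_logan(prop, ref, t_star = 10)
  expect_equal(fit$dvr, 1.7, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # noiseless 1TC target with known DVR; k2prime closes the model exactly
  cp <- fix_input()
  tgt <- onetc_forward(cp, 0.45, 0.04 / 1.5, ref$schedule, region = "HC")
  l1 <- fit_ref_logan(tgt, ref, t_star = 10, k2prime = 0.04)
  expect_lt(abs(l1$dvr - 1.5) / 1.5, 0.02)
  expect_true(l1$n_points >= 3)

  # t* = 0 and t* = 10 agree closely when the k2prime term is included
  l0 <- fit_ref_logan(tgt, ref, t_star = 0, k2prime = 0.04)
  expect_lt(abs(l0$dvr - l1$dvr), 0.01)

  expect_error(fit_ref_logan(tgt, ref, t_star = 89), "at least 3")
  expect_error(fit_ref_logan(tgt, ref, t_star = 10, k2prime = -0.1),
               "positive")
})

test_that("Logan DVRs at t* = 0 and t* = 10 agree across a subject's regions", {
  scans <- simulate_cohort(cohort_config(n_per_group = 2, seed = 31L))
  sc <- scans[[1]]
  ref <- sc$tacs[[sc$reference_region]]
  fits <- suppressWarnings(fit_subject(sc))
  k2p <- ref_k2prime(fits)
  regions <- setdiff(names(sc$tacs), sc$reference_region)
  d0 <- sapply(regions, function(r)
    fit_ref_logan(sc$tacs[[r]], ref, t_star = 0, k2prime = k2p)$dvr)
  d10 <- sapply(regions, function(r)
    fit_ref_logan(sc$tacs[[r]], ref, t_star = 10, k2prime = k2p)$dvr)
  sl <- coef(lm(d0 ~ d10))[2]
  expect_gt(sl, 0.8)
  expect_lt(sl, 1.05)
})

test_that("fit_subject fits every non-reference region, reference DVR is 1", {
  scans <- simulate_cohort(cohort_config(n_per_group = 2, alpha = 0, cv = 0))
  sc <- scans[[1]]
  fits <- fit_subject(sc, method = "nls", logan = TRUE, k2prime = 0.04)
  truth <- attr(sc, "dvr_true")
  # noiseless regional DVRs match the generative truth (WB is a mixture
  # of 1TC curves, not itself 1TC, so it is excluded from the exact check)
  for (r in setdiff(names(fits$srtm), "WB"))
    expect_equal(fits$srtm[[r]]$dvr, truth[[r]], tolerance = 1e-3)
  d <- dvrs(fits)
  expect_equal(unname(d["BS"]), 1)
  tab <- as.data.frame(fits)
  expect_true(all(c("subject", "region", "R1", "DVR", "rss") %in% names(tab)))
  expect_equal(tab$DVR[tab$region == "BS"], 1)
  # a degenerate region is dropped from the Logan set with a warning while
  # the remaining regions are still fitted
  sc$tacs$BAD <- tac(sc$schedule, rep(0, n_frames(sc$schedule)), "BAD",
                     units = "SUV")
  expect_warning(f2 <- fit_subject(sc, logan = TRUE), "BAD")
  expect_false("BAD" %in% names(f2$logan))
  expect_true("HC" %in% names(f2$srtm))
  expect_true("HC" %in% names(f2$logan))
})

test_that("median SRTM DVR bias is small and shrinks with the noise level", {
  ref0 <- fix_ref()
  cp <- fix_input()
  true_dvr <- 1.513
  tgt0 <- onetc_forward(cp, 0.45, 0.04 / true_dvr, ref0$schedule,
                        region = "HC")
  bias <- sapply(c(0.0015, 0.0005), function(alpha) {
    d <- vapply(1:40, function(i) {
      r <- add_frame_noise(ref0, alpha, seed = 2000 + i)
      h <- add_frame_noise(tgt0, alpha, seed = 6000 + i)
      suppressWarnings(fit_srtm(h, r)$dvr)
    }, numeric(1))
    abs(median(d) - true_dvr) / true_dvr
  })
  expect_lt(bias[1], 0.02)
  expect_lte(bias[2], bias[1] + 0.002)
})
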