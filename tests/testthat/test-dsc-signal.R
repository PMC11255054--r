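# Per-curve analytics: landmark detection, concentration conversion, PSR,
# BSW leakage fit and corrected CBV.

test_that("signal/concentration conversion identities hold", {
  mk <- markers_of(arrival = 17, t_min = 19, fpe = 25)
  # constant signal at s0 maps to zero concentration everywhere
  cv <- time_curve(rep(100, 60), 1.5, 0.04)
  expect_equal(signal_to_delta_r2star(cv, mk)$delta_r2star, rep(0, 60))

  # closed form at a single point
  s <- rep(100, 60)
  s[30] <- 100 * exp(-0.04 * 5)
  cc <- signal_to_delta_r2star(time_curve(s, 1.5, 0.04), mk)
  expect_equal(cc$delta_r2star[30], 5, tolerance = 1e-12)

  # reconstruction round trip to 1e-10
  set.seed(1)
  s <- 100 * exp(-0.04 * pmax(rnorm(60, 5, 3), 0))
  cc <- signal_to_delta_r2star(time_curve(s, 1.5, 0.04), mk)
  expect_lt(max(abs(100 * exp(-0.04 * cc$delta_r2star) - s)), 1e-10)

  # non-positive signal is clipped, not NaN
  s[10] <- -5
  cc <- signal_to_delta_r2star(time_curve(s, 1.5, 0.04), mk)
  expect_true(all(is.finite(cc$delta_r2star)))
})

test_that("bolus arrival and minimum match an exhaustive scan of the rule", {
  s <- dip_curve()
  mk <- detect_bolus_markers(s, acq = t_acq)

  # independent re-implementation: first index with two consecutive points
  # below mean - 3 sd of the baseline accumulated up to two points earlier
  oracle_arrival <- NA
  for (i in 14:59) {
    bw <- s[4:(i - 3)]
    thr <- mean(bw) - 3 * sd(bw)
    if (s[i] < thr && s[i + 1] < thr) {
      oracle_arrival <- i
      break
    }
  }
  expect_equal(mk$arrival, oracle_arrival)
  expect_true(mk$arrival %in% 14:16)
  expect_equal(mk$t_min, 17)
  expect_equal(mk$s0, 100)
  expect_equal(s[mk$t_min], 40)
})

test_that("flat curves and too-early boluses are rejected", {
  expect_error(detect_bolus_markers(rep(100, 60), acq = t_acq),
               class = "pq_no_bolus")
  # dip before a baseline can be formed
  s <- c(rep(100, 6), 60, 40, 60, rep(100, 51))
  expect_error(detect_bolus_markers(s, acq = t_acq),
               class = "pq_insufficient_baseline")
})

test_that("first-pass end follows the slope rule and its fallback", {
  # decaying recovery onto a plateau: rule fires within 2 of plateau onset
  t_min <- 17
  s <- c(dip_curve(baseline_n = 13, dip = c(85, 70, 55, 40),
                   recovery = c(55, 64, 67), plateau = 67))
  fp <- detect_first_pass_end(s, t_min, acq = t_acq)
  expect_false(fp$fallback)
  expect_lte(abs(fp$fpe - (t_min + 3)), 2)

  # independent brute-force evaluation of the rule on random curves
  set.seed(7)
  for (rep in 1:25) {
    s <- c(rep(100, 16), 40, pmin(40 + cumsum(runif(43, 0, 6)), 92)) +
      rnorm(60, 0, 1)
    fp <- detect_first_pass_end(s, 17, acq = t_acq)
    d <- diff(s)[17:59]
    ofpe <- NA
    for (j in 3:length(d)) {
      m <- mean(d[1:j])
      if (m >= 0 && m < sd(d[1:j])) {
        ofpe <- 17 + j
        break
      }
    }
    if (is.na(ofpe)) {
      expect_true(fp$fallback)
      expect_equal(fp$fpe, min(17 + 10, 60))
    } else {
      expect_equal(fp$fpe, ofpe)
    }
  }

  # monotone decline after the minimum: fallback at t_min + 10, flagged
  s <- c(rep(100, 16), 100 - cumsum(rep(1.5, 44)))
  fp <- detect_first_pass_end(s, 17, acq = t_acq)
  expect_true(fp$fallback)
  expect_equal(fp$fpe, 27)

  # too few points after the minimum
  expect_error(detect_first_pass_end(rep(100, 40), t_min = 38, acq = t_acq),
               class = "pq_curve_too_short")
})

test_that("PSR is the recovered fraction of the bolus depth", {
  s <- dip_curve()
  mk <- markers_of(arrival = 14, t_min = 17, fpe = 21)
  cv <- time_curve(s, t_acq$tr, t_acq$te)
  # s0 = 100, S_min = 40, S(fpe) = 88
  expect_equal(compute_psr(cv, mk), (88 - 40) / 60)

  s[21] <- 100
  expect_equal(compute_psr(time_curve(s, 1.5, 0.04), mk), 1)
  s[21] <- 40
  expect_equal(compute_psr(time_curve(s, 1.5, 0.04), mk), 0)
  s[21] <- 80
  expect_equal(compute_psr(time_curve(s, 1.5, 0.04), mk), 2 / 3)

  # strictly increasing in S(fpe)
  vals <- sapply(seq(40, 110, by = 5), function(sf) {
    s[21] <- sf
    compute_psr(time_curve(s, 1.5, 0.04), mk)
  })
  expect_true(all(diff(vals) > 0))

  # below the noise floor: QC rejection
  mk_shallow <- markers_of(arrival = 14, t_min = 17, fpe = 22, s0 = 100)
  s2 <- rep(100, 60)
  s2[17] <- 99
  expect_error(compute_psr(time_curve(s2, 1.5, 0.04), mk_shallow,
                           noise_floor = 5),
               class = "pq_qc_reject")
})

test_that("BSW fit equals the normal-equations solution", {
  mk <- markers_of(arrival = 17, t_min = 19, fpe = 25)
  ref <- conc_of(t_tpl$conc)

  # proportional curves: pure K1, no leakage
  fit <- fit_bsw(conc_of(2 * t_tpl$conc), ref, mk)
  expect_equal(fit$k1, 2, tolerance = 1e-10)
  expect_lt(abs(fit$k2), 1e-8)

  # known K1/K2 recovered through the cumulative basis
  tt <- seq_along(t_tpl$conc) * t_acq$tr
  cum <- pracma::cumtrapz(tt, t_tpl$conc)[, 1]
  fit <- fit_bsw(conc_of(1.5 * t_tpl$conc - 0.02 * cum), ref, mk)
  expect_equal(fit$k1, 1.5, tolerance = 1e-6)
  expect_equal(fit$k2, 0.02, tolerance = 1e-6)

  # 100 random instances against an independent normal-equations oracle
  set.seed(11)
  for (i in 1:100) {
    r <- abs(rnorm(60, 5, 3)) * c(rep(0, 16), rep(1, 44))
    y <- runif(1, 0.5, 3) * r - runif(1, -0.05, 0.05) *
      pracma::cumtrapz(tt, r)[, 1] + rnorm(60, 0, 0.2)
    w <- 17:60
    cumr <- pracma::cumtrapz(tt, r)[, 1]
    X <- cbind(r[w], cumr[w])
    beta <- solve(t(X) %*% X, t(X) %*% y[w])
    fit <- fit_bsw(conc_of(y), conc_of(r), mk)
    expect_equal(fit$k1, beta[1], tolerance = 1e-8)
    expect_equal(fit$k2, -beta[2], tolerance = 1e-8)
  }

  expect_error(fit_bsw(conc_of(t_tpl$conc), conc_of(rep(0, 60)), mk),
               class = "pq_degenerate_reference")
})

test_that("corrected CBV integrates the corrected curve linearly", {
  mk <- markers_of(arrival = 17, t_min = 19, fpe = 25)
  nofit <- structure(list(k1 = 1, k2 = 0, ref_cum = rep(0, 60)),
                     class = "leakage_fit")
  # rectangle of amplitude 1 (1/s) spanning the whole 10 s window
  rect <- c(rep(0, 16), rep(1, 44))
  mk10 <- markers_of(arrival = 54, t_min = 56, fpe = 58)
  expect_equal(corrected_cbv(conc_of(rect, dt = 10 / 6), nofit, mk10), 10,
               tolerance = 1e-12)

  # linearity in the concentration curve
  set.seed(2)
  y <- abs(rnorm(60))
  base <- corrected_cbv(conc_of(y), nofit, mk)
  for (a in c(0.5, 2, 7)) {
    expect_equal(corrected_cbv(conc_of(a * y), nofit, mk), a * base,
                 tolerance = 1e-12)
  }
})

test_that("noiseless leak-free voxels round-trip cbv and psr", {
  pre <- glioma_class_presets()$oligodendroglioma
  pre$leak_prob <- 0
  pat <- simulate_patient(pre, 150, seed = 9, dim3 = c(18, 18, 8),
                          noise_sd = 0)
  m <- extract_voxel_metrics(pat$dsc, pat$tumor_mask, pat$nawm_mask)
  ok <- m$qc_flag == "ok"
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(m$nrcbv[ok] / pat$truth$cbv_ratio[ok] - 1)), 0.03)
  expect_lt(max(abs(m$psr[ok] - pat$truth$psr_true[ok])), 0.02)
})

test_that("leakage leaves BSW-corrected CBV within 5% of the leak-free twin", {
  ref <- nawm_reference_from_curves(
    sapply(1:10, function(i)
      simulate_curve(voxel_truth(1, 0.9), t_tpl, noise_sd = 0)$signal),
    t_acq)
  for (cbv in c(1.2, 2.05, 3)) {
    for (k2 in c(-0.02, 0.01, 0.03)) {
      base <- simulate_curve(voxel_truth(cbv, 0.7), t_tpl, noise_sd = 0)
      leak <- simulate_curve(voxel_truth(cbv, 0.7, leak_k2 = k2), t_tpl,
                             noise_sd = 0)
      rc <- sapply(list(base, leak), function(sm) {
        cv <- time_curve(sm$signal, t_acq$tr, t_acq$te)
        mk <- detect_bolus_markers(cv)
        cc <- signal_to_delta_r2star(cv, mk)
        corrected_cbv(cc, fit_bsw(cc, ref$ref_conc, mk), mk)
      })
      expect_lt(abs(rc[2] / rc[1] - 1), 0.05)
    }
  }
})
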