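test_that("clock_timer wiring freezes phase at handover and gates by tau1", {
  h <- cached_run("ct_default", seg_config("clock_timer", steps = 400))
  tau1 <- h$vars$tau1; ph <- h$vars$phase
  # once tau1 = 0, the phase never moves again
  for (j in c(5, 15, 30)) {
    off <- which(!is.na(tau1[, j]) & tau1[, j] <= 0)
    expect_gt(length(off), 1)
    expect_equal(stats::sd(ph[off, j]), 0)
  }
})

test_that("clock_two_timers patterns the switch from timer 2", {
  h <- run_preset("fig4_three_state")
  fate <- final_pattern(h)
  t2 <- tau2_at_handover(h)
  fated <- which(fate > 0)
  expect_identical(fate[fated],
                   fate_from_mapping(t2[fated], switch_mapping("three_state")))
})

test_that("clock_three_timers reads its elongation rate from the growth profile", {
  h <- run_preset("fig7_growth")
  gp <- growth_profile(h$config$growth_profile)
  tau3 <- h$vars$tau3
  L_t <- rowSums(!is.na(tau3))
  pred <- vapply(seq_along(h$v_eff), function(s) {
    row <- s + 1L
    if (!as.logical(h$vars$signal[row, L_t[row]])) return(0) # PSC gone
    growth_rate(tau3[row, L_t[row]], gp)
  }, numeric(1))
  expect_equal(h$v_eff, pred)
})

test_that("apply_clamp validates its module and composes", {
  cfg <- preset_config("fig6_timer_feedback")
  expect_error(apply_clamp(cfg, "tau3", 0.5), "clamp")
  expect_error(apply_clamp(cfg, "nonsense", 0.5), "clamp")
  expect_error(apply_clamp(cfg, "oscillator", 2), "clamp values")
  same <- validate_config(cfg)
  expect_equal(unclass(same), unclass(cfg)) # clamping nothing changes nothing
})

test_that("oscillator clamp in the timer-feedback model removes wavefront pulses", {
  hfree <- run_preset("fig6_freeze")
  hfb <- run_preset("fig6_timer_feedback")
  hcl <- cached_run("fig6_tf_clamp0",
                    apply_clamp(preset_config("fig6_timer_feedback"),
                                "oscillator", 0))
  # with o clamped to 0 the rate scale is exp(0) = 1: the maturation field is
  # bit-identical to the feedback-free freeze model (the clamp also freezes
  # the oscillator phase itself, so only tau1 is compared)
  expect_identical(hcl$vars$tau1, hfree$vars$tau1)
  # the un-clamped feedback run pulses: the front stalls for longer stretches
  stall <- function(h) {
    wf <- summary_curves(h)$wavefront
    max(rle(diff(wf[150:400]) == 0)$lengths)
  }
  expect_gt(stall(hfb), stall(hcl))
  expect_false(identical(hfb$vars$tau1, hfree$vars$tau1))
})

test_that("oscillator clamped to 1 scales timer 1 by exp(-k)", {
  cfg <- apply_clamp(preset_config("fig6_timer_feedback"), "oscillator", 1)
  cfg$steps <- 120
  h <- run_model(validate_config(cfg))
  tau1 <- h$vars$tau1
  j <- 1L # anterior cell, released once the embryo outgrows the signal range
  x <- tau1[, j]
  dec <- -diff(x[!is.na(x)])
  dec <- dec[dec > 0 & x[-length(x)] < 1]
  expect_equal(unique(round(dec, 12)),
               round(exp(-cfg$k) / cfg$T1, 12))
})

test_that("derive_noclock_config solves the gradient closed form", {
  expect_equal(derive_noclock_config(4, m = 4, L_final = 10,
                                     T1 = 10, T3 = 400)$slope, 1 / 16)
  expect_equal(derive_noclock_config(4, m = 1, L_final = 4,
                                     T1 = 10, T3 = 400)$slope, 1 / 4)
  expect_error(derive_noclock_config(4, m = 1, L_final = 10, T3 = 40),
               "leaves \\[0, 1\\]")
  expect_error(derive_noclock_config(10, m = 2, L_final = 21,
                                     T1 = 40, T3 = 40), "depleted")
})

test_that("segment and SAZ lengths obey L_seg = P*v and L_SAZ = T*v", {
  for (P in c(10, 20, 30)) for (v in c(0.1, 0.2, 0.5)) {
    h <- cached_run(sprintf("sweep_P%d_v%g", P, v),
                    seg_config("clock_timer", P = P, v = v, steps = 400))
    ss <- steady_state_metrics(h)
    expect_lte(abs(ss$L_SAZ - 40 * v), 1) # T1 = 40
    if (round(P * v) >= 2)  # P*v = 1 gives a uniform (segment-free) pattern
      expect_lte(abs(ss$L_seg - P * v), 1)
  }
})

test_that("spatial SAZ length ignores v and scales with lambda", {
  saz <- vapply(c(0.1, 0.2, 0.5), function(v) {
    h <- cached_run(sprintf("sp_v%g", v),
                    seg_config("clock_timer", saz_mode = "spatial", v = v,
                               steps = 400))
    steady_state_metrics(h)$L_SAZ
  }, numeric(1))
  expect_lt(max(saz) - min(saz), 1)
  saz16 <- steady_state_metrics(
    cached_run("sp_lam16", seg_config("clock_timer", saz_mode = "spatial",
                                      lam = 16, steps = 400)))$L_SAZ
  expect_equal(saz16 / saz[2], 15 / 7, tolerance = 0.05)
})

test_that("SAZ phase difference: v-invariant with a timer, v-sensitive with PI", {
  # a long-timer regime keeps several stripes in the SAZ, so the stripe-count
  # metric is not dominated by single-cell sampling granularity
  dphi_t <- vapply(c(0.1, 0.2, 0.5), function(v) {
    h <- cached_run(sprintf("dphi_t_v%g", v),
                    seg_config("clock_timer", T1 = 300, v = v, steps = 900))
    steady_state_metrics(h)$delta_phase
  }, numeric(1))
  expect_lt((max(dphi_t) - min(dphi_t)) / mean(dphi_t), 0.05)
  dphi_s <- vapply(c(0.1, 0.2, 0.5), function(v) {
    h <- cached_run(sprintf("dphi_s_v%g", v),
                    seg_config("clock_timer", saz_mode = "spatial", lam = 60,
                               v = v, steps = 900))
    steady_state_metrics(h)$delta_phase
  }, numeric(1))
  expect_true(all(diff(dphi_s) < 0))
})

test_that("one segment boundary is fixed every P steps (+/- 1)", {
  h <- cached_run("ct_default", seg_config("clock_timer", steps = 400))
  sf <- segment_formation(h)
  expect_gt(nrow(sf), 5)
  expect_true(all(abs(diff(sf$t_formed) - h$config$P) <= 1))
})

test_that("timer-2 duration reshapes the pattern as T2 : P dictates", {
  base <- seg_config("clock_two_timers", mapping = "three_state", v = 0.5,
                     T2 = 20, steps = 400)
  fated <- function(h) { p <- final_pattern(h); p[p > 0] }
  r_eq <- interior_repeat(fated(cached_run("tt_T2eq", base)))
  share <- function(r, s) sum(r == s) / length(r)
  # T2 = P: realized proportions resemble the equal-width mapping
  expect_true(all(abs(vapply(1:3, share, numeric(1), r = r_eq) - 1 / 3)
                  <= 1.5 / length(r_eq)))
  # T2 = P/2: the final mapping state over-fills each repeat
  cfg_half <- base; cfg_half$T2 <- 10
  r_half <- interior_repeat(
    fated(cached_run("tt_T2half", validate_config(cfg_half))))
  expect_gt(share(r_half, 3), share(r_eq, 3))
  # T2 = 2P: timer 2 is always reset before its late states are reached
  cfg_dbl <- base; cfg_dbl$T2 <- 40
  p_dbl <- final_pattern(cached_run("tt_T2dbl", validate_config(cfg_dbl)))
  expect_false(3L %in% p_dbl[p_dbl > 0])
})

test_that("oscillator-gated elongation halts while o >= 0.5 and halves the readout", {
  h <- run_preset("fig6_elongation_feedback")
  osc <- h$vars$osc
  L_t <- rowSums(!is.na(osc))
  opost <- osc[cbind(seq_len(nrow(osc)), L_t)]
  adds <- diff(L_t)
  expect_true(all(adds == 0 | opost[-1] < 0.5))
  ph <- recorded_phase_distribution(h)
  expect_lte(phase_span(ph$phases), 0.5)
})

test_that("k = 0 timer feedback is bit-identical to the plain freeze model", {
  h0 <- run_model(seg_config("freeze_timer_feedback", k = 0, steps = 300))
  hf <- run_model(seg_config("freeze", steps = 300))
  expect_identical(h0$vars, hf$vars)
})

test_that("temporal three-timer runs exhaust the SAZ; spatial ones persist", {
  h <- run_preset("fig7_growth")
  expect_false(is.na(h$term_step))
  expect_true(all(final_pattern(h) > 0))
  expect_false(h$final$psc_active)
  # elongation halts permanently: the positive-rate steps form one block
  pos <- which(h$v_eff > 0)
  expect_identical(pos, seq_len(length(pos)))
  hs <- cached_run("fig7_spatial",
                   seg_config("clock_three_timers", saz_mode = "spatial",
                              mapping = "three_state", T3 = 600, steps = 900,
                              growth_profile = list(tau3 = c(0, 1),
                                                    v = c(0, 0.5))))
  expect_true(is.na(hs$term_step))
  expect_gt(sum(final_pattern(hs) == 0), 0)  # PI > 0 cells never fate
  expect_true(all(tail(hs$v_eff, 50) == 0))
  expect_identical(final_pattern(hs) == 0, hs$final$tau1 > 0)
})

test_that("segment sizes are a monotone image of the growth profile", {
  h <- run_preset("fig7_growth")
  sf <- segment_formation(h)
  expect_gt(nrow(sf), 10)
  # lengths are integers, so monotonicity is asserted up to the 1-cell
  # quantization used throughout the scaling laws
  ord <- order(sf$v_at_formation)
  len <- sf$length[ord]
  expect_true(all(diff(len) >= -1))
  expect_gt(stats::cor(sf$v_at_formation, sf$length, method = "spearman"),
            0.95)
})

test_that("the matched clock-free model reproduces the sequential repeat faster", {
  href <- cached_run("noclock_ref", noclock_reference_config())
  hnc <- run_preset("fig8_noclock")
  expect_true(all(final_pattern(href) > 0))
  expect_true(all(final_pattern(hnc) > 0))
  eq <- pattern_equivalence(final_pattern(href), final_pattern(hnc))
  expect_true(eq$equivalent)
  expect_identical(eq$mismatches, 0L)
  expect_lt(hnc$term_step, href$term_step)
})

test_that("tau3 -> tau1 rate modulation shrinks the late SAZ phase difference", {
  base <- seg_config("clock_three_timers", mapping = "three_state", T3 = 600,
                     steps = 900,
                     growth_profile = list(tau3 = c(0, 0.3, 1),
                                           v = c(0, 0.5, 0.5)))
  mod <- validate_config(modifyList(unclass(base), list(
    tau3_to_tau1 = list(mode = "rate",
                        map = list(tau3 = c(0, 1), value = c(3, 1))))))
  cb <- summary_curves(cached_run("mod13_base", base))
  cm <- summary_curves(cached_run("mod13_rate", mod))
  # with modulation, late-run stripes are squeezed out relative to early run
  expect_lt(cm$delta_phase[521] / cm$delta_phase[301], 0.7)
  expect_gt(cb$delta_phase[521] / cb$delta_phase[301], 0.8)
})

test_that("uniform frequency profile abolishes the SAZ phase difference", {
  h <- cached_run("ct_uniform",
                  seg_config("clock_timer", freq_profile_osc = "uniform",
                             steps = 300))
  curves <- summary_curves(h)
  expect_true(all(abs(curves$delta_phase) < 1e-12, na.rm = TRUE))
})
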