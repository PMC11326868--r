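soma_only_morph <- tibble::tibble(
  section = 1L, name = "soma", group = "soma", parent = NA_integer_,
  length_um = 33.6, diam_um = 6.1, nseg = 1L
)

passive_channels <- function(leak = 8e-5, e_leak = -60, ih = 0) {
  moc_channels(leak = c(all = leak), kht = c(all = 0, soma = 0, axon = 0),
               klt = c(all = 0), na = c(all = 0), ih = c(all = ih),
               e_leak = e_leak)
}

test_that("the reference morphology discretises to exactly 86 segments", {
  m <- moc_morphology()
  expect_equal(sum(m$nseg), 86)
  model <- default_model()
  expect_equal(model$n_segments, 86)
  # total membrane area equals the analytic sum of cylinder areas
  analytic <- sum(pi * m$diam_um * m$length_um) * 1e-8
  expect_lt(abs(model$total_area_cm2 - analytic) / analytic, 1e-3)
  expect_error(moc_morphology(n_daughters = c(0, 5, 5)))
  bad <- m
  bad$length_um[3] <- 0
  expect_error(build_model(bad), "positive")
})

test_that("a soma-only compartment has the analytic cylinder area", {
  model <- build_model(soma_only_morph, channels = passive_channels())
  expect_lt(abs(model$total_area_cm2 * 1e8 - pi * 6.1 * 33.6) /
              (pi * 6.1 * 33.6), 1e-3)
})

test_that("morphologies round-trip through SWC", {
  m <- moc_morphology()
  path <- file.path(withr::local_tempdir(), "moc.swc")
  write_swc(m, path)
  back <- read_swc(path)
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$length_um, m$length_um, tolerance = 1e-3)
  expect_equal(back$diam_um, m$diam_um, tolerance = 1e-3)
  expect_equal(back$parent, m$parent)
})

test_that("synapse conductance is peak-normalised to its weight", {
  for (taus in list(c(0.2, 6), c(2.75, 3.64), c(0.5, 2))) {
    syn <- synapse_spec(taus[1], taus[2], weight = 0.0015, reversal = 0)
    tp <- mocsyn:::biexp_peak_time(taus[1], taus[2])
    g_peak <- synapse_conductance(syn, tp)
    expect_lt(abs(g_peak - 0.0015) / 0.0015, 1e-6)
    # analytic peak time is the true maximum
    tgrid <- seq(max(tp - 0.5, 1e-3), tp + 0.5, by = 1e-4)
    expect_lte(max(synapse_conductance(syn, tgrid)), g_peak * (1 + 1e-6))
  }
  expect_warning(s <- synapse_spec(3.64, 2.75, 1e-4, -90), "swap")
  expect_lt(s$tau_rise, s$tau_decay)
})

test_that("holding current behaves as steady-state balance predicts", {
  model <- build_model(soma_only_morph, channels = passive_channels())
  h <- set_holding(model)
  expect_lt(abs(h$bias_na), 1e-3)  # leak reversal at the target -> no bias
  # HCN (reversal -38) depolarises, so a hyperpolarising bias is needed
  model_ih <- build_model(soma_only_morph,
                          channels = passive_channels(ih = 2e-4))
  expect_lt(set_holding(model_ih)$bias_na, 0)
  # deeper target -> strictly more negative bias
  h70 <- set_holding(model_ih, target = -70)
  expect_lt(h70$bias_na, set_holding(model_ih, target = -60)$bias_na)
})

test_that("the integrator matches a 16x-finer reference on a single compartment", {
  model <- build_model(soma_only_morph, channels = passive_channels())
  h <- set_holding(model)
  syn <- synapse_spec(0.2, 6, 2e-5, 0, onset = 20)
  amp_at <- function(dt) {
    sim <- simulate(model, syn, duration = 120, holding = h, dt = dt)
    max(sim$v_soma) + 60
  }
  a_coarse <- amp_at(0.05)
  a_fine <- amp_at(0.05 / 16)
  expect_lt(abs(a_coarse - a_fine) / a_fine, 0.005)
})

test_that("the calibrated model holds its resting state and converges in dt", {
  model <- default_model()
  h <- default_holding()
  sim <- simulate(model, NULL, duration = 300, holding = h)
  expect_true(all(abs(sim$v_soma + 60) < 0.5))
  # halving dt changes the evoked-PSP amplitude by < 1%
  e1 <- run_evoked_psp(model, "epsp_only", holding = h, dt = 0.05)
  h2 <- set_holding(model, dt = 0.025)
  e2 <- run_evoked_psp(model, "epsp_only", holding = h2, dt = 0.025)
  expect_lt(abs(e1$amplitude_mv - e2$amplitude_mv) / e2$amplitude_mv, 0.01)
})

test_that("synaptic current vanishes at the reversal potential", {
  # hold a passive compartment at the synapse reversal: no deflection
  model <- build_model(soma_only_morph,
                       channels = passive_channels(e_leak = -90))
  h <- set_holding(model, target = -90)
  sim <- simulate(model, synapse_spec(2.75, 3.64, 5e-4, -90, onset = 20),
                  duration = 100, holding = h)
  expect_lt(diff(range(sim$v_soma)), 0.02)
})

test_that("PSP measurement handles edge cases", {
  model <- default_model()
  h <- default_holding()
  z <- run_evoked_psp(model, "epsp_only", holding = h, dt = 0.05)
  sim0 <- simulate(model, evoked_epsp_spec(20, weight_scale = 0),
                   duration = 150, holding = h, dt = 0.05)
  expect_lt(abs(measure_psp(sim0, onset = 20)$amplitude_mv), 0.05)
  expect_gt(z$amplitude_mv, 1)
})

test_that("AP detection applies threshold, refractory and both rate rules", {
  spike <- function(t0, t) 80 * exp(-((t - t0) / 0.4)^2) - 60
  t <- seq(0, 100, by = 0.025)
  v <- do.call(pmax, lapply(seq(30, 70, by = 10), spike, t))
  fake <- list(time = t, v_soma = v, synapses = NULL)
  aps <- detect_aps(fake, t_ref = 0)
  expect_equal(aps$n_aps, 5)
  expect_equal(aps$rate_span_hz, 100, tolerance = 0.01)
  expect_lt(abs(aps$first_ap_latency_ms - 30), 0.5)
  expect_equal(aps$rate_window_hz, 50, tolerance = 0.01)
  # subthreshold trace -> none
  expect_equal(detect_aps(list(time = t, v_soma = rep(-60, length(t)),
                               synapses = NULL))$n_aps, 0)
  # two crossings 0.3 ms apart count once
  v2 <- -60 + 80 * (exp(-((t - 50) / 0.1)^2) + exp(-((t - 50.3) / 0.1)^2))
  expect_equal(detect_aps(list(time = t, v_soma = v2, synapses = NULL))$n_aps, 1)
})
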