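test_that("train protocols validate and compose synapse schedules", {
  expect_error(train_protocol(rate = 0))
  expect_error(train_protocol(n_pulses = 0))
  expect_error(train_protocol(ipsp_scale = -1))
  p <- train_protocol(ei_latency = -10)
  expect_true(p$include_epsp && p$include_ipsp)
})

test_that("calibration is a fixed point at its own outputs", {
  cal <- default_calibration()
  achieved <- list(
    mepsp = c(amplitude = cal$report$achieved[1],
              decay_tau = cal$report$achieved[2]),
    mipsp = c(amplitude = cal$report$achieved[3],
              decay_tau = cal$report$achieved[4])
  )
  cal2 <- calibrate_model(default_model(), targets = achieved)
  expect_equal(cal2$report$achieved[c(1, 3)],
               cal$report$achieved[c(1, 3)], tolerance = 1e-3)
  expect_lt(max(abs(cal2$report$residual[c(1, 3)])), 0.01)
})

test_that("mini synapses never outlast their evoked counterparts", {
  cal <- default_calibration()
  expect_lte(cal$mini_synapses$epsp$tau_decay, 6)
  expect_lte(cal$mini_synapses$ipsp$tau_decay, 3.64)
  # amplitudes fitted to the recorded means
  expect_lt(abs(cal$report$achieved[1] - 0.86), 0.01)
  expect_lt(abs(cal$report$achieved[3] + 1.57), 0.02)
})

test_that("removing one component reduces the evoked PSP appropriately", {
  model <- default_model()
  h <- default_holding()
  e <- run_evoked_psp(model, "epsp_only", holding = h)
  cc <- run_evoked_psp(model, "control", holding = h)
  i <- run_evoked_psp(model, "ipsp_only", holding = h)
  expect_lt(cc$amplitude_mv, e$amplitude_mv)  # inhibition shrinks the peak
  expect_lt(i$amplitude_mv, 0)
  expect_error(run_evoked_psp(model, "nonsense", holding = h))
})

test_that("the single-PSP latency sweep obeys its limiting cases", {
  model <- default_model()
  h <- default_holding()
  e_only <- run_evoked_psp(model, "epsp_only", holding = h)$amplitude_mv
  sw <- run_ei_single_sweep(model, deltas = c(-10, -1, 3, 10), holding = h)
  # inhibition can only reduce peak depolarisation
  expect_true(all(sw$amplitude_mv <= e_only * 1.001))
  # widely separated IPSP barely affects the peak
  expect_lt(abs(sw$amplitude_mv[sw$delta == 10] - e_only) / e_only, 0.05)
  # zero IPSP weight restores the EPSP exactly
  sw0 <- run_ei_single_sweep(model, deltas = 0, holding = h, ipsp_scale = 0)
  expect_equal(sw0$amplitude_mv, e_only, tolerance = 1e-6)
  # maximal overlap is at least as suppressed as either extreme
  expect_lte(min(sw$amplitude_mv),
             min(sw$amplitude_mv[sw$delta %in% c(-10, 10)]))
})

test_that("trains fire, and disabling all synapses silences the model", {
  model <- default_model()
  h <- default_holding()
  tr <- run_train(model, train_protocol(include_ipsp = FALSE), holding = h)
  expect_gt(tr$n_aps, 2)
  none <- run_train(model, train_protocol(include_epsp = FALSE,
                                          include_ipsp = FALSE), holding = h)
  expect_equal(none$n_aps, 0)
  # zero IPSP scale collapses onto the EPSP-only result
  sc0 <- run_train(model, train_protocol(ei_latency = 2.8, ipsp_scale = 0),
                   holding = h)
  expect_equal(sc0$n_aps, tr$n_aps)
  expect_equal(sc0$first_ap_latency_ms, tr$first_ap_latency_ms,
               tolerance = 1e-6)
})

test_that("protocol presets load from the shipped YAML files", {
  path <- system.file("extdata", "protocols", package = "mocsyn")
  files <- list.files(path, pattern = "\\.yaml$")
  expect_true(all(c("control.yaml", "epsp_only.yaml", "ei_sweep.yaml",
                    "depression.yaml") %in% files))
  ctrl <- read_protocol_yaml(file.path(path, "control.yaml"))
  expect_s3_class(ctrl, "train_protocol")
  expect_equal(ctrl$ei_latency, 2.8)
  dep <- read_protocol_yaml(file.path(path, "depression.yaml"))
  expect_equal(dep$ipsp_scale, 0.51)
})
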