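#' Passive membrane properties of the MOC model
#'
#' @param ra Axial resistivity, Ohm cm.
#' @param cm Specific membrane capacitance, uF/cm^2.
#' @param temperature Simulation temperature, degrees C.  Channel rates are
#'   defined at 22 C and scaled by a Q10 of 3.
#' @return A list of class `moc_passive`.
#' @export
moc_passive <- function(ra = 210, cm = 1, temperature = 35) {
  stopifnot(ra > 0, cm > 0)
  structure(list(ra = ra, cm = cm, temperature = temperature),
            class = "moc_passive")
}

#' Channel densities of the MOC model
#'
#' Specifies conductance densities (S/cm^2) for the auditory-brainstem
#' channel set carried by the model: high-threshold K+ (`kht`), low-threshold
#' K+ (`klt`), fast transient Na+ (`na`), HCN (`ih`) and passive leak.  Each
#' density is given for the general membrane (`all`) with an optional `axon`
#' override, mirroring the two compartment groups of the model cell.
#'
#' `kbl_lt` scales the activation rate (1/tau) of the low-threshold K+
#' channel's fast gate.  Defaults are the calibrated densities that reproduce
#' the recorded MOC miniature and evoked PSP waveforms (see
#' [calibrate_model()]); the printed reference densities are available from
#' [moc_table_densities()].
#'
#' @param leak,kht,klt,na,ih Named numeric vectors, S/cm^2: an `all` entry
#'   plus optional `soma`, `axon` or `dendrite` overrides.
#' @param kbl_lt Multiplier on the low-threshold K+ activation rate.
#' @param na_mshift,na_hshift Voltage shifts (mV) of the Na+ activation and
#'   inactivation curves per compartment group; the axonal shifts (activation
#'   left, inactivation right) mimic the low-threshold axon-initial-segment
#'   Na+ isoform so that spikes initiate in the axon.
#' @param e_leak,e_k,e_na,e_h Reversal potentials, mV.
#' @return A list of class `moc_channels`.
#' @export
moc_channels <- function(leak = c(all = 1.84e-4),
                         kht = c(all = 0.0018, soma = 0.006, axon = 0.006),
                         klt = c(all = 1.5e-5),
                         na = c(all = 0.161),
                         ih = c(all = 5e-6),
                         kbl_lt = 1,
                         na_mshift = c(all = 0),
                         na_hshift = c(all = 0),
                         e_leak = -65, e_k = -90, e_na = 55, e_h = -38) {
  dens <- list(leak = leak, kht = kht, klt = klt, na = na, ih = ih)
  for (nm in names(dens)) {
    d <- dens[[nm]]
    if (!"all" %in% names(d)) abort(sprintf("channel '%s' needs an 'all' density", nm))
    bad <- setdiff(names(d), c("all", "soma", "axon", "dendrite"))
    if (length(bad) > 0) {
      abort(sprintf("channel '%s': unknown compartment group(s) %s", nm,
                    paste(bad, collapse = ", ")))
    }
    if (any(d < 0)) abort(sprintf("channel '%s' has a negative density", nm))
  }
  stopifnot(kbl_lt > 0)
  if (!"all" %in% names(na_mshift) || !"all" %in% names(na_hshift)) {
    abort("na_mshift and na_hshift need an 'all' entry")
  }
  structure(c(dens, list(kbl_lt = kbl_lt, na_mshift = na_mshift,
                         na_hshift = na_hshift,
                         e_leak = e_leak, e_k = e_k,
                         e_na = e_na, e_h = e_h)),
            class = "moc_channels")
}

#' Channel table as printed in the source description of the model
#'
#' The literal published density table for the modeled MOC neuron, kept for
#' reference next to the calibrated values actually used by
#' [moc_channels()].  Several printed units are typographically inconsistent
#' (cS, kS, nS per cm^2), which is why the working densities are treated as
#' free parameters fixed by calibration.
#'
#' @return A tibble with columns `channel`, `location`, `printed_value`.
#' @export
moc_table_densities <- function() {
  tibble::tribble(
    ~channel, ~location, ~printed_value,
    "High threshold K+", "all", "0.02 S/cm^2",
    "Low threshold K+", "all", "12 mS/cm^2",
    "Low threshold K+ activation rate (kbl_LT)", "all", "0.6 ms^-1",
    "HH-type Na+", "all", "8 nS/cm^2",
    "HCN", "all", "12 uS/cm^2",
    "High threshold K+", "axon", "0.32 mS/cm^2",
    "Low threshold K+", "axon", "6 cS/cm^2",
    "HH-type Na+", "axon", "9 kS/cm^2"
  )
}

#' Build the compartmental MOC neuron model
#'
#' Discretises a morphology into segments, attaches passive properties and
#' channel densities, and precomputes the quantities needed by the implicit
#' cable integrator.
#'
#' @param morphology A morphology tibble ([moc_morphology()]).
#' @param passive A [moc_passive()] object.
#' @param channels A [moc_channels()] object.
#' @return An object of class `moc_model`.
#' @examples
#' m <- build_model()
#' m$n_segments # 86 for the reference morphology
#' @export
build_model <- function(morphology = moc_morphology(),
                        passive = moc_passive(),
                        channels = moc_channels()) {
  stopifnot(inherits(passive, "moc_passive"), inherits(channels, "moc_channels"))
  segs <- segment_table(morphology, passive$ra, passive$cm)
  density_of <- function(d, group) {
    if (group %in% names(d)) unname(d[[group]]) else unname(d[["all"]])
  }
  gbar <- sapply(c("leak", "kht", "klt", "na", "ih"), function(ch) {
    vapply(segs$group, function(g) density_of(channels[[ch]], g), numeric(1)) *
      segs$area_cm2 * 1e6  # S -> uS
  })
  if (!is.matrix(gbar)) gbar <- matrix(gbar, nrow = 1,
                                       dimnames = list(NULL, names(gbar)))
  na_mshift <- vapply(segs$group,
                      function(g) density_of(channels$na_mshift, g),
                      numeric(1))
  na_hshift <- vapply(segs$group,
                      function(g) density_of(channels$na_hshift, g),
                      numeric(1))
  structure(list(
    morphology = morphology,
    passive = passive,
    channels = channels,
    segments = segs,
    n_segments = nrow(segs),
    gbar_us = gbar,
    na_mshift = unname(na_mshift),
    na_hshift = unname(na_hshift),
    q_rate = 3^((passive$temperature - 22) / 10),
    total_area_cm2 = sum(segs$area_cm2)
  ), class = "moc_model")
}

#' @export
print.moc_model <- function(x, ...) {
  cat("<moc_model>\n")
  cat(sprintf("  %d sections, %d segments, total area %.0f um^2\n",
              nrow(x$morphology), x$n_segments, x$total_area_cm2 * 1e8))
  cat(sprintf("  Ra %.0f Ohm cm, Cm %.1f uF/cm^2, %.0f C\n",
              x$passive$ra, x$passive$cm, x$passive$temperature))
  invisible(x)
}

#' Double-exponential conductance synapse
#'
#' Describes one synaptic conductance event
#' `g(t) = weight * N * (exp(-t/tau_decay) - exp(-t/tau_rise))`, with `N`
#' chosen so the peak conductance equals `weight` (the Exp2Syn convention).
#' If `tau_rise >= tau_decay` the two are swapped with a warning, since the
#' biexponential is symmetric under exchange up to sign.
#'
#' @param tau_rise,tau_decay Rise and decay time constants, ms.
#' @param weight Peak conductance, uS.
#' @param reversal Reversal potential, mV.
#' @param onset Onset time, ms.
#' @param section Section name at which the synapse is placed (default soma).
#' @return A tibble row describing the synapse.
#' @export
synapse_spec <- function(tau_rise, tau_decay, weight, reversal,
                         onset = 0, section = "soma") {
  stopifnot(tau_rise > 0, tau_decay > 0, weight >= 0)
  if (tau_rise >= tau_decay) {
    warn("tau_rise >= tau_decay; swapping the two time constants")
    tmp <- tau_rise; tau_rise <- tau_decay; tau_decay <- tmp
  }
  tibble::tibble(tau_rise = tau_rise, tau_decay = tau_decay, weight = weight,
                 reversal = reversal, onset = onset, section = section)
}

# Peak time and normalisation factor of the biexponential conductance.
biexp_peak_time <- function(tau_rise, tau_decay) {
  tau_decay * tau_rise / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

biexp_norm_factor <- function(tau_rise, tau_decay) {
  tp <- biexp_peak_time(tau_rise, tau_decay)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Evaluate a synapse's conductance waveform
#'
#' @param syn A synapse tibble from [synapse_spec()].
#' @param times Time points, ms.
#' @return Conductance in uS at `times` (summed over rows of `syn`).
#' @export
synapse_conductance <- function(syn, times) {
  g <- numeric(length(times))
  for (i in seq_len(nrow(syn))) {
    t <- times - syn$onset[i]
    active <- t > 0
    N <- biexp_norm_factor(syn$tau_rise[i], syn$tau_decay[i])
    g[active] <- g[active] + syn$weight[i] * N *
      (exp(-t[active] / syn$tau_decay[i]) - exp(-t[active] / syn$tau_rise[i]))
  }
  g
}

# Run the compiled integrator. `synapses` is a tibble (possibly empty);
# state0 may be NULL (gates initialised at v_init steady state).
run_cable <- function(model, synapses, duration, dt, i_bias_na = 0,
                      v_init = -60, state0 = NULL, record_all = FALSE) {
  segs <- model$segments
  n <- model$n_segments
  soma_seg <- which(segs$name == "soma")[1]
  if (is.null(synapses) || nrow(synapses) == 0) {
    syn <- matrix(numeric(0), ncol = 6)
  } else {
    seg_idx <- vapply(synapses$section, function(nm) {
      hit <- which(segs$name == nm)
      if (length(hit) == 0) abort(sprintf("no section named '%s'", nm))
      hit[length(hit)]
    }, numeric(1))
    syn <- cbind(seg_idx - 1,
                 synapses$onset,
                 synapses$tau_rise,
                 synapses$tau_decay,
                 synapses$weight *
                   mapply(biexp_norm_factor, synapses$tau_rise, synapses$tau_decay),
                 synapses$reversal)
  }
  ibias <- numeric(n)
  ibias[soma_seg] <- i_bias_na
  n_steps <- as.integer(round(duration / dt))
  ch <- model$channels
  res <- simulate_cable(
    parent = as.integer(segs$parent_seg - 1L),
    g_axial = segs$g_axial_us,
    cm = segs$cm_nf,
    gbar = model$gbar_us,
    e_leak = rep(ch$e_leak, n),
    e_k = ch$e_k, e_na = ch$e_na, e_h = ch$e_h,
    q_rate = model$q_rate, klt_wscale = ch$kbl_lt,
    na_mshift = model$na_mshift,
    na_hshift = model$na_hshift,
    syn = syn,
    i_bias = ibias,
    dt = dt, n_steps = n_steps, v_init = v_init,
    state0 = state0, record_all = record_all
  )
  res$time <- seq(0, by = dt, length.out = n_steps + 1)
  res
}

#' Find the holding current that rests the soma at a target potential
#'
#' Bisects on a constant somatic current until the steady-state somatic
#' voltage over the last 50 ms of a settling simulation is within
#' `tol` of `target` mV.
#'
#' @param model A [build_model()] object.
#' @param target Target somatic holding potential, mV.
#' @param tol Acceptable deviation, mV.
#' @param settle_ms Settling simulation length, ms.
#' @param dt Time step, ms.
#' @param max_iter Maximum bisection iterations.
#' @return A list of class `moc_holding` with the bias current (`bias_na`),
#'   the achieved voltage (`v_end`) and the full settled integrator state
#'   (`state`), reusable as the initial condition of protocol simulations.
#' @export
set_holding <- function(model, target = -60, tol = 0.1, settle_ms = 500,
                        dt = 0.025, max_iter = 100) {
  steady_v <- function(bias) {
    r <- run_cable(model, NULL, settle_ms, dt, i_bias_na = bias, v_init = target)
    tail_v <- r$v_soma[r$time >= settle_ms - 50]
    list(v = mean(tail_v), state = r$state)
  }
  lo <- -2; hi <- 2
  f_lo <- steady_v(lo); f_hi <- steady_v(hi)
  if ((f_lo$v - target) * (f_hi$v - target) > 0) {
    abort(sprintf("cannot bracket holding current; V in [%.1f, %.1f] mV",
                  f_lo$v, f_hi$v))
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- steady_v(mid)
    if (abs(f_mid$v - target) <= tol) {
      return(structure(list(bias_na = mid, v_end = f_mid$v, state = f_mid$state,
                            target = target, dt = dt), class = "moc_holding"))
    }
    if ((f_lo$v - target) * (f_mid$v - target) < 0) {
      hi <- mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  abort(sprintf("holding current did not converge in %d iterations (achieved %.2f mV)",
                max_iter, f_mid$v))
}

#' Simulate the model under a synaptic protocol
#'
#' Integrates the cable equation with the given synapses from the settled
#' holding state.
#'
#' @param model A [build_model()] object.
#' @param synapses Tibble of synapses ([synapse_spec()] rows); may be `NULL`.
#' @param duration Simulation length, ms.
#' @param holding A [set_holding()] result; computed on the fly if `NULL`.
#' @param dt Time step, ms (default 0.025).
#' @return An object of class `moc_sim` with `time`, `v_soma`, the synapse
#'   table and the holding used.
#' @export
simulate <- function(model, synapses = NULL, duration = 300,
                     holding = NULL, dt = 0.025) {
  stopifnot(inherits(model, "moc_model"))
  if (is.null(holding)) holding <- set_holding(model, dt = dt)
  res <- run_cable(model, synapses, duration, dt,
                   i_bias_na = holding$bias_na,
                   v_init = holding$target, state0 = holding$state)
  structure(list(time = res$time, v_soma = res$v_soma,
                 synapses = synapses, holding = holding, dt = dt),
            class = "moc_sim")
}

#' @export
print.moc_sim <- function(x, ...) {
  cat(sprintf("<moc_sim> %.0f ms, dt %.3f ms, %d synapses, V in [%.1f, %.1f] mV\n",
              max(x$time), x$dt,
              if (is.null(x$synapses)) 0L else nrow(x$synapses),
              min(x$v_soma), max(x$v_soma)))
  invisible(x)
}

#' @export
tidy.moc_sim <- function(x, ...) {
  tibble::tibble(time = x$time, v_soma = x$v_soma)
}

#' Measure amplitude and decay of a subthreshold PSP
#'
#' Amplitude is the extremum of (V - baseline) after `onset`; the decay time
#' constant comes from a single-exponential fit starting where the
#' relaxation falls below 90% of peak.
#'
#' @param sim A [simulate()] result.
#' @param onset Synaptic onset time, ms (baseline is measured before it).
#' @param window Measurement window after onset, ms.
#' @return A tibble with `amplitude_mv`, `decay_tau_ms`, `peak_time_ms`
#'   (relative to onset) and `baseline_mv`.
#' @export
measure_psp <- function(sim, onset = NULL, window = 150) {
  stopifnot(inherits(sim, "moc_sim"))
  if (is.null(onset)) {
    if (is.null(sim$synapses) || nrow(sim$synapses) == 0) {
      abort("no synapses in simulation; supply `onset` explicitly")
    }
    onset <- min(sim$synapses$onset)
  }
  apt <- detect_aps(sim)$ap_times[[1]]
  if (any(apt >= onset & apt <= onset + window)) {
    abort("action potential detected in the PSP window; use detect_aps() instead")
  }
  base_idx <- sim$time < onset & sim$time >= onset - 20
  if (!any(base_idx)) base_idx <- sim$time <= onset
  baseline <- mean(sim$v_soma[base_idx])
  sel <- sim$time >= onset & sim$time <= onset + window
  t <- sim$time[sel] - onset
  dv <- sim$v_soma[sel] - baseline
  ipk <- which.max(abs(dv))
  amplitude <- dv[ipk]
  # decay fit from the 90%-of-peak crossing on the relaxation; the window
  # is capped at 5 fitted tau (two-pass), as in the event-level decay fits
  after <- seq(ipk, length(dv))
  rel <- abs(dv[after]) / abs(amplitude)
  start <- after[which(rel <= 0.9)[1]]
  decay_tau <- NA_real_
  if (!is.na(start) && length(dv) - start >= 3) {
    seg <- abs(dv[start:length(dv)])
    decay_tau <- fit_decay_tau(seg, dt = sim$dt)
    for (pass in 1:2) {
      if (is.na(decay_tau)) break
      end <- min(length(seg), ceiling(5 * decay_tau / sim$dt))
      if (end >= 3) decay_tau <- fit_decay_tau(seg[1:end], dt = sim$dt)
    }
  }
  tibble::tibble(amplitude_mv = amplitude, decay_tau_ms = decay_tau,
                 peak_time_ms = t[ipk], baseline_mv = baseline)
}

#' Detect action potentials in a simulated voltage trace
#'
#' An AP is an upward crossing of `threshold` separated from the previous
#' one by at least `refractory`.  The firing rate is reported two ways:
#' `rate_span_hz = (N - 1) / (t_last - t_first)` (primary) and
#' `rate_window_hz = N / window` where `window` spans from the first
#' synaptic onset (or 0) to the end of the trace.
#'
#' @param sim A [simulate()] result, or a list with `time` and `v_soma`.
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum separation between APs, ms.
#' @param t_ref Reference time for first-AP latency, ms (defaults to the
#'   first synaptic onset, else 0).
#' @return A tibble with `n_aps`, `first_ap_latency_ms`, `rate_span_hz`,
#'   `rate_window_hz` and a list column `ap_times`.
#' @export
detect_aps <- function(sim, threshold = -10, refractory = 1, t_ref = NULL) {
  v <- sim$v_soma
  t <- sim$time
  if (any(is.na(v))) abort("voltage trace contains NA")
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  ap_times <- numeric(0)
  for (i in up) {
    if (length(ap_times) == 0 || t[i] - ap_times[length(ap_times)] >= refractory) {
      ap_times <- c(ap_times, t[i])
    }
  }
  if (is.null(t_ref)) {
    t_ref <- if (!is.null(sim$synapses) && NROW(sim$synapses) > 0) {
      min(sim$synapses$onset)
    } else 0
  }
  n <- length(ap_times)
  window <- max(t) - t_ref
  structure(tibble::tibble(
    n_aps = n,
    first_ap_latency_ms = if (n > 0) ap_times[1] - t_ref else NA_real_,
    rate_span_hz = if (n >= 2) 1000 * (n - 1) / (ap_times[n] - ap_times[1]) else NA_real_,
    rate_window_hz = 1000 * n / window,
    ap_times = list(ap_times)
  ), ap_times = ap_times)
}
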