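#' Initial neuron state
#'
#' The model starts at rest: membrane potential at `V_rest`, no synaptic
#' perturbation and no afterpotential activation.
#'
#' @param params a valid [neuron_params()] set.
#' @return A `neuron_state` list with fields `V`, `V_syn`, `hap`, `dap`,
#'   `ahp` (mV, all magnitudes) and `t` (s).
#' @export
init_state <- function(params) {
  validate_neuron_params(params)
  structure(list(V = params$V_rest, V_syn = 0, hap = 0, dap = 0, ahp = 0,
                 t = 0),
            class = "neuron_state")
}

#' Advance the neuron by one integration step
#'
#' Applies one fixed step of the modified integrate-and-fire update given
#' the PSP counts arriving in the step: the previous synaptic perturbation
#' decays by its half-life factor `2^(-dt/lambda_syn)` and this step's PSPs
#' are added at full amplitude; the afterpotentials decay by their half-life
#' factors; the membrane potential `V = V_rest + V_syn - hap - ahp + dap` is
#' tested against threshold; on a spike the afterpotentials are incremented
#' by their `k` values. There is no explicit membrane reset - the HAP
#' provides refractoriness.
#'
#' This is the reference single-step implementation; [simulate_neuron()]
#' runs the identical update in compiled code.
#'
#' @param state a `neuron_state`.
#' @param params a valid [neuron_params()] set.
#' @param dt step size (ms).
#' @param n_epsp,n_ipsp numbers of excitatory and inhibitory PSPs arriving
#'   in this step.
#' @return A list with elements `state` (the new `neuron_state`) and
#'   `spiked` (logical).
#' @export
step_neuron <- function(state, params, dt = 1, n_epsp = 0, n_ipsp = 0) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (n_epsp < 0 || n_ipsp < 0) stop("PSP counts must be >= 0")
  state$V_syn <- state$V_syn * 2^(-dt / params$lambda_syn) +
    n_epsp * params$e_h + n_ipsp * params$i_h
  state$hap <- state$hap * 2^(-dt / params$lambda_HAP)
  state$dap <- state$dap * 2^(-dt / params$lambda_DAP)
  state$ahp <- state$ahp * 2^(-dt / params$lambda_AHP)
  state$V <- params$V_rest + state$V_syn - state$hap - state$ahp + state$dap
  spiked <- state$V >= params$V_thresh
  if (spiked) {
    state$hap <- state$hap + params$k_HAP
    state$dap <- state$dap + params$k_DAP
    state$ahp <- state$ahp + params$k_AHP
  }
  state$t <- state$t + dt / 1000
  list(state = state, spiked = spiked)
}

#' Simulate a model neuron under an input protocol
#'
#' Integrates the modified integrate-and-fire model with a fixed step
#' (1 ms by default). Excitatory and inhibitory PSP counts per step are
#' independent Poisson draws with means `I_re(t) * dt` and
#' `I_ratio * I_re(t) * dt`, where `I_re(t)` follows the protocol schedule.
#' All decays use exact per-step half-life factors `2^(-dt/lambda)`.
#' Runs are reproducible given `seed`.
#'
#' @param params a valid [neuron_params()] set.
#' @param protocol an [input_protocol()].
#' @param seed integer RNG seed, or `NULL` to continue the session stream.
#' @param dt step size (ms).
#' @param label label for the returned train.
#' @return A [spike_train()] spanning the protocol duration.
#' @examples
#' tr <- simulate_neuron(consensus_neuron_params(),
#'                       constant_protocol(370, 60), seed = 1)
#' mean_rate(tr)
#' @export
simulate_neuron <- function(params, protocol, seed = NULL, dt = 1,
                            label = "") {
  validate_neuron_params(params)
  if (!inherits(protocol, "input_protocol")) {
    stop("protocol must be an input_protocol")
  }
  segs <- as.matrix(protocol[, c("duration", "rate", "slope")])
  times <- with_seed(seed, .sim_protocol_cpp(
    segs, params$I_ratio, params$e_h, params$i_h, params$lambda_syn,
    params$k_HAP, params$lambda_HAP, params$k_DAP, params$lambda_DAP,
    params$k_AHP, params$lambda_AHP, params$V_rest, params$V_thresh, dt))
  spike_train(times, protocol_duration(protocol), label = label)
}

# Pure-R simulator used to cross-validate the compiled kernel on short
# runs. Draws PSP counts in the same order (excitatory then inhibitory per
# step) so that, for the same seed, it must reproduce the kernel exactly.
simulate_neuron_r <- function(params, protocol, seed = NULL, dt = 1) {
  validate_neuron_params(params)
  segs <- as.matrix(protocol[, c("duration", "rate", "slope")])
  dt_s <- dt / 1000
  with_seed(seed, {
    state <- init_state(params)
    spikes <- numeric(0)
    t0 <- 0
    for (s in seq_len(nrow(segs))) {
      nsteps <- round(segs[s, 1] / dt_s)
      for (i in seq_len(nsteps)) {
        rate <- max(0, segs[s, 2] + segs[s, 3] * ((i - 1) * dt_s))
        ne <- rpois(1, rate * dt_s)
        ni <- rpois(1, params$I_ratio * rate * dt_s)
        res <- step_neuron(state, params, dt, ne, ni)
        state <- res$state
        if (res$spiked) spikes <- c(spikes, t0 + i * dt_s)
      }
      t0 <- t0 + nsteps * dt_s
    }
    spike_train(spikes, protocol_duration(protocol))
  })
}
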