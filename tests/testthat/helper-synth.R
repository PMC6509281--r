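# shared synthetic fixtures, generated once per test run
.fixtures <- new.env(parent = emptyenv())

fixture_session <- function(duration = 120, seed = 7, coupling_gain = 0,
                            voltage = FALSE) {
  key <- paste(duration, seed, coupling_gain, voltage, sep = "_")
  if (is.null(.fixtures[[key]])) {
    p <- synth_params(coupling_gain = coupling_gain)
    .fixtures[[key]] <- generate_session(p, duration = duration, seed = seed,
                                         voltage_traces = voltage)
  }
  .fixtures[[key]]
}

# boundary error: distance from each true state boundary to the nearest
# detected one
boundary_errors <- function(true_seg, est_seg) {
  tb <- sort(c(true_seg$start, true_seg$end))
  tb <- tb[c(-1, -length(tb))]
  eb <- sort(c(est_seg$start, est_seg$end))
  vapply(tb, function(b) min(abs(eb - b)), numeric(1))
}

# sample-wise UP/DOWN agreement, ignoring indeterminate samples on either side
label_agreement <- function(true_seg, est_seg, rate = 1000) {
  tt <- seq(min(true_seg$start), max(true_seg$end) - 1 / rate, by = 1 / rate)
  truth <- state_at(true_seg, tt)
  est <- state_at(est_seg, tt)
  m <- !is.na(truth) & truth != "INDET" & !is.na(est) & est != "INDET"
  mean(truth[m] == est[m])
}
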