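# Shared fixtures: base parameter set constructor and an independent
# path-enumeration oracle for the cohort engine.

# Base case with optional base-value tweaks, validation warnings silenced
# (the shipped wastage range anomaly is asserted explicitly where relevant).
bp <- function(...) {
  p <- load_parameters(quiet = TRUE)
  mods <- list(...)
  for (nm in names(mods)) p <- set_param(p, nm, mods[[nm]])
  p
}

# Exhaustive path-enumeration oracle: occupancy at cycle c is the sum, over
# every explicit state path of length c starting in state 1 (HEALTHY), of
# n0 times the product of step transition probabilities. Independent of the
# matrix-power recursion used by run_cohort.
enum_occupancy <- function(m, n0, cycles) {
  ns <- nrow(m)
  occ <- matrix(0, cycles + 1, ns, dimnames = list(0:cycles, rownames(m)))
  occ[1, 1] <- n0
  for (cc in seq_len(cycles)) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), cc)))
    for (i in seq_len(nrow(paths))) {
      pr <- n0
      cur <- 1L
      for (step in seq_len(cc)) {
        nxt <- paths[i, step]
        pr <- pr * m[cur, nxt]
        cur <- nxt
      }
      occ[cc + 1, cur] <- occ[cc + 1, cur] + pr
    }
  }
  occ
}

# Random in-range parameter draws for property tests.
draw_sets <- function(n, seed = 42L) {
  sample_parameter_sets(scenario_spec(seed = seed, n_scenarios = n),
                        bp())
}
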