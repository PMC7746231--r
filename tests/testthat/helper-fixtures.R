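# shared fixtures: one canonical structure + test sets, built once per run
fx_structure <- build_structure(seed = 1)
fx_sets <- build_test_sets(fx_structure, seed = 2)

fx_training_A <- function() {
  s <- fx_structure$training
  as.matrix(s[s$category == "A", paste0("f", 1:8)])
}

fx_training_B <- function() {
  s <- fx_structure$training
  as.matrix(s[s$category == "B", paste0("f", 1:8)])
}

# attention-weight profile of a "strong" (late-learning) synthetic observer:
# unequal attention across features, near-deterministic choices
fx_strong_w <- c(0.2, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05, 0.05)
fx_strong_c <- 10

# simulate one observer and return one phase's trials
fx_observer_trials <- function(strategy, phase = "final", c = fx_strong_c,
                               w = fx_strong_w, seed = 1) {
  spec <- observer_spec(strategy, w = w, c = c, seed = seed)
  tr <- simulate_responses(spec, fx_sets, fx_structure)
  tr[tr$phase == phase, ]
}

# naive per-feature / per-exemplar loop oracles, deliberately scalar
oracle_proto_sim <- function(x, proto, w, c) {
  d <- 0
  for (i in 1:8) d <- d + w[i] * abs(x[i] - proto[i])
  unname(exp(-c * d))
}

oracle_exem_sim <- function(x, exemplars, w, c) {
  s <- 0
  for (e in seq_len(nrow(exemplars))) {
    d <- 0
    for (i in 1:8) d <- d + w[i] * abs(x[i] - exemplars[e, i])
    s <- s + exp(-c * d)
  }
  unname(s)
}
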