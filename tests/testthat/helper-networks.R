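# Shared fixtures: small simulation configs and state-set comparison helpers.

# canonical string set for a matrix of states (rows), order-independent
state_set <- function(states) {
  if (nrow(states) == 0) return(character(0))
  sort(apply(states, 1, paste, collapse = ","))
}

# quick config for tests that only need the support, not tight frequencies
quick_config <- function(seed = 1, n_init = 2000, reps = 2)
  sim_config(n_init = n_init, max_steps = 1000, n_replicates = reps,
             seed = seed)

expect_same_states <- function(a, b) expect_identical(state_set(a), state_set(b))
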