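# shared tiny models used across test files

# single free node flipping both ways: X's rule is its own negation, so the
# target always differs from the current value -> a two-state CTMC with
# rates (k_up, k_down)
free_node_model <- function(k_up = 1, k_down = 1, istate = 0) {
  model <- parse_bnd("node X { logic = !X; }")
  settings <- default_settings(model)
  settings$nodes$k_up <- k_up
  settings$nodes$k_down <- k_down
  settings$nodes$istate <- istate
  list(model = model, settings = settings)
}

# all 2^n complete states of a model, as a named-list iterator helper
all_states <- function(model) {
  n <- length(model$nodes)
  keys <- 0:(2^n - 1)
  m <- vapply(seq_len(n), function(i) (keys %/% 2^(i - 1)) %% 2, numeric(2^n))
  colnames(m) <- model$nodes
  m
}
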