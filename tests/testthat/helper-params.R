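# Loaded once per test run.
BASE_PARAMS <- load_parameters(cea_base_case())

# Parameter set whose only live state is NYHA I with a constant monthly
# death probability -- the single-transient-state chain with geometric
# survival used by the closed-form checks.
single_state_params <- function(p_death, omt_monthly = NULL,
                                discount = NULL, half_cycle = NULL) {
  p <- BASE_PARAMS
  m <- matrix(0, 5, 5, dimnames = list(
    c("nyha1", "nyha2", "nyha3", "nyha4", "dead"),
    c("nyha1", "nyha2", "nyha3", "nyha4", "dead")
  ))
  m["nyha1", "nyha1"] <- 1 - p_death
  m["nyha1", "dead"] <- p_death
  for (s in c("nyha2", "nyha3", "nyha4")) m[s, s] <- 1
  m["dead", "dead"] <- 1
  p$transitions$mitraclip <- m
  p$transitions$omt <- m
  for (arm in c("mitraclip", "omt")) {
    p$decision_tree$initial_distribution[[arm]] <-
      c(nyha1 = 1, nyha2 = 0, nyha3 = 0, nyha4 = 0)
  }
  if (!is.null(omt_monthly)) p$costs$omt_monthly <- omt_monthly
  if (!is.null(discount)) p$econ$annual_discount_rate <- discount
  if (!is.null(half_cycle)) p$model$half_cycle_correction <- half_cycle
  p
}

# Random valid transition matrix: Dirichlet-style rows over the five states
# with absorbing death.
random_transition_matrix <- function() {
  m <- matrix(0, 5, 5)
  for (i in 1:4) {
    g <- rgamma(5, shape = c(1, 1, 1, 1, 0.3))
    m[i, ] <- g / sum(g)
  }
  m[5, 5] <- 1
  dimnames(m) <- list(c("nyha1", "nyha2", "nyha3", "nyha4", "dead"),
                      c("nyha1", "nyha2", "nyha3", "nyha4", "dead"))
  m
}

random_simplex <- function(k = 5) {
  g <- rgamma(k, 1)
  g / sum(g)
}
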