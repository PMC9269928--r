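# Shared fixtures: one model instance per test run, plus small helpers
# used across files.

the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- smad_model()
    m
  }
})

# detection settings known to resolve the synthetic benchmark's bursts
bench_detection <- function() {
  detection_config(height_threshold = 0.05, burst_bandwidth = 35,
                   trend_bandwidth = 180, duration_bounds = c(75, 430))
}

# internalization noise in the clip-free (Feller-satisfied) regime
mild_internalization <- function(model = the_model()) {
  noise_block(model, "internalization",
              sigma = c(0.01, 0.04, 0.02), theta = 0.02)
}

# SMAD2 stoichiometry weights of the shipped network (monomers 1,
# heterotrimer 2, homotrimer 3), by species name
smad2_weights <- function(model = the_model()) {
  w <- stats::setNames(numeric(model$n_species), model$species)
  w[c("S2c", "pS2c", "pS2n", "S2n")] <- 1
  w[c("T2c", "T2n")] <- 2
  w[c("T3c", "T3n")] <- 3
  w
}

random_state <- function(model = the_model()) {
  stats::runif(model$n_species, 0, 2)
}
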