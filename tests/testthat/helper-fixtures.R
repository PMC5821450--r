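# Shared analytic fixtures for the test suite. Everything is generated in
# code; no stored data.

# A smooth single-humped vertical profile and braking-propulsion couplet on a
# uniform stance grid.
analytic_profiles <- function(n = 1001) {
  t <- seq(0, 1, length.out = n)
  list(t = t, fz = sin(pi * t), fx = -0.2 * sin(2 * pi * t))
}

# Random sine coefficient sets with decaying magnitude, reproducible.
random_sine_coeffs <- function(n_harm = 10, seed = 1) {
  set.seed(seed)
  stats::rnorm(n_harm, 0, 1 / seq_len(n_harm))
}

# Brute-force oracle for stance detection: first/last index of the longest
# run above threshold, by direct enumeration.
stance_oracle <- function(fz, threshold) {
  above <- which(fz > threshold)
  if (!length(above)) return(NULL)
  breaks <- c(0, which(diff(above) > 1), length(above))
  runs <- lapply(seq_len(length(breaks) - 1), function(i)
    above[(breaks[i] + 1):breaks[i + 1]])
  lens <- vapply(runs, length, integer(1))
  r <- runs[[which.max(lens)]]
  c(touchdown = r[1], liftoff = r[length(r)])
}

# Twelve synthetic species spanning the study's mass range on a log scale.
synthetic_species <- function() {
  data.frame(species = paste0("sp", 1:12),
             mass_kg = 10^seq(log10(0.05), log10(75), length.out = 12))
}
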