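# Shared fixtures: all data is generated in code at test time.

# Narrow network configuration used wherever a test only needs the
# architecture's behaviour, not its clinical-scale capacity.
slim_config <- function(...) {
  net_config(widths = c(4L, 8L, 16L, 32L, 32L), ...)
}

tiny_config <- function(...) {
  net_config(widths = c(2L, 3L, 4L, 5L, 5L), ...)
}

# A small in-memory phantom training set of one tissue.
phantom_set <- function(n, tissue = "eyeball", size = 64L, seed = 100L,
                        plane = "axial1", spec = phantom_spec(image_size = size)) {
  sls <- simulate(spec, nsim = n, seed = seed, plane = plane)
  list(images = lapply(sls, function(s) s$image$hu),
       masks = lapply(sls, function(s) s$masks[[tissue]]))
}

# Brute-force 2x2 max pooling oracle: plain window scan over a matrix,
# independent of the C++ kernel.
pool_oracle <- function(m) {
  ho <- nrow(m) / 2; wo <- ncol(m) / 2
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    out[i, j] <- max(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  out
}

with_seed_rnorm <- function(n, seed = 1L) {
  set.seed(seed)
  rnorm(n)
}
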