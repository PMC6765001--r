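# Small fixtures shared across test files; everything is generated in code.

small_expr_config <- function(n_genes = 200, noise_sd = 0, seed = 42, ...) {
  expr_sim_config(n_genes = n_genes, noise_sd = noise_sd, seed = seed, ...)
}

# a tiny signal_matrix built by hand: `days` named vector day -> replicates
toy_signal_matrix <- function(values, days, fraction = "tissue",
                              compartment = "cortex") {
  samples <- tibble::tibble(
    sample = colnames(values),
    compartment = compartment, fraction = fraction,
    day = rep(names(days), days),
    replicate = unlist(lapply(days, seq_len), use.names = FALSE))
  signal_matrix(values, samples)
}

# digitized ball mask: voxel centres within `radius` of the centre
ball_mask <- function(radius_vox, spacing = c(1, 1, 1), pad = 2) {
  n <- 2 * (radius_vox + pad) + 1
  ctr <- (n - 1) / 2
  co <- lapply(1:3, function(k) ((seq_len(n) - 1) - ctr) * spacing[k])
  Z <- rep(co[[1]], times = n * n)
  Y <- rep(rep(co[[2]], each = n), times = n)
  X <- rep(co[[3]], each = n * n)
  array(Z^2 + Y^2 + X^2 <= radius_vox^2, c(n, n, n))
}

cube_mask <- function(side_vox, pad = 2) {
  n <- side_vox + 2 * pad
  m <- array(FALSE, c(n, n, n))
  idx <- (pad + 1):(pad + side_vox)
  m[idx, idx, idx] <- TRUE
  m
}

# toy gene universe and sets for enrichment tests
toy_collection <- function(n_universe = 100, seed = 7) {
  withr::with_seed(seed, {
    universe <- sprintf("g%03d", seq_len(n_universe))
    sets <- list(
      projection_assembly = sample(universe, 20),
      cell_projection_organization = sample(universe, 15),
      small_projection_set = sample(universe, 9),
      lipid_metabolism = sample(universe, 25),
      mTOR_signalling = sample(universe, 12),
      ERK_signaling_cascade = sample(universe, 30)
    )
    gene_set_collection(sets, universe)
  })
}
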