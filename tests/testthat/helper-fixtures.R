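# Shared fixtures, built in code. Kept tiny: full-size cohorts are
# generated inside the tests that need them.

# deterministic small spectra block (no simulator involvement)
toy_block <- function(n = 6, p = 40, seed = 42) {
  set.seed(seed)
  grid <- seq(9000, 5000, length.out = p)
  X <- matrix(rnorm(n * p, mean = 1, sd = 0.2), n, p)
  spectra_block(X, grid,
                sample_id = sprintf("F%02d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]),
                cultivar = rep("A", n),
                replicate = rep(c(1L, 2L), length.out = n))
}

# two-cultivar profiles with well-separated means (for fast classification
# tests); variability small enough that classes are separable
sep_profiles <- function(cv = 0.05) {
  list(hi = cultivar_profile("Hi", c(ssc = 9, ta = 0.9, vitc = 40, acy = 50, phen = 30),
                             lab_cvs = rep(cv, 5)),
       lo = cultivar_profile("Lo", c(ssc = 5, ta = 0.4, vitc = 12, acy = 90, phen = 20),
                             lab_cvs = rep(cv, 5)))
}

# small full cohort for pipeline-level tests (coarse grid keeps it fast)
small_cohort <- function(seed = 11, n_per_cultivar = 14, n_missing = 3,
                         grid = c(10000, 4000, 181), separation = 1) {
  panel <- generate_lab_panel(n_per_cultivar = n_per_cultivar,
                              seed = derive_seed(seed, 1L))
  spectra <- generate_spectra(panel, grid_spec = grid,
                              band_model = default_band_model(separation),
                              seed = derive_seed(seed, 2L))
  panel <- inject_missing(panel, n_missing, seed = derive_seed(seed, 3L))
  list(panel = panel, spectra = spectra)
}
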