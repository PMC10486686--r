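test_that("lab panel generation is reproducible and respects the profile", {
  p1 <- generate_lab_panel(n_per_cultivar = 30, seed = 5)
  p2 <- generate_lab_panel(n_per_cultivar = 30, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 120)
  expect_equal(unname(table(p1$cultivar)["Romina"]), 30, ignore_attr = TRUE)
  expect_true(all(lab_values(p1) >= 0))
  expect_setequal(unique(p1$harvest), 1:2)

  # degenerate distribution: zero CVs reproduce the means exactly
  prof0 <- default_profiles(cv = 0)
  p0 <- generate_lab_panel(prof0, n_per_cultivar = 4, seed = 1)
  v <- lab_values(p0)[p0$cultivar == "Sibilla", ]
  expect_equal(unname(v), matrix(rep(prof0$Sibilla$lab_means, each = 4), 4),
               tolerance = 1e-12)
})

test_that("generated correlations match the empirical-correlation oracle", {
  prof <- list(cultivar_profile("X", c(ssc = 7, ta = 0.7, vitc = 30, acy = 50, phen = 25),
                                lab_cvs = rep(0.12, 5),
                                lab_corr = default_lab_corr(ssc_ta = 0.8)))
  p <- generate_lab_panel(prof, n_per_cultivar = 10000, seed = 1)
  v <- lab_values(p)
  expect_lt(abs(cor(v[, "ssc"], v[, "ta"]) - 0.8), 0.05)
  expect_lt(abs(cor(v[, "vitc"], v[, "acy"])), 0.05)
})

test_that("cultivar rank order of generated means matches the profiles", {
  profs <- default_profiles()
  p <- generate_lab_panel(profs, n_per_cultivar = 1000, seed = 3)
  v <- lab_values(p)
  for (par in lab_params()) {
    gen <- vapply(split(v[, par], p$cultivar), mean, 0)
    tru <- vapply(profs, function(pr) pr$lab_means[par], 0)
    names(tru) <- names(profs)
    expect_identical(names(sort(gen)), names(sort(tru[names(gen)])),
                     info = par)
  }
})

test_that("spectra have the reference geometry and are reproducible", {
  panel <- generate_lab_panel(n_per_cultivar = 54, seed = 2)
  sp <- generate_spectra(panel, seed = 9)
  expect_equal(dim(sp), c(432L, 1557L))
  expect_length(sp$grid, 1557)
  expect_equal(sp$grid[1], 10000)
  expect_equal(sp$grid[1557], 4000)
  expect_true(all(diff(sp$grid) < 0))
  expect_true(all(table(sp$sample_id) == 2))
  expect_identical(sp, generate_spectra(panel, seed = 9))
})

test_that("noise-free identical fruits give identical spectra", {
  df <- data.frame(sample_id = c("a", "b"), cultivar = "X", harvest = 1L,
                   ssc = 7, ta = 0.7, vitc = 30, acy = 50, phen = 25)
  bm <- default_band_model()
  bm$water_sd <- 0
  sp <- generate_spectra(lab_panel(df), band_model = bm,
                         scatter = c(0, 0), noise_sd = 0, seed = 1)
  expect_equal(sp$X[1, ], sp$X[3, ], tolerance = 1e-14)
  expect_equal(sp$X[1, ], sp$X[2, ], tolerance = 1e-14)  # replicates too
})

test_that("band links propagate composition into the spectra", {
  prof <- list(cultivar_profile("X", c(ssc = 7, ta = 0.7, vitc = 30, acy = 50, phen = 25),
                                lab_cvs = rep(0.15, 5), lab_corr = diag(5)))
  panel <- generate_lab_panel(prof, n_per_cultivar = 1000, seed = 4)
  bm <- default_band_model()
  bm$water_sd <- 0
  bm$links[] <- 0
  bm$links["6860", "ssc"] <- 0.02
  sp <- generate_spectra(panel, band_model = bm, scatter = c(0, 0),
                         noise_sd = 0, seed = 1)
  peak <- which.min(abs(sp$grid - 6860))
  reps1 <- sp$replicate == 1L
  expect_gt(cor(lab_values(panel)[, "ssc"], sp$X[reps1, peak]), 0.99)
})

test_that("separation scaling widens between-cultivar contrast only", {
  panel <- generate_lab_panel(n_per_cultivar = 14, seed = derive_seed(2, 1L))
  gs <- c(10000, 4000, 121)
  sp1 <- generate_spectra(panel, gs, default_band_model(1), seed = derive_seed(2, 2L))
  sp5 <- generate_spectra(panel, gs, default_band_model(5), seed = derive_seed(2, 2L))
  peak <- which.min(abs(sp1$grid - 5188))
  grp <- function(sp) {
    pairs <- ifelse(sp$cultivar %in% c("Romina", "Sibilla"), "RS", "SC")
    tapply(sp$X[, peak], pairs, mean)
  }
  d1 <- diff(grp(sp1)); d5 <- diff(grp(sp5))
  expect_gt(abs(d5), 3 * abs(d1))
  # within-pair spread is untouched by the separation dial
  rs1 <- sd(sp1$X[sp1$cultivar == "Romina", peak])
  rs5 <- sd(sp5$X[sp5$cultivar == "Romina", peak])
  expect_equal(rs5, rs1, tolerance = 0.5)
})

test_that("missing injection hits exactly the requested fruits", {
  panel <- generate_lab_panel(n_per_cultivar = 54, seed = 2)
  pm <- inject_missing(panel, 19, seed = 7)
  expect_equal(sum(rowSums(missing_mask(pm)) > 0), 19)
  expect_equal(nrow(complete_panel(pm)), 197)
  untouched <- rowSums(missing_mask(pm)) == 0
  expect_equal(lab_values(pm)[untouched, ], lab_values(panel)[untouched, ])

  expect_identical(inject_missing(panel, 0), panel)

  all_masked <- inject_missing(panel, nrow(panel), seed = 1)
  expect_equal(nrow(complete_panel(all_masked)), 0)
  sp <- generate_spectra(panel, grid_spec = c(10000, 4000, 61), seed = 1)
  expect_error(join_blocks(sp, all_masked), "complete-case")
})

test_that("generator argument errors are caught", {
  expect_error(generate_lab_panel(n_per_cultivar = 0), ">= 1")
  expect_error(inject_missing(generate_lab_panel(n_per_cultivar = 3, seed = 1), -1),
               "non-negative")
  badR <- default_lab_corr(); badR[1, 2] <- badR[2, 1] <- 2
  expect_error(cultivar_profile("x", rep(1, 5), lab_corr = badR),
               "positive semi-definite")
  panel <- generate_lab_panel(n_per_cultivar = 3, seed = 1)
  pm <- inject_missing(panel, 12, seed = 1)
  if (any(is.na(lab_values(pm)[, "ssc"]) | is.na(lab_values(pm)[, "ta"]) |
            is.na(lab_values(pm)[, "vitc"])))
    expect_error(generate_spectra(pm, grid_spec = c(10000, 4000, 31)),
                 "band-linked")
  bm <- default_band_model()
  bm$bands$center[3] <- 20000
  expect_warning(generate_spectra(panel, grid_spec = c(10000, 4000, 31),
                                  band_model = bm), "outside grid")
})
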