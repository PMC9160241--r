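test_that("phantom generation is deterministic and respects HU contrast", {
  ph1 <- generate_phantom(phantom_spec(seed = 42))
  ph2 <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(ph1$volume$hu, ph2$volume$hu)
  expect_identical(ph1$truth$labels, ph2$truth$labels)
  expect_false(identical(ph1$volume$hu,
                         generate_phantom(phantom_spec(seed = 43))$volume$hu))
  # 7-sigma margin: essentially all lung voxels are air-like, heart tissue-like
  lung_hu <- ph1$volume$hu[ph1$truth$labels == 2L]
  heart_hu <- ph1$volume$hu[ph1$truth$labels == 1L]
  expect_gt(mean(lung_hu < -400), 0.997)
  expect_gt(mean(heart_hu > -400), 0.997)
})

test_that("rasterized organ volumes match analytic ellipsoid volumes", {
  ph <- generate_phantom(phantom_spec(noise_sd = 20, seed = 1))
  vox <- prod(phantom_spec()$spacing)
  for (organ in list(list(code = 1L, semi = phantom_spec()$heart$semi),
                     list(code = 2L, semi = phantom_spec()$lungs$semi))) {
    analytic <- 4 / 3 * pi * prod(organ$semi)
    if (organ$code == 2L) analytic <- 2 * analytic # two lungs
    rasterized <- sum(ph$truth$labels == organ$code) * vox
    expect_lt(abs(rasterized - analytic) / analytic, 0.05)
  }
})

test_that("degenerate and invalid phantom geometry is handled", {
  spec <- phantom_spec()
  spec$heart$semi <- c(0, 0, 0)
  ph <- generate_phantom(spec)
  expect_identical(sum(ph$truth$labels == 1L), 0L)
  spec2 <- phantom_spec()
  spec2$heart$center <- spec2$lungs$center[1, ] # move heart onto a lung
  expect_error(generate_phantom(spec2), "overlap")
  expect_error(phantom_spec(lungs = list(center = rbind(c(-16, -4, 0), c(16, -4, 0)),
                                         semi = c(9, 12.5, 27),
                                         hu_mean = -100, hu_sd = 10)),
               "lung HU mean")
})

test_that("chest interval in ground truth is the minimal lung-slice cover", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  ci <- ph$truth$chest_interval
  lung_slices <- which(apply(ph$truth$labels == 2L, 3, any))
  expect_identical(ci, c(min(lung_slices) - 1L, max(lung_slices)))
})

test_that("simulated pedigrees count and order correctly", {
  # founders only
  ped0 <- simulate_pedigree(sim_pedigree_spec(2, 1, 0, 4, seed = 1))
  expect_identical(nrow(ped0), 4L)
  expect_true(all(ped0$sire == 0 & ped0$dam == 0))
  # 2/sex-year, 3 years, 2 litters x 4 progeny: litters in years 2 and 3
  ped <- simulate_pedigree(sim_pedigree_spec(2, 3, 2, 4, seed = 1))
  expect_identical(nrow(ped), 2L * 2L * 3L + 2L * 4L * 2L)
  # topological order for several seeds
  for (s in 1:5) {
    p <- simulate_pedigree(sim_pedigree_spec(3, 4, 5, 3, seed = s))
    idx <- stats::setNames(seq_len(nrow(p)), p$animal)
    si <- ifelse(p$sire == 0, 0L, idx[as.character(p$sire)])
    di <- ifelse(p$dam == 0, 0L, idx[as.character(p$dam)])
    expect_true(all(si < seq_len(nrow(p))) && all(di < seq_len(nrow(p))))
    expect_true(all(p$birth_year[si[si > 0]] < p$birth_year[si > 0]))
  }
})

test_that("gene dropping reproduces the additive model", {
  ped <- simulate_pedigree(sim_pedigree_spec(20, 4, 60, 5, seed = 2))
  vars <- cors <- slopes <- c()
  for (s in 1:10) {
    a <- gene_drop(ped, matrix(0.35), seed = s)
    founders <- ped$sire == 0 & ped$dam == 0
    vars <- c(vars, var(a[founders, 1]))
    # regression of offspring on mid-parent
    off <- which(!founders)
    idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
    mp <- (a[idx[as.character(ped$sire[off])], 1] +
             a[idx[as.character(ped$dam[off])], 1]) / 2
    slopes <- c(slopes, coef(lm(a[off, 1] ~ mp))[2])
    G <- matrix(c(1, -0.48, -0.48, 1), 2)
    a2 <- gene_drop(ped, G, seed = s)
    cors <- c(cors, cor(a2[founders, 1], a2[founders, 2]))
  }
  expect_lt(abs(mean(vars) - 0.35), 0.03)
  expect_lt(abs(mean(slopes) - 1), 0.05)
  expect_lt(abs(mean(cors) - (-0.48)), 0.05)
})

test_that("phenotypes reduce to the fixed part in the small-variance limit", {
  ped <- simulate_pedigree(sim_pedigree_spec(3, 3, 4, 3, seed = 1))
  eps <- 1e-12
  trait <- sim_trait_spec(eps, eps, eps, gamma = 0.5,
                          hy_sd = 0, bm_sd = 0, pn_sd = 0)
  dat <- simulate_phenotypes(ped, trait, seed = 1)
  expect_lt(max(abs(dat$trait1 - 0.5 * dat$live_weight_kg)), 1e-4)
})

test_that("bivariate phenotype simulation honours the genetic correlation", {
  ped <- simulate_pedigree(sim_pedigree_spec(40, 2, 10, 2, seed = 4))
  founders <- ped$sire == 0 & ped$dam == 0
  cors <- c()
  for (s in 1:10) {
    trait <- sim_trait_spec(c(0.35, 0.4), c(0.05, 0.05), c(0.6, 0.55),
                            r_g = -0.48, r_e = 0.2)
    dat <- simulate_phenotypes(ped, trait, seed = s)
    a <- gene_drop(ped, matrix(c(0.35, -0.48 * sqrt(0.35 * 0.4),
                                 -0.48 * sqrt(0.35 * 0.4), 0.4), 2),
                   seed = s * 2 + 1)
    cors <- c(cors, cor(a[founders, 1], a[founders, 2]))
  }
  expect_lt(abs(mean(cors) - (-0.48)), 0.05)
})

test_that("allometric simulation follows the power law exactly when noiseless", {
  d <- simulate_allometric_weights(200, alpha = 2, beta = 1,
                                   log_noise_sd = 0, seed = 1)
  expect_equal(d$volume_ml, 2 * d$live_weight_kg, tolerance = 1e-12)
  f <- suppressWarnings(fit_allometric(d, "volume_ml"))
  expect_equal(f$beta, 1, tolerance = 1e-10)
  expect_equal(f$alpha, 2, tolerance = 1e-8)
  d2 <- simulate_allometric_weights(300, alpha = 5, beta = 0.93,
                                    log_noise_sd = 0, seed = 2)
  f2 <- suppressWarnings(fit_allometric(d2, "volume_ml"))
  expect_equal(f2$beta, 0.93, tolerance = 1e-10)
})

test_that("phantom text round-trip preserves HU and spacing", {
  ph <- generate_phantom(phantom_spec(image_size = 16, n_slices = 6, seed = 9))
  dir <- withr::local_tempdir()
  write_ct_dir(ph$volume, dir)
  back <- read_ct_dir(dir)
  expect_equal(back$spacing, ph$volume$spacing)
  expect_lt(max(abs(back$hu - ph$volume$hu)), 0.5 + 1e-9) # integer rounding
})
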