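test_that("A-inverse matches the dense tabular-method inverse", {
  # textbook trio
  trio <- tibble::tibble(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  Ai <- as.matrix(build_a_inverse(trio))
  expect_equal(Ai, rbind(c(1.5, 0.5, -1), c(0.5, 1.5, -1), c(-1, -1, 2)),
               ignore_attr = TRUE)
  # founders only -> identity
  f5 <- tibble::tibble(animal = 1:5, sire = 0, dam = 0)
  expect_equal(as.matrix(build_a_inverse(f5)), diag(5), ignore_attr = TRUE)
  # random pedigrees up to ~50 animals, incl. inbreeding, vs dense inverse
  for (s in 1:6) {
    ped <- simulate_pedigree(sim_pedigree_spec(3, 3, 5, 3, seed = s))
    A <- tabular_A(ped)
    expect_lt(max(abs(as.matrix(build_a_inverse(ped)) - solve(A))), 1e-8)
    expect_equal(attr(build_a_inverse(ped), "log_det_a"),
                 as.numeric(determinant(A)$modulus), tolerance = 1e-10)
  }
})

test_that("inbreeding coefficients match the tabular method", {
  # offspring of full-sib mating: F = 0.25
  ped <- tibble::tibble(animal = 1:5, sire = c(0, 0, 1, 1, 3),
                        dam = c(0, 0, 2, 2, 4))
  f <- as.numeric(inbreeding_coefficients(ped))
  expect_equal(f[5], 0.25)
  expect_equal(f[1:4], rep(0, 4))
  for (s in 1:4) {
    p <- simulate_pedigree(sim_pedigree_spec(2, 4, 4, 3, seed = s))
    expect_equal(as.numeric(inbreeding_coefficients(p)),
                 unname(diag(tabular_A(p)) - 1), tolerance = 1e-12)
  }
})

test_that("pedigree pruning keeps the requested ancestor depth", {
  chain <- tibble::tibble(animal = 1:11,
                          sire = c(0L, 1:10), dam = 0L,
                          sex = "M", birth_year = 2000 + 1:11)
  pr0 <- prune_pedigree(chain, 11, n_generations = 0)
  expect_identical(pr0$animal, 11L)
  pr5 <- prune_pedigree(chain, 11, n_generations = 5)
  expect_identical(nrow(pr5), 6L)
  expect_identical(pr5$animal, 6:11)
  expect_identical(pr5$sire[1], 0L) # parent outside kept set becomes unknown
  expect_identical(prune_pedigree(pr5, 11, 5), pr5) # idempotent
  expect_error(prune_pedigree(chain, 99), "unknown phenotyped ids")
})

test_that("genetic groups merge founder year bins greedily to min size", {
  mk <- function(per_sex_year, years) {
    n <- per_sex_year * 2 * years
    tibble::tibble(
      animal = seq_len(n), sire = 0L, dam = 0L,
      sex = rep(rep(c("M", "F"), each = per_sex_year), years),
      birth_year = rep(2000 + seq_len(years), each = 2 * per_sex_year))
  }
  g1 <- assign_genetic_groups(mk(60, 3), min_size = 50)
  expect_identical(nrow(g1$groups), 6L)
  g2 <- assign_genetic_groups(mk(30, 4), min_size = 50)
  expect_identical(nrow(g2$groups), 4L)
  expect_identical(g2$groups$n_members, rep(60L, 4))
  g3 <- assign_genetic_groups(mk(120, 1), min_size = 50)
  expect_identical(nrow(g3$groups), 2L)
  # every unknown-parent slot mapped
  expect_identical(nrow(g2$slots), 2L * nrow(mk(30, 4)))
  expect_warning(assign_genetic_groups(mk(10, 2), min_size = 50),
                 "fewer than 50")
})

test_that("MME solutions match a dense GLS oracle and approach OLS as variances vanish", {
  fx <- qg_fixture(seed = 5)
  vc <- list(G = matrix(0.35), P = 0.05, R = matrix(0.6))
  mme <- build_mme(model_spec("trait1"), fx$dat, fx$ped, vc = vc)
  # solver contract: tiny residual norm of the linear system
  expect_lt(max(abs(as.numeric(mme$M %*% mme$sol) - mme$rhs)), 1e-8)
  # dense GLS oracle for the fixed effects
  A <- tabular_A(fx$ped)
  ia <- match(fx$dat$animal, fx$ped$animal)
  Zp <- stats::model.matrix(~ 0 + factor(pen), fx$dat)
  V <- 0.35 * A[ia, ia] + 0.05 * tcrossprod(Zp) + diag(0.6, nrow(fx$dat))
  X <- as.matrix(mme$prep$Tmat[, mme$sections$fixed])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% mme$prep$y)
  expect_equal(mme$sol[mme$sections$fixed], drop(beta), tolerance = 1e-6,
               ignore_attr = TRUE)
  # dense-oracle EBVs: a_hat = G Z' P y with P = Vi - Vi X (X'ViX)^-1 X'Vi
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  Za <- matrix(0, nrow(fx$dat), nrow(fx$ped)); Za[cbind(seq_len(nrow(fx$dat)), ia)] <- 1
  ahat <- 0.35 * A %*% t(Za) %*% P %*% mme$prep$y
  expect_equal(mme$sol[mme$sections$animal[[1]]], drop(ahat), tolerance = 1e-6,
               ignore_attr = TRUE)
  # lambda -> infinity limit: fixed-effect solutions approach OLS
  vc0 <- list(G = matrix(0.6e-8), P = 0.6e-8, R = matrix(0.6))
  mme0 <- build_mme(model_spec("trait1"), fx$dat, fx$ped, vc = vc0)
  ols <- qr.coef(qr(X), mme$prep$y)
  expect_equal(mme0$sol[mme0$sections$fixed], unname(ols), tolerance = 1e-3)
})

test_that("EM-REML has a monotone restricted likelihood", {
  fx <- qg_fixture(seed = 3)
  fit <- suppressWarnings(
    reml_univariate(model_spec("trait1"), fx$dat, fx$ped,
                    method = "em", max_iter = 40, tol = 1e-6))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  fx2 <- qg_fixture(seed = 8, h2_target = c(0.1, 0.2, 0.7))
  fit2 <- suppressWarnings(
    reml_univariate(model_spec("trait1"), fx2$dat, fx2$ped,
                    method = "em", max_iter = 40, tol = 1e-6))
  expect_true(all(diff(fit2$loglik_trace) > -1e-6))
})

test_that("the AI score equals the numeric gradient of the restricted likelihood", {
  ns <- asNamespace("ctpheno")
  fx <- qg_fixture(seed = 4)
  prep <- ns$mm_prepare(list(model_spec("trait1")), fx$dat, fx$ped)
  th <- list(G = matrix(0.3), P = 0.08, R = matrix(0.55))
  fit <- ns$mm_solve(prep, th)
  sa <- ns$mm_score_ai(prep, th, fit)
  pack <- ns$theta_pack(th)
  for (i in seq_along(pack)) {
    h <- 1e-5
    up <- pack; up[i] <- up[i] + h
    dn <- pack; dn[i] <- dn[i] - h
    lu <- ns$mm_solve(prep, ns$theta_unpack(up, 1L), want_inverse = FALSE)$loglik
    ld <- ns$mm_solve(prep, ns$theta_unpack(dn, 1L), want_inverse = FALSE)$loglik
    expect_equal(sa$score[i], (lu - ld) / (2 * h), tolerance = 1e-3)
  }
})

test_that("bivariate AI score matches the numeric gradient", {
  ns <- asNamespace("ctpheno")
  ped <- simulate_pedigree(sim_pedigree_spec(3, 3, 6, 3, seed = 6))
  trait <- sim_trait_spec(c(0.35, 0.4), c(0.05, 0.06), c(0.6, 0.5),
                          r_g = 0.3, r_e = 0.2)
  dat <- simulate_phenotypes(ped, trait, seed = 7)
  prep <- suppressWarnings(
    ns$mm_prepare(list(model_spec("trait1"), model_spec("trait2")), dat, ped))
  th <- list(G = matrix(c(0.3, 0.05, 0.05, 0.35), 2),
             P = c(0.06, 0.07),
             R = matrix(c(0.5, 0.1, 0.1, 0.45), 2))
  fit <- ns$mm_solve(prep, th)
  sa <- ns$mm_score_ai(prep, th, fit)
  pack <- ns$theta_pack(th)
  for (i in seq_along(pack)) {
    h <- 1e-5
    up <- pack; up[i] <- up[i] + h
    dn <- pack; dn[i] <- dn[i] - h
    lu <- ns$mm_solve(prep, ns$theta_unpack(up, 2L), want_inverse = FALSE)$loglik
    ld <- ns$mm_solve(prep, ns$theta_unpack(dn, 2L), want_inverse = FALSE)$loglik
    expect_equal(sa$score[i], (lu - ld) / (2 * h), tolerance = 1e-3)
  }
})

test_that("REML equals closed-form ANOVA estimators on a balanced nested design", {
  set.seed(31)
  q <- 40; m <- 4; k <- 2 # animals, records per animal, animals per pen
  npen <- q / k
  sp <- 2; sa <- 1; se <- 1
  pen_of <- rep(seq_len(npen), each = k)
  a_eff <- rnorm(q, 0, sqrt(sa)); p_eff <- rnorm(npen, 0, sqrt(sp))
  dat <- tibble::tibble(
    animal = rep(seq_len(q), each = m),
    pen = paste0("p", pen_of[rep(seq_len(q), each = m)]),
    y = 10 + p_eff[pen_of[rep(seq_len(q), each = m)]] +
      a_eff[rep(seq_len(q), each = m)] + rnorm(q * m, 0, sqrt(se)))
  ped <- tibble::tibble(animal = seq_len(q), sire = 0L, dam = 0L)
  fit <- reml_univariate(model_spec("y", fixed = character(0),
                                    covariate = NULL),
                         dat, ped, tol = 1e-8, max_iter = 100)
  # balanced nested ANOVA closed forms
  ybar_a <- tapply(dat$y, dat$animal, mean)
  ybar_p <- tapply(dat$y, dat$pen, mean)[paste0("p", pen_of)]
  msa <- sum(m * (ybar_a - ybar_p)^2) / (npen * (k - 1))
  mse <- sum((dat$y - ybar_a[dat$animal])^2) / (q * m - q)
  grand <- mean(dat$y)
  msp <- sum(k * m * (tapply(dat$y, dat$pen, mean) - grand)^2) / (npen - 1)
  est <- c(a = (msa - mse) / m, p = (msp - msa) / (k * m), e = mse)
  expect_equal(as.numeric(fit$G), est[["a"]], tolerance = 1e-4)
  expect_equal(as.numeric(fit$pen), est[["p"]], tolerance = 1e-4)
  expect_equal(as.numeric(fit$R), est[["e"]], tolerance = 1e-4)
  # independent mixed-model cross-check (identity relationship, repeated
  # records): lme4 REML on the same two-random-effect model
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(y ~ (1 | animal) + (1 | pen), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(as.numeric(fit$G), vc$vcov[vc$grp == "animal"],
               tolerance = 1e-3)
  expect_equal(as.numeric(fit$pen), vc$vcov[vc$grp == "pen"],
               tolerance = 1e-3)
  expect_equal(as.numeric(fit$R), vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-3)
})

test_that("REML collapses the additive variance when there is none", {
  ped <- simulate_pedigree(sim_pedigree_spec(8, 4, 20, 5, seed = 9))
  trait <- sim_trait_spec(1e-6, 0.1, 1, gamma = 0.1)
  dat <- simulate_phenotypes(ped, trait, seed = 2)
  fit <- suppressWarnings(
    reml_univariate(model_spec("trait1"), dat, ped, tol = 1e-4))
  expect_lte(fit$h2, 0.05)
})

test_that("bivariate REML is symmetric under trait order swap", {
  ped <- simulate_pedigree(sim_pedigree_spec(6, 4, 15, 4, seed = 12))
  trait <- sim_trait_spec(c(0.35, 0.4), c(0.05, 0.05), c(0.6, 0.55),
                          r_g = 0.34, r_e = 0.3)
  dat <- simulate_phenotypes(ped, trait, seed = 3)
  f12 <- reml_bivariate(list(model_spec("trait1"), model_spec("trait2")),
                        dat, ped, tol = 1e-6)
  f21 <- reml_bivariate(list(model_spec("trait2"), model_spec("trait1")),
                        dat, ped, tol = 1e-6)
  expect_equal(f12$r_g, f21$r_g, tolerance = 1e-3)
  expect_equal(f12$G[1, 1], f21$G[2, 2], tolerance = 1e-3)
  expect_equal(f12$h2[["trait1"]], f21$h2[["trait1"]], tolerance = 1e-3)
})

test_that("heritability uses the stated denominator", {
  expect_equal(heritability(c(1, 1, 1)), 1 / 3)
  expect_equal(heritability(c(0.35, 0.05, 0.60)), 0.35)
  expect_equal(heritability(c(0.28, 0.12, 0.60)), 0.28)
  expect_equal(heritability(c(0.28, 0.12, 0.60), include_pen = FALSE),
               0.28 / 0.88)
  expect_error(heritability(c(0, 0, 0)), "positive")
})

test_that("BLUP breeding values behave as expected", {
  fx <- qg_fixture(seed = 6)
  vc <- list(G = matrix(0.35), P = 0.05, R = matrix(0.6))
  # all phenotypes equal -> all EBVs zero
  dat0 <- fx$dat
  dat0$trait1 <- 5
  ebv0 <- solve_blup(model_spec("trait1", fixed = character(0)),
                     dat0, fx$ped, vc = vc)
  expect_lt(max(abs(ebv0$ebv_trait1)), 1e-8)
  # EBVs cover every pedigree animal, phenotyped or not
  ebv <- solve_blup(model_spec("trait1"), fx$dat, fx$ped, vc = vc)
  expect_identical(nrow(ebv), nrow(fx$ped))
  # accuracy: rank correlation with true breeding values
  ped <- simulate_pedigree(sim_pedigree_spec(10, 4, 30, 5, seed = 10))
  trait <- sim_trait_spec(0.35, 0.05, 0.6, gamma = 0.1)
  dat <- simulate_phenotypes(ped, trait, seed = 4)
  ebv2 <- solve_blup(model_spec("trait1"), dat, ped, vc = vc)
  m <- merge(dat[, c("animal", "true_a_trait1")], ebv2)
  expect_gt(cor(m$true_a_trait1, m$ebv_trait1, method = "spearman"), 0.5)
})

test_that("unknown-parent groups shrink founder EBVs toward group means", {
  ped <- simulate_pedigree(sim_pedigree_spec(30, 4, 40, 4, seed = 14))
  gr <- assign_genetic_groups(ped, min_size = 50)
  trait <- sim_trait_spec(0.35, 0.05, 0.6, gamma = 0.1, mean = 3)
  dat <- simulate_phenotypes(ped, trait, seed = 5)
  vc <- list(G = matrix(0.35), P = 0.05, R = matrix(0.6))
  ebv <- solve_blup(model_spec("trait1"), dat, ped, groups = gr, vc = vc)
  expect_identical(nrow(ebv), nrow(ped))
  ge <- attr(ebv, "group_effects")[[1]]
  expect_identical(length(ge), nrow(gr$groups))
  # a founder with no records sits exactly at the mean of its two parent groups
  founders <- ped$animal[ped$sire == 0 & ped$dam == 0]
  unph <- setdiff(founders, dat$animal)
  if (length(unph)) {
    sl <- gr$slots[gr$slots$animal == unph[1], ]
    pred <- mean(ge[sl$group_id])
    # without progeny information the founder EBV equals its group mean
    has_prog <- any(ped$sire == unph[1] | ped$dam == unph[1])
    if (!has_prog) {
      expect_equal(ebv$ebv_trait1[ebv$animal == unph[1]], pred,
                   tolerance = 1e-6)
    }
  }
})

test_that("genetic trends are anchored and location-invariant", {
  ebvs <- tibble::tibble(animal = 1:60,
                         birth_year = rep(2010:2015, each = 10),
                         ebv_t = rnorm(60) - 0.05 * rep(0:5, each = 10))
  tr <- genetic_trend(ebvs, sigma_g = 0.5, ref_year = 2010, trait = "ebv_t")
  expect_equal(tr$trend[tr$birth_year == 2010], 0)
  ebvs2 <- ebvs; ebvs2$ebv_t <- ebvs2$ebv_t + 100
  tr2 <- genetic_trend(ebvs2, sigma_g = 0.5, ref_year = 2010, trait = "ebv_t")
  expect_equal(tr$trend, tr2$trend, tolerance = 1e-10)
  expect_error(genetic_trend(ebvs, 0.5, ref_year = 1999, trait = "ebv_t"),
               "no animals born")
})

test_that("directional selection produces a monotone recovered trend", {
  # truncation selection on true breeding values across 5 cohorts
  set.seed(20)
  n_per <- 60
  ped <- tibble::tibble(animal = 1:n_per, sire = 0L, dam = 0L,
                        sex = rep(c("M", "F"), n_per / 2),
                        birth_year = 2010L)
  a <- rnorm(n_per, 0, sqrt(0.35))
  for (yr in 2011:2014) {
    cohort <- ped[ped$birth_year == yr - 1L, ]
    av <- a[match(cohort$animal, ped$animal)]
    top <- cohort[order(-av), ]
    sires <- top$animal[top$sex == "M"][1:5]
    dams <- top$animal[top$sex == "F"][1:15]
    for (i in seq_len(n_per)) {
      s <- sample(sires, 1); d <- sample(dams, 1)
      id <- nrow(ped) + 1L
      ped <- rbind(ped, tibble::tibble(animal = id, sire = s, dam = d,
                                       sex = sample(c("M", "F"), 1),
                                       birth_year = yr))
      a <- c(a, 0.5 * (a[s] + a[d]) + rnorm(1, 0, sqrt(0.5 * 0.35)))
    }
  }
  dat <- tibble::tibble(animal = ped$animal,
                        pen = paste0("p", rep(1:6, length.out = nrow(ped))),
                        y = a + rnorm(nrow(ped), 0, sqrt(0.65)))
  vc <- list(G = matrix(0.35), P = 0.02, R = matrix(0.65))
  ebv <- solve_blup(model_spec("y", fixed = character(0), covariate = NULL),
                    dat, ped, vc = vc)
  tr <- genetic_trend(ebv, sigma_g = sqrt(0.35), ref_year = 2010)
  expect_identical(nrow(tr), 5L)
  expect_gt(tr$trend[tr$birth_year == 2014], tr$trend[tr$birth_year == 2010])
  expect_gt(cor(tr$birth_year, tr$trend, method = "spearman"), 0.8)
})
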