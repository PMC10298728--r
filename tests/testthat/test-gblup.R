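make_pheno <- function(grm, h2, seed) {
  ph <- simulate_phenotypes(grm, h2 = h2, seed = seed)
  dplyr::rename(ph, adjusted = "y")
}

test_that("REML maximum matches a dense-grid dense-algebra oracle", {
  # tiny-n draws with an interior variance-ratio optimum
  for (seed in c(45, 48, 51)) {
    pop <- simulate_founders(10, 150, seed = seed)
    g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
    ph <- make_pheno(g, 0.5, seed + 100)
    fit <- fit_gblup(ph, g)
    expect_false(fit$boundary)
    lam_grid <- grid_search_lambda(ph$adjusted, g$mat)
    expect_lt(abs(fit$lambda - lam_grid) / lam_grid, 1e-4)
  }
})

test_that("BLUP reduces to ridge shrinkage when G is the identity", {
  n <- 40
  ids <- sprintf("i%02d", 1:n)
  g <- structure(
    list(mat = diag(n) |> `dimnames<-`(list(ids, ids)), ids = ids,
         method = "full_tetraploid", n_loci_used = 0L, freq = NULL,
         repaired = FALSE),
    class = "tetra_grm"
  )
  withr::with_seed(44, y <- rnorm(n))
  fit <- fit_gblup(tibble::tibble(id = ids, adjusted = y), g)
  lam <- fit$lambda
  # with G = I the BLUP is (lambda / (lambda + 1)) * (y - mean-ish GLS mu)
  expect_equal(tidy(fit)$gebv, (lam / (lam + 1)) * (y - fit$mu),
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear errors", {
  pop <- simulate_founders(5, 40, seed = 45)
  g <- build_grm(dosages(pop), maf_min = 0.01)
  ph <- tibble::tibble(id = pop$id, adjusted = rep(1, 5))
  expect_error(fit_gblup(ph, g), "constant")
  nonpsd <- g
  nonpsd$mat[1, 2] <- nonpsd$mat[2, 1] <- 50
  expect_error(
    fit_gblup(tibble::tibble(id = pop$id, adjusted = rnorm(5)), nonpsd),
    "repair"
  )
  expect_error(fit_gblup(ph[1:2, ], g), "at least 3")
})

test_that("noise-free phenotype along G's leading eigenvector hits the
           large-lambda boundary with u tracking y", {
  pop <- simulate_founders(12, 200, seed = 46)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  e <- eigen(g$mat, symmetric = TRUE)
  y <- 3 * e$vectors[, 1]
  fit <- fit_gblup(tibble::tibble(id = pop$id, adjusted = y), g)
  expect_true(fit$boundary)
  expect_gt(fit$lambda, 1e3)
  expect_equal(tidy(fit)$gebv, y - fit$mu, tolerance = 1e-3)
})

test_that("Gibbs agrees with the closed-form BLUP at matched variances", {
  pop <- simulate_founders(50, 800, seed = 47)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  ph <- make_pheno(g, 0.5, 48)
  fg <- fit_gblup(ph, g, method = "gibbs",
                  mcmc = mcmc_config(n_burn_in = 500, n_samples = 1500,
                                     seed = 49))
  # oracle: u = s2g G (s2g G + s2e I)^{-1} (y - mu) at the posterior means
  blup <- fg$sigma2_g * g$mat %*%
    solve(fg$sigma2_g * g$mat + fg$sigma2_e * diag(50), ph$adjusted - fg$mu)
  rms <- sqrt(mean((tidy(fg)$gebv - blup)^2))
  expect_lt(rms, 0.05)
  expect_true(all(fg$posterior$ess > 30))
  expect_true(fg$h2 >= 0 && fg$h2 <= 1)
})

test_that("Gibbs chains are seed-reproducible and priors can pin variances", {
  pop <- simulate_founders(20, 200, seed = 50)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  ph <- make_pheno(g, 0.4, 51)
  cfg <- mcmc_config(n_burn_in = 100, n_samples = 300, seed = 52)
  f1 <- fit_gblup(ph, g, method = "gibbs", mcmc = cfg)
  f2 <- fit_gblup(ph, g, method = "gibbs", mcmc = cfg)
  expect_identical(f1$traces, f2$traces)
  expect_identical(tidy(f1)$gebv, tidy(f2)$gebv)
  # a degenerate prior forcing sigma2_g ~ 0 shrinks all GEBVs to ~ 0
  tight <- mcmc_config(n_burn_in = 100, n_samples = 300, seed = 53,
                       prior_df = 1e7, prior_scale_g = 1e-8)
  f0 <- fit_gblup(ph, g, method = "gibbs", mcmc = tight)
  expect_lt(max(abs(tidy(f0)$gebv)), 0.01)
})

test_that("prediction routes agree and respect algebraic identities", {
  pop <- simulate_founders(40, 600, seed = 54)
  d <- dosages(pop)
  # duplicate one genotype as an unphenotyped copy
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d[7, ], id = "twin"))
  g <- build_grm(d2, freq = pop$freq, repair = TRUE)
  ph <- make_pheno(g, 0.6, 55)
  train <- ph[ph$id != "twin", ]
  fit <- fit_gblup(train, g)
  test_ids <- c("twin", train$id[35:40])
  p1 <- predict_gebv(fit, g, test_ids)
  p2 <- predict_gebv(fit, g, test_ids, method = "joint")
  expect_equal(p1$gebv, p2$gebv, tolerance = 1e-8)
  # sigma2_g = 0 -> all predictions zero
  fit0 <- fit
  fit0$sigma2_g <- 0
  expect_equal(predict_gebv(fit0, g, test_ids)$gebv, rep(0, 7))
})

test_that("a duplicated training genotype predicts to its twin's GEBV", {
  pop <- simulate_founders(30, 500, seed = 56)
  d <- dosages(pop)
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d[3, ], id = "twin"))
  g <- build_grm(d2, freq = pop$freq)  # unrepaired: twin rows exactly equal
  ph <- make_pheno(build_grm(d2, freq = pop$freq, repair = TRUE), 0.6, 57)
  train <- ph[ph$id != "twin", ]
  fit <- fit_gblup(train, g)
  pred <- predict_gebv(fit, g, "twin")
  expect_equal(pred$gebv, tidy(fit)$gebv[fit$ids == "S0_3"],
               tolerance = 1e-6)
})

test_that("variance components are recovered without systematic bias", {
  pop <- simulate_founders(150, 600, seed = 58)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  est <- vapply(1:12, function(k) {
    ph <- make_pheno(g, 0.6, 600 + k)
    fit <- fit_gblup(ph, g)
    c(fit$sigma2_g, fit$h2)
  }, numeric(2))
  se_g <- sd(est[1, ]) / sqrt(ncol(est))
  se_h <- sd(est[2, ]) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 0.6), 3 * se_g)
  expect_lt(abs(mean(est[2, ]) - 0.6), 3 * se_h)
})
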