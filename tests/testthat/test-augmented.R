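test_that("correction factors match hand arithmetic on the 2x2 toy", {
  trial <- toy_trial_2x2()
  cf <- correction_factors(trial, "y")
  # block means 12 and 8, grand check mean 10 -> CF = +2, -2
  expect_equal(cf$cf[match(1:2, cf$block)], c(2, -2))
  adj <- adjust_phenotypes(trial, "y")
  expect_equal(adj$adjusted[adj$entry == "t1"], 18)
  # adjusted check means identical across blocks: c1 -> 8, c2 -> 12
  expect_equal(adj$adjusted[adj$entry == "c1"], 8)
  expect_equal(adj$adjusted[adj$entry == "c2"], 12)
})

test_that("correction factors sum to zero and absorb per-block shifts", {
  withr::with_seed(7, {
    trial <- null_trial(g = 3, r = 6, tests_per_block = 5)
  })
  cf <- correction_factors(trial, "y")
  expect_equal(sum(cf$cf), 0, tolerance = 1e-12)
  # identical checks across blocks -> all CF zero
  flat <- trial
  flat$y[flat$is_check] <- as.numeric(factor(flat$entry[flat$is_check]))
  cf0 <- correction_factors(flat, "y")
  expect_equal(cf0$cf, rep(0, 6), tolerance = 1e-12)
  # adding k to every plot of one block is absorbed by the correction
  # factors up to the common k/r offset every entry shares, so all entry
  # comparisons are unchanged
  k <- 11.5
  r <- 6
  shifted <- trial
  shifted$y[shifted$block == 3] <- shifted$y[shifted$block == 3] + k
  a1 <- adjust_phenotypes(trial, "y")
  a2 <- adjust_phenotypes(shifted, "y")
  delta <- a2$adjusted[match(a1$entry, a2$entry)] - a1$adjusted
  expect_equal(delta, rep(k / r, length(delta)), tolerance = 1e-12)
  expect_lt(diff(range(delta)), 1e-12)
})

test_that("a check missing from a block is a total validation failure", {
  trial <- toy_trial_2x2()[-4, ]  # drop c1 from block 2
  expect_error(correction_factors(trial, "y"), "c1.*block 2")
})

test_that("error-df design rule matches its closed form", {
  expect_true(validate_design(3, 9)$pass)     # bound 6, df 16
  expect_false(validate_design(3, 6)$pass)    # r = bound = 6
  expect_false(validate_design(2, 11)$pass)   # bound 11
  expect_true(validate_design(2, 12)$pass)
  expect_equal(validate_design(3, 9)$df_error, 16)
})

test_that("check ANOVA matches a brute-force two-way decomposition", {
  withr::with_seed(11, {
    trial <- null_trial(g = 3, r = 3, tests_per_block = 2, sd = 2)
  })
  aa <- anova_augmented(trial, "y")
  # brute-force SS on the 3x3 check table
  ch <- dplyr::filter(trial, is_check)
  m <- tapply(ch$y, list(ch$entry, ch$block), mean)
  grand <- mean(m)
  ss_checks <- 3 * sum((rowMeans(m) - grand)^2)
  ss_blocks <- 3 * sum((colMeans(m) - grand)^2)
  ss_err <- sum((m - outer(rowMeans(m), colMeans(m), `+`) + grand)^2)
  tab <- aa$anova
  expect_equal(tab$ss[tab$term == "checks"], ss_checks, tolerance = 1e-10)
  expect_equal(tab$ss[tab$term == "blocks"], ss_blocks, tolerance = 1e-10)
  expect_equal(tab$ss[tab$term == "error"], ss_err, tolerance = 1e-10)
  expect_equal(aa$df_error, 4)
})

test_that("check MSE estimates the residual variance", {
  # zero residual variation: additive checks x blocks -> MSE = 0, LSD = 0
  trial <- tidyr::expand_grid(entry = paste0("c", 1:3), block = 1:5)
  trial$is_check <- TRUE
  trial$plot <- paste0("p", seq_len(nrow(trial)))
  trial$y <- as.numeric(as.factor(trial$entry)) + 2 * trial$block
  t2 <- tibble::tibble(entry = "t1", block = 1L, is_check = FALSE,
                       plot = "pt", y = 1)
  aa0 <- anova_augmented(dplyr::bind_rows(trial, t2), "y")
  expect_equal(aa0$ms_error, 0, tolerance = 1e-20)
  expect_equal(aa0$lsd, 0, tolerance = 1e-9)

  # known sigma: MSE within a chi-square 99% interval
  sigma <- 3
  withr::with_seed(13, {
    big <- null_trial(g = 4, r = 10, tests_per_block = 2, sd = sigma)
  })
  aa <- anova_augmented(big, "y")
  df <- aa$df_error
  ci <- sigma^2 * qchisq(c(0.005, 0.995), df) / df
  expect_gt(aa$ms_error, ci[1])
  expect_lt(aa$ms_error, ci[2])
})

test_that("generation contrasts recover a simulated inbreeding penalty", {
  cfg <- study_config(
    n_founders = 4, n_loci = 150, maf_min = 0.05, n_blocks = 9,
    test_plots_per_block = 24, s1_family_size = 40, f1_family_size = 28,
    seed = 17
  )
  st <- simulate_study(cfg)
  aa <- anova_augmented(st$trial, "weight_total")
  adj <- adjust_phenotypes(st$trial, "weight_total")
  gc <- generation_contrasts(adj, st$pedigree, aa)
  s0s1 <- gc$contrasts[gc$contrasts$contrast == "S0 vs S1", ]
  expect_gt(s0s1$estimate, 0)
  expect_lt(s0s1$p.value, 0.01)
  expect_gt(gc$inbreeding_depression, 0)
  expect_equal(nrow(gc$heterosis), 2)
  expect_true(all(gc$heterosis$frac_above_best >= 0 &
                  gc$heterosis$frac_above_best <= 1))
})

test_that("contrast type-I error is near nominal under the null", {
  withr::with_seed(19, {
    rej <- replicate(200, {
      trial <- null_trial(g = 3, r = 9, tests_per_block = 10)
      ped <- null_pedigree(trial)
      aa <- anova_augmented(trial, "y")
      adj <- adjust_phenotypes(trial, "y")
      gc <- generation_contrasts(adj, ped, aa)
      gc$contrasts$p.value < 0.05
    })
  })
  rates <- rowMeans(rej)
  # 3 binomial SEs around 0.05 at n = 200 is about [0.004, 0.096]
  expect_true(all(rates > 0.002 & rates < 0.11))
  # identical groups give a contrast of exactly zero
  trial <- null_trial(g = 3, r = 4, tests_per_block = 4)
  trial$y <- 1
  ped <- null_pedigree(trial)
  aa <- anova_augmented(trial, "y")
  gc <- generation_contrasts(adjust_phenotypes(trial, "y"), ped, aa)
  expect_equal(gc$contrasts$estimate, rep(0, 3))
})

test_that("crossing-program summary computes rates and handles edge cases", {
  rec <- tibble::tibble(
    parent = c("A", "A", "B"), flowers = c(100, 100, 234),
    berries = c(40, 42, 88), seeds = c(120, 150, 90),
    type = c("cross", "self", "cross")
  )
  s <- summarize_program(rec)
  expect_equal(s$overall$crossing_success_pct, 100 * 170 / 434)
  expect_equal(s$per_parent$berry_set_pct[s$per_parent$parent == "A"], 41)
  expect_true(is.na(s$seed_set$sd[s$seed_set$type == "self"]))
  expect_equal(s$seed_set$mean[s$seed_set$type == "cross"], 105)
  expect_error(summarize_program(dplyr::mutate(rec, flowers = 0)), "flowers")
})
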