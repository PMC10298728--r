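#' Random-partition cross-validation of genomic prediction accuracy
#'
#' Repeats `n_reps` times: draw `floor(train_frac * n)` individuals without
#' replacement as the training set, fit GBLUP on them, predict the held-out
#' individuals, and record the Pearson correlation between observed and
#' predicted phenotypes (the prediction accuracy). Defaults are 50
#' partitions at 70/30. A replicate whose test phenotypes or predictions
#' have zero variance gets a missing accuracy with a warning; missing
#' replicates are reported, never dropped.
#'
#' @param pheno tibble with an id column (`id` or `entry`) and the trait.
#' @param grm a [build_grm()] object covering all phenotyped ids.
#' @param trait phenotype column name (default `"adjusted"`).
#' @param n_reps number of random partitions (default 50).
#' @param train_frac training fraction, strictly in (0, 1) (default 0.7).
#' @param seed optional integer seed (partitions are reproducible).
#' @param method fitting method passed to [fit_gblup()] (default
#'   `"reml"`).
#' @param mcmc [mcmc_config()] when `method = "gibbs"`.
#' @return Object of class `cv_result`: `reps` tibble (`rep`, `accuracy`,
#'   `n_train`, `n_test`) and summary statistics. [tidy()] returns the
#'   per-replicate tibble, [glance()] the summary, [autoplot()] a boxplot.
#' @export
random_cv <- function(pheno, grm, trait = "adjusted", n_reps = 50,
                      train_frac = 0.7, seed = NULL, method = "reml",
                      mcmc = mcmc_config()) {
  if (train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must be strictly between 0 and 1")
  }
  idcol <- intersect(c("id", "entry"), names(pheno))[1L]
  if (is.na(idcol)) abort("`pheno` needs an `id` or `entry` column")
  n <- nrow(pheno)
  if (n < 10) abort("need at least 10 individuals for cross-validation")
  if (!is.null(seed)) withr::local_seed(seed)

  n_train <- floor(train_frac * n)
  acc <- numeric(n_reps)
  for (k in seq_len(n_reps)) {
    tr <- sample.int(n, n_train)
    fit <- fit_gblup(pheno[tr, ], grm, trait = trait, method = method,
                     mcmc = mcmc)
    test_ids <- as.character(pheno[[idcol]][-tr])
    pred <- predict_gebv(fit, grm, test_ids)
    obs <- pheno[[trait]][-tr]
    if (length(obs) < 2 || !isTRUE(sd(obs) > 0) ||
        !isTRUE(sd(pred$gebv) > 0)) {
      warn(sprintf("replicate %d: zero variance in test set; accuracy NA", k))
      acc[k] <- NA_real_
    } else {
      acc[k] <- cor(obs, pred$gebv)
    }
  }
  reps <- tibble::tibble(
    rep = seq_len(n_reps), accuracy = acc,
    n_train = n_train, n_test = n - n_train
  )
  structure(
    list(
      reps = reps, trait = trait, method = method,
      mean = mean(acc, na.rm = TRUE),
      sd = sd(acc, na.rm = TRUE),
      n_valid = sum(!is.na(acc))
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validation (%s, trait '%s'): mean accuracy %.3f (sd %.3f, %d/%d valid reps)\n",
    x$method, x$trait, x$mean, x$sd, x$n_valid, nrow(x$reps)
  ))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$reps

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, method = x$method, mean_accuracy = x$mean,
    sd_accuracy = x$sd, n_reps = nrow(x$reps), n_valid = x$n_valid
  )
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = "", y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "prediction accuracy (Pearson r)",
                  title = object$trait) +
    ggplot2::theme_minimal()
}

#' Relatedness class of two families
#'
#' `full_sib` for a family with itself, `half_sib` when two distinct
#' families share at least one parent, `unrelated` otherwise.
#'
#' @param fam_a,fam_b family labels.
#' @param families tibble from [family_table()].
#' @return A character scalar.
#' @export
relatedness_class <- function(fam_a, fam_b, families) {
  if (fam_a == fam_b) return("full_sib")
  pa <- unlist(families[families$family == fam_a, c("parent1", "parent2")])
  pb <- unlist(families[families$family == fam_b, c("parent1", "parent2")])
  if (length(intersect(pa, pb)) > 0) "half_sib" else "unrelated"
}

#' Family-structured training/testing accuracy matrix
#'
#' Builds the full matrix of (training family, testing family) prediction
#' accuracies for one trait. Diagonal cells (a family predicting itself)
#' use [random_cv()] within the family and report its mean accuracy;
#' off-diagonal cells are single fits training on the whole of family A
#' and predicting the whole of family B. Each cell carries the pedigree
#' relatedness class of the pair (`full_sib`, `half_sib`, `unrelated`).
#' Cells whose test set is too small for a correlation (fewer than 3
#' individuals) are reported missing.
#'
#' @inheritParams random_cv
#' @param pedigree tibble with `id`, `family`, `parent1`, `parent2` for
#'   every phenotyped individual.
#' @param within_reps partitions for the diagonal cells (default 50).
#' @return Object of class `accuracy_matrix`: long tibble `cells`
#'   (`training`, `testing`, `trait`, `accuracy`, `relatedness`,
#'   `n_train`, `n_test`) plus the within-family [random_cv()] objects.
#' @export
scheme_cv <- function(pheno, grm, pedigree, trait = "adjusted",
                      within_reps = 50, train_frac = 0.7, seed = NULL,
                      method = "reml", mcmc = mcmc_config()) {
  idcol <- intersect(c("id", "entry"), names(pheno))[1L]
  if (is.na(idcol)) abort("`pheno` needs an `id` or `entry` column")
  if (!is.null(seed)) withr::local_seed(seed)
  d <- dplyr::inner_join(
    pheno, pedigree[, c("id", "family", "parent1", "parent2")],
    by = setNames("id", idcol)
  )
  d <- dplyr::filter(d, !is.na(.data$family))
  fams <- family_table(pedigree)
  fams <- fams[fams$family %in% d$family, ]
  split_d <- split(d, d$family)

  cells <- list()
  within <- list()
  for (fa in fams$family) {
    for (fb in fams$family) {
      da <- split_d[[fa]]
      db <- split_d[[fb]]
      rel <- relatedness_class(fa, fb, fams)
      if (fa == fb) {
        if (nrow(da) >= 10) {
          cv <- random_cv(da, grm, trait = trait, n_reps = within_reps,
                          train_frac = train_frac, method = method,
                          mcmc = mcmc)
          within[[fa]] <- cv
          acc <- cv$mean
          ntr <- floor(train_frac * nrow(da))
          nte <- nrow(da) - ntr
        } else {
          acc <- NA_real_
          ntr <- NA_integer_
          nte <- NA_integer_
        }
      } else {
        ntr <- nrow(da)
        nte <- nrow(db)
        if (nte < 3 || ntr < 3) {
          acc <- NA_real_
        } else {
          fit <- fit_gblup(da, grm, trait = trait, method = method,
                           mcmc = mcmc)
          pred <- predict_gebv(fit, grm, as.character(db[[idcol]]))
          obs <- db[[trait]]
          acc <- if (sd(obs) == 0 || sd(pred$gebv) == 0) NA_real_
                 else cor(obs, pred$gebv)
        }
      }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        training = fa, testing = fb, trait = trait, accuracy = acc,
        relatedness = rel, n_train = ntr, n_test = nte
      )
    }
  }
  structure(
    list(cells = dplyr::bind_rows(cells), within = within, trait = trait),
    class = "accuracy_matrix"
  )
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat("Accuracy matrix, trait '", x$trait, "'\n", sep = "")
  wide <- tidyr::pivot_wider(
    x$cells[, c("training", "testing", "accuracy")],
    names_from = "testing", values_from = "accuracy"
  )
  print(wide)
  invisible(x)
}

#' @export
tidy.accuracy_matrix <- function(x, ...) x$cells

#' @export
autoplot.accuracy_matrix <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(.data$testing, .data$training, fill = .data$accuracy)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$accuracy), "",
                     sprintf("%.2f", .data$accuracy))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::labs(x = "testing family", y = "training family",
                  fill = "r", title = object$trait) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write / read a long-format accuracy table
#'
#' The long TSV (`training`, `testing`, `trait`, `accuracy`,
#' `relatedness`, `n_train`, `n_test`) round-trips the accuracy matrix,
#' missing cells included.
#'
#' @param am an [scheme_cv()] result (or its `cells` tibble).
#' @param path output path.
#' @return `path` (write) or the cells tibble (read).
#' @export
write_accuracy_tsv <- function(am, path) {
  cells <- if (inherits(am, "accuracy_matrix")) am$cells else am
  readr::write_tsv(cells, path, na = "NA")
  invisible(path)
}

#' @rdname write_accuracy_tsv
#' @export
read_accuracy_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    training = readr::col_character(),
                    testing = readr::col_character(),
                    trait = readr::col_character(),
                    relatedness = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
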