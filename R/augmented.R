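#' Per-block correction factors from replicated checks
#'
#' In an augmented design the replicated check cultivars estimate block
#' effects. The correction factor of block j is
#' `CF_j = (mean of check plots in block j) - (grand mean of all check
#' plots)`; subtracting it from every plot in block j removes the block
#' effect. With equal check counts per block the factors sum to zero.
#'
#' @param trial trial tibble (`entry`, `block`, `plot`, `is_check`, trait
#'   columns), one row per plot.
#' @param trait name of the trait column to use.
#' @return Tibble with columns `block`, `cf`.
#' @export
#' @examples
#' toy <- tibble::tibble(
#'   entry = c("c1", "c2", "t1", "c1", "c2"),
#'   block = c(1, 1, 1, 2, 2), plot = paste0("p", 1:5),
#'   is_check = c(TRUE, TRUE, FALSE, TRUE, TRUE),
#'   y = c(10, 14, 20, 6, 10)
#' )
#' correction_factors(toy, "y")
correction_factors <- function(trial, trait) {
  check_trial(trial, trait)
  checks <- dplyr::filter(trial, .data$is_check)
  if (nrow(checks) == 0) abort("no check plots in trial")
  tab <- dplyr::count(checks, .data$entry, .data$block)
  grid <- tidyr::expand_grid(
    entry = unique(checks$entry), block = unique(trial$block)
  )
  missing <- dplyr::anti_join(grid, tab, by = c("entry", "block"))
  if (nrow(missing) > 0 || any(tab$n != 1L)) {
    bad <- if (nrow(missing) > 0) missing else tab[tab$n != 1L, 1:2]
    abort(paste0(
      "every check must appear exactly once per block; problem at: ",
      paste(sprintf("(%s, block %s)", bad$entry, bad$block), collapse = ", ")
    ))
  }
  grand <- mean(checks[[trait]])
  dplyr::summarise(
    dplyr::group_by(checks, .data$block),
    cf = mean(.data[[trait]]) - grand, .groups = "drop"
  )
}

check_trial <- function(trial, trait) {
  need <- c("entry", "block", "plot", "is_check")
  if (!all(need %in% names(trial))) {
    abort(paste0("trial must have columns ", paste(need, collapse = ", ")))
  }
  if (!trait %in% names(trial)) {
    abort(paste0("trait column '", trait, "' not found in trial"))
  }
  if (anyDuplicated(trial[c("block", "plot")])) {
    abort("(block, plot) pairs must be unique")
  }
  invisible(trial)
}

#' Block-adjusted phenotypes
#'
#' Subtracts each block's correction factor from every plot in the block
#' (`Y' = Y - CF`); check entries, observed once per block, are then
#' averaged over blocks so that every entry ends up with a single adjusted
#' value. A constant added to every plot of one block is absorbed by the
#' correction factors up to a `k / r` offset shared by every entry (the
#' grand check mean moves by `k / r`), so all comparisons among adjusted
#' values are invariant to per-block shifts.
#'
#' @inheritParams correction_factors
#' @param cf optional precomputed tibble from [correction_factors()];
#'   computed from the trial when `NULL`.
#' @return Tibble with one row per entry: `entry`, `is_check`, `block`
#'   (`NA` for checks, which span all blocks), `raw` (`NA` for checks),
#'   `cf_applied` and `adjusted`.
#' @export
adjust_phenotypes <- function(trial, trait, cf = NULL) {
  check_trial(trial, trait)
  if (is.null(cf)) cf <- correction_factors(trial, trait)
  d <- dplyr::left_join(trial, cf, by = "block")
  if (anyNA(d$cf)) abort("trial contains blocks with no correction factor")
  d <- dplyr::mutate(d, adjusted = .data[[trait]] - .data$cf)
  tests <- dplyr::transmute(
    dplyr::filter(d, !.data$is_check),
    entry = .data$entry, is_check = FALSE, block = .data$block,
    raw = .data[[trait]], cf_applied = .data$cf, adjusted = .data$adjusted
  )
  if (anyDuplicated(tests$entry)) {
    abort("non-check entries must occupy exactly one plot")
  }
  checks <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(d, .data$is_check), .data$entry),
    is_check = TRUE, block = NA, raw = NA_real_, cf_applied = NA_real_,
    adjusted = mean(.data$adjusted), .groups = "drop"
  )
  dplyr::bind_rows(checks, tests)
}

#' Augmented-design validity rule for the error degrees of freedom
#'
#' The check-based error of an augmented design has `(c - 1)(r - 1)` degrees
#' of freedom; requiring more than 10 of them is equivalent to
#' `r > 10 / (c - 1) + 1`.
#'
#' @param c_checks number of check cultivars per block.
#' @param r_blocks number of blocks.
#' @return One-row tibble: `c_checks`, `r_blocks`, `bound`, `df_error`,
#'   `pass`, `message`.
#' @export
#' @examples
#' validate_design(3, 9)  # passes: 9 > 6, error df 16
validate_design <- function(c_checks, r_blocks) {
  if (c_checks < 2 || r_blocks < 2) {
    abort("need at least 2 checks and 2 blocks")
  }
  bound <- 10 / (c_checks - 1) + 1
  df_error <- (c_checks - 1) * (r_blocks - 1)
  pass <- r_blocks > bound
  tibble::tibble(
    c_checks = c_checks, r_blocks = r_blocks, bound = bound,
    df_error = df_error, pass = pass,
    message = sprintf(
      "error df = %d (%s 10): r = %d %s bound %.3g",
      df_error, if (pass) ">" else "<=", r_blocks,
      if (pass) "exceeds" else "does not exceed", bound
    )
  )
}

#' Check-based ANOVA and least significant differences
#'
#' Fits the two-way checks-by-blocks ANOVA on the replicated check plots;
#' the interaction mean square is the experimental error, with
#' `(c - 1)(r - 1)` degrees of freedom. Standard errors of a difference
#' between adjusted means follow the classical augmented-design cases:
#' * two checks: `sqrt(2 MSE / r)`
#' * two test entries in the same block: `sqrt(2 MSE)`
#' * two test entries in different blocks: `sqrt(2 MSE (1 + 1/g))`
#'   (the block correction adds variance)
#' * a test entry vs a check mean: `sqrt(MSE (1 + 1/r + 1/g + 1/(r g)))`
#'
#' `LSD = t(1 - alpha/2, df) * SED` for each case; the headline `lsd` is
#' the two-tests-in-different-blocks case.
#'
#' @inheritParams correction_factors
#' @param alpha significance level for the LSD (default 0.05).
#' @return Object of class `augmented_anova`: list with `trait`, `g`
#'   (checks per block), `r` (blocks), `df_error`, `ms_error`, `anova`
#'   (tibble of terms, df, SS, MS), `lsd_table` (tibble of SED/LSD by
#'   case), `lsd` and `alpha`. Has [tidy()] and [glance()] methods.
#' @export
anova_augmented <- function(trial, trait, alpha = 0.05) {
  check_trial(trial, trait)
  checks <- dplyr::filter(trial, .data$is_check)
  g <- dplyr::n_distinct(checks$entry)
  r <- dplyr::n_distinct(checks$block)
  df_error <- (g - 1) * (r - 1)
  if (df_error <= 0) abort("check layout leaves no error degrees of freedom")
  # verify the complete one-obs-per-cell layout before trusting the aov
  correction_factors(trial, trait)

  fit <- aov(stats::reformulate(c("factor(entry)", "factor(block)"),
                                response = trait),
             data = checks)
  at <- summary(fit)[[1L]]
  terms <- trimws(rownames(at))
  terms[terms == "factor(entry)"] <- "checks"
  terms[terms == "factor(block)"] <- "blocks"
  terms[terms == "Residuals"] <- "error"
  anova_tbl <- tibble::tibble(
    term = terms, df = at$Df, ss = at$`Sum Sq`, ms = at$`Mean Sq`
  )
  mse <- anova_tbl$ms[anova_tbl$term == "error"]
  stopifnot(anova_tbl$df[anova_tbl$term == "error"] == df_error)

  tcrit <- qt(1 - alpha / 2, df_error)
  sed <- c(
    two_checks = sqrt(2 * mse / r),
    two_tests_same_block = sqrt(2 * mse),
    two_tests_diff_block = sqrt(2 * mse * (1 + 1 / g)),
    test_vs_check = sqrt(mse * (1 + 1 / r + 1 / g + 1 / (r * g)))
  )
  lsd_table <- tibble::tibble(
    case = names(sed), sed = unname(sed), lsd = tcrit * unname(sed)
  )
  structure(
    list(
      trait = trait, g = g, r = r, df_error = df_error, ms_error = mse,
      anova = anova_tbl, lsd_table = lsd_table,
      lsd = lsd_table$lsd[lsd_table$case == "two_tests_diff_block"],
      alpha = alpha
    ),
    class = "augmented_anova"
  )
}

#' @export
print.augmented_anova <- function(x, ...) {
  cat("Augmented-design ANOVA for trait '", x$trait, "' (", x$g,
      " checks x ", x$r, " blocks)\n", sep = "")
  print(x$anova)
  cat(sprintf("error MS = %.4g on %d df; LSD_%g = %.4g\n",
              x$ms_error, x$df_error, x$alpha, x$lsd))
  invisible(x)
}

#' @export
tidy.augmented_anova <- function(x, ...) x$anova

#' @export
glance.augmented_anova <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, g = x$g, r = x$r, df_error = x$df_error,
    ms_error = x$ms_error, lsd = x$lsd, alpha = x$alpha
  )
}

#' Generation contrasts, inbreeding depression and heterosis
#'
#' Compares the generation means of block-adjusted values: parents vs selfed
#' offspring (S0 vs S1, inbreeding depression), parents vs hybrids (S0 vs
#' F1, average heterosis) and selfed vs hybrid offspring (S1 vs F1). Each
#' contrast is a difference of group means tested with a t statistic on the
#' check-error degrees of freedom, with the check-derived error mean square
#' supplying the per-entry variance: an unreplicated test entry contributes
#' `MSE`, a check entry (a mean over the `r` blocks) contributes `MSE / r`,
#' so `SED^2 = MSE (sum(v_1)/n_1^2 + sum(v_2)/n_2^2)` with `v` the
#' per-entry weights. Covariances induced by the shared block correction
#' are ignored (they cancel exactly for test groups balanced over blocks).
#'
#' Also reported: proportional inbreeding depression
#' `1 - mean(S1) / mean(S0)`, and per F1 family the mid-parent and
#' best-parent heterosis plus the fraction of F1 entries exceeding the best
#' parent.
#'
#' @param adjusted tibble from [adjust_phenotypes()].
#' @param pedigree tibble with columns `id`, `parent1`, `parent2`,
#'   `generation` (values among S0/S1/F1) and optionally `family`.
#' @param anova an [anova_augmented()] fit supplying the error term.
#' @param s1_families optional character vector restricting which S1
#'   families enter the contrasts (default: all).
#' @return Object of class `generation_contrasts`: list with `contrasts`
#'   (tibble: contrast, estimate, se, df, statistic, p.value),
#'   `group_means`, `inbreeding_depression` (proportional, on means) and
#'   `heterosis` (per F1 family). [tidy()] returns the contrast tibble.
#' @export
generation_contrasts <- function(adjusted, pedigree, anova,
                                 s1_families = NULL) {
  ped_cols <- intersect(c("id", "parent1", "parent2", "generation",
                          "family"), names(pedigree))
  d <- dplyr::inner_join(adjusted, pedigree[ped_cols], by = c(entry = "id"))
  if (!is.null(s1_families) && "family" %in% names(d)) {
    d <- dplyr::filter(
      d, .data$generation != "S1" | .data$family %in% s1_families
    )
  }
  d <- dplyr::mutate(d, .vwt = ifelse(.data$is_check, 1 / anova$r, 1))
  groups <- dplyr::summarise(
    dplyr::group_by(d, .data$generation),
    n = dplyr::n(), mean = mean(.data$adjusted),
    vsum = sum(.data$.vwt), .groups = "drop"
  )
  gm <- setNames(groups$mean, groups$generation)
  gn <- setNames(groups$n, groups$generation)
  gv <- setNames(groups$vsum, groups$generation)
  pairs <- list(c("S0", "S1"), c("S0", "F1"), c("S1", "F1"))
  contrasts <- purrr::map_dfr(pairs, function(pr) {
    if (!all(pr %in% names(gm))) {
      return(tibble::tibble(
        contrast = paste(pr, collapse = " vs "), estimate = NA_real_,
        se = NA_real_, df = anova$df_error, statistic = NA_real_,
        p.value = NA_real_
      ))
    }
    est <- gm[[pr[1L]]] - gm[[pr[2L]]]
    se <- sqrt(anova$ms_error * (gv[[pr[1L]]] / gn[[pr[1L]]]^2 +
                                 gv[[pr[2L]]] / gn[[pr[2L]]]^2))
    tstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est))
    tibble::tibble(
      contrast = paste(pr, collapse = " vs "), estimate = est, se = se,
      df = anova$df_error, statistic = tstat,
      p.value = 2 * pt(-abs(tstat), anova$df_error)
    )
  })

  id_prop <- if (all(c("S0", "S1") %in% names(gm)) && gm[["S0"]] != 0) {
    1 - gm[["S1"]] / gm[["S0"]]
  } else {
    NA_real_
  }

  het <- NULL
  if ("family" %in% names(d) && "F1" %in% d$generation) {
    f1 <- dplyr::filter(d, .data$generation == "F1")
    parent_mean <- setNames(
      d$adjusted[d$generation == "S0"], d$entry[d$generation == "S0"]
    )
    het <- purrr::map_dfr(split(f1, f1$family), function(fam) {
      ps <- c(fam$parent1[1L], fam$parent2[1L])
      if (!all(ps %in% names(parent_mean))) {
        return(tibble::tibble(
          family = fam$family[1L], mid_parent = NA_real_,
          best_parent = NA_real_, mean_f1 = mean(fam$adjusted),
          mph = NA_real_, bph = NA_real_, frac_above_best = NA_real_
        ))
      }
      mp <- mean(parent_mean[ps])
      bp <- max(parent_mean[ps])
      tibble::tibble(
        family = fam$family[1L], mid_parent = mp, best_parent = bp,
        mean_f1 = mean(fam$adjusted),
        mph = (mean(fam$adjusted) - mp) / abs(mp),
        bph = (mean(fam$adjusted) - bp) / abs(bp),
        frac_above_best = mean(fam$adjusted > bp)
      )
    })
  }

  groups$vsum <- NULL
  structure(
    list(contrasts = contrasts, group_means = groups,
         inbreeding_depression = unname(id_prop), heterosis = het),
    class = "generation_contrasts"
  )
}

#' @export
tidy.generation_contrasts <- function(x, ...) x$contrasts

#' @export
print.generation_contrasts <- function(x, ...) {
  print(x$contrasts)
  if (!is.na(x$inbreeding_depression)) {
    cat(sprintf("proportional inbreeding depression (S1 vs S0): %.3f\n",
                x$inbreeding_depression))
  }
  invisible(x)
}

#' Proportional inbreeding depression from group means
#'
#' `1 - mean(s1) / mean(s0)`: the fraction of the parental mean lost in the
#' selfed offspring (0.75 means the selfed generation retains a quarter of
#' the parents' performance).
#'
#' @param s0 numeric vector of parental (S0) means.
#' @param s1 numeric vector of selfed-offspring (S1) means.
#' @return A single proportion.
#' @export
#' @examples
#' inbreeding_depression(s0 = c(2771, 3304, 2247), s1 = c(725, 781, 497))
inbreeding_depression <- function(s0, s1) {
  if (length(s0) == 0 || length(s1) == 0) abort("empty group")
  m0 <- mean(s0)
  if (m0 == 0) abort("S0 mean is zero; proportion undefined")
  1 - mean(s1) / m0
}

#' Crossing-program summary statistics
#'
#' From per-parent crossing records (flowers pollinated, berries obtained,
#' seeds per berry, pollination type) computes the overall crossing success
#' (100 x berries / flowers), the per-parent berry set, and the seed set
#' mean and SD by pollination type. SD over a single record is undefined
#' and reported missing.
#'
#' @param records tibble with columns `parent`, `flowers`, `berries`,
#'   `seeds` (may be `NA`), `type` (e.g. `"self"` or `"cross"`).
#' @return List with tibbles `overall` (`flowers`, `berries`,
#'   `crossing_success_pct`), `per_parent` (`parent`, `berry_set_pct`) and
#'   `seed_set` (`type`, `n`, `mean`, `sd`).
#' @export
#' @examples
#' summarize_program(tibble::tibble(
#'   parent = c("A", "B"), flowers = c(200, 234), berries = c(80, 90),
#'   seeds = c(120, 150), type = c("cross", "self")
#' ))
summarize_program <- function(records) {
  need <- c("parent", "flowers", "berries", "seeds", "type")
  if (!all(need %in% names(records))) {
    abort(paste0("records must have columns ", paste(need, collapse = ", ")))
  }
  fl <- sum(records$flowers)
  if (fl <= 0) abort("total flowers must be positive")
  overall <- tibble::tibble(
    flowers = fl, berries = sum(records$berries),
    crossing_success_pct = 100 * sum(records$berries) / fl
  )
  per_parent <- dplyr::summarise(
    dplyr::group_by(records, .data$parent),
    berry_set_pct = 100 * sum(.data$berries) / sum(.data$flowers),
    .groups = "drop"
  )
  seed_set <- dplyr::summarise(
    dplyr::group_by(records, .data$type),
    n = sum(!is.na(.data$seeds)),
    mean = mean(.data$seeds, na.rm = TRUE),
    sd = if (sum(!is.na(.data$seeds)) > 1) sd(.data$seeds, na.rm = TRUE)
         else NA_real_,
    .groups = "drop"
  )
  list(overall = overall, per_parent = per_parent, seed_set = seed_set)
}
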