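#' Study design configuration
#'
#' Describes the simulated breeding study: founders genotyped at unlinked
#' SNPs, one selfed (S1) family per founder, two half-sib F1 families that
#' share the first founder as common female parent, and an augmented field
#' design in which the founders are replicated as checks in every incomplete
#' block while each S1/F1 test entry occupies exactly one plot.
#'
#' Defaults mirror the motivating trial: 4 founder cultivars, ~2000 SNPs with
#' generating MAF at least 1%, 9 incomplete blocks of 100 test plots each,
#' and 6 families of 150 entries (4 x 150 S1 + 2 x 150 F1 = 900 = 9 x 100).
#'
#' @param n_founders,n_loci,maf_min passed to [simulate_founders()].
#' @param n_blocks number of incomplete blocks.
#' @param test_plots_per_block unreplicated test plots per block.
#' @param s1_family_size,f1_family_size entries per S1 family (one family
#'   per founder) and per F1 family (two families: founder1 x founder2 and
#'   founder1 x founder3).
#' @param alpha double-reduction probability for all meioses.
#' @param seed integer seed for the whole study.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_founders = 4, n_loci = 2000, maf_min = 0.01,
                         n_blocks = 9, test_plots_per_block = 100,
                         s1_family_size = 150, f1_family_size = 150,
                         alpha = 0, seed = 1) {
  cfg <- list(
    n_founders = n_founders, n_loci = n_loci, maf_min = maf_min,
    n_blocks = n_blocks, test_plots_per_block = test_plots_per_block,
    s1_family_size = s1_family_size, f1_family_size = f1_family_size,
    alpha = alpha, seed = seed
  )
  counts <- unlist(cfg[c("n_founders", "n_loci", "n_blocks",
                         "test_plots_per_block", "s1_family_size",
                         "f1_family_size")])
  if (any(counts < 1)) abort("all design counts must be positive")
  if (n_founders < 3) abort("need at least 3 founders for the two F1 families")
  if (maf_min <= 0 || maf_min >= 0.5) abort("`maf_min` must be in (0, 0.5)")
  n_test <- n_founders * s1_family_size + 2 * f1_family_size
  if (n_test > n_blocks * test_plots_per_block) {
    abort(sprintf(
      "family sizes need %d test plots but the design provides %d",
      n_test, n_blocks * test_plots_per_block
    ))
  }
  structure(cfg, class = "study_config")
}

#' Trait generative model
#'
#' A plot phenotype is
#' `intercept + block effect + sum(dosage * additive effect)
#'  - id_coefficient * F_ibd + N(0, residual_sd^2)`,
#' where `F_ibd` is the individual's realized IBD homozygosity fraction
#' ([realized_inbreeding()]). The `id_coefficient` is a directional-dominance
#' proxy: a positive value makes phenotypes fall linearly with realized
#' inbreeding, which is how inbreeding depression after selfing enters the
#' simulation.
#'
#' @param name trait name.
#' @param additive_effects numeric vector, one effect per locus per dosage
#'   unit.
#' @param id_coefficient penalty (trait units) per unit realized IBD
#'   homozygosity.
#' @param block_effects numeric vector, one per block.
#' @param residual_sd non-negative residual standard deviation.
#' @param intercept trait intercept.
#' @return A list of class `trait_model`.
#' @export
trait_model <- function(name, additive_effects, id_coefficient = 0,
                        block_effects = 0, residual_sd = 0, intercept = 0) {
  if (residual_sd < 0) abort("`residual_sd` must be non-negative")
  structure(
    list(
      name = name, additive_effects = additive_effects,
      id_coefficient = id_coefficient, block_effects = block_effects,
      residual_sd = residual_sd, intercept = intercept
    ),
    class = "trait_model"
  )
}

#' Default tuber-trait models
#'
#' Ten traits echoing a potato tuber evaluation: total tuber weight and five
#' grading sizes (grams per 4-plant plot), shape and size uniformity and eye
#' depth (1-9 scores), and reducing sugar. Weight traits carry a strong
#' directional inbreeding-depression penalty (so that one selfing, F = 1/6,
#' costs on the order of three quarters of the total plot weight); score
#' traits a mild one; reducing sugar increases with inbreeding (negative
#' penalty, i.e. inbreds score worse).
#'
#' @param n_loci,n_blocks design dimensions the models must match.
#' @param seed integer seed for effect draws.
#' @return A named list of [trait_model()] objects.
#' @export
default_trait_models <- function(n_loci, n_blocks, seed = 1) {
  withr::local_seed(seed)
  meta <- tibble::tibble(
    name = c("weight_lt25", "weight_25_40", "weight_40_50", "weight_50_60",
             "weight_gt60", "weight_total", "shape_uniformity",
             "size_uniformity", "eye_depth", "reducing_sugar"),
    intercept = c(45, 350, 700, 900, 450, 2700, 5.6, 5.5, 5.2, 0.15),
    gen_sd = c(15, 90, 180, 250, 180, 450, 0.5, 0.5, 0.5, 0.12),
    id_coef = c(-60, 700, 2400, 4200, 2200, 12000, 0.4, 3.5, 3.0, -1.3),
    resid_sd = c(12, 60, 120, 160, 120, 250, 0.45, 0.4, 0.35, 0.12)
  )
  models <- purrr::pmap(meta, function(name, intercept, gen_sd, id_coef,
                                       resid_sd) {
    eff <- rnorm(n_loci, 0, gen_sd / sqrt(n_loci))
    trait_model(
      name = name,
      additive_effects = eff - mean(eff),
      id_coefficient = id_coef,
      block_effects = rnorm(n_blocks, 0, gen_sd / 4),
      residual_sd = resid_sd,
      intercept = intercept
    )
  })
  setNames(models, meta$name)
}

#' Genotypic value of each individual under a trait model
#'
#' `intercept + sum(dosage * effect) - id_coefficient * F_ibd`; no block or
#' residual term.
#'
#' @param pop a [tetra_pop][new_tetra_pop].
#' @param model a [trait_model()].
#' @return Tibble with columns `id`, `value`.
#' @export
genetic_values <- function(pop, model) {
  d <- as.matrix(dosages(pop)[-1L])
  f <- realized_inbreeding(pop)$f_ibd
  tibble::tibble(
    id = pop$id,
    value = model$intercept + as.numeric(d %*% model$additive_effects) -
      model$id_coefficient * f
  )
}

#' Simulate a complete augmented-design breeding study
#'
#' Builds founders, one S1 family per founder, two half-sib F1 families
#' sharing the first founder as female parent, lays all test entries out in
#' an augmented design with the founders replicated as checks in every
#' block, and generates plot phenotypes under the given trait models.
#'
#' @param config a [study_config()].
#' @param trait_models named list of [trait_model()] objects; default
#'   [default_trait_models()] at the config's dimensions.
#' @return A list of class `tetra_study` with elements
#'   `pop` (all individuals), `dosage` (wide tibble),
#'   `trial` (one row per plot: `entry`, `block`, `plot`, `is_check`,
#'   one column per trait), `pedigree` (tibble `id`, `parent1`, `parent2`,
#'   `generation`, `family`, `is_check`), `trait_models`, `config`.
#' @export
simulate_study <- function(config = study_config(),
                           trait_models = NULL) {
  stopifnot(inherits(config, "study_config"))
  withr::local_seed(config$seed)
  if (is.null(trait_models)) {
    trait_models <- default_trait_models(config$n_loci, config$n_blocks,
                                         seed = config$seed)
  }
  for (m in trait_models) {
    if (length(m$additive_effects) != config$n_loci) {
      abort(paste0("trait ", m$name, ": additive effects must match n_loci"))
    }
  }

  founders <- simulate_founders(config$n_founders, config$n_loci,
                                config$maf_min)
  pop <- founders
  for (k in seq_len(config$n_founders)) {
    pop <- bind_pops(pop, self_fertilize(
      founders, founders$id[[k]], config$s1_family_size, config$alpha
    ))
  }
  f1_parents <- list(c(1L, 2L), c(1L, 3L))
  for (pr in f1_parents) {
    pop <- bind_pops(pop, cross_parents(
      founders, founders$id[[pr[1L]]], founders$id[[pr[2L]]],
      config$f1_family_size, config$alpha
    ))
  }

  ped <- dplyr::mutate(pop$pedigree,
                       is_check = .data$generation == "S0")
  test_ids <- ped$id[!ped$is_check]
  check_ids <- ped$id[ped$is_check]

  # layout: each check once per block; test entries randomized over the
  # remaining plots, each in exactly one plot of one block
  n_blocks <- config$n_blocks
  per_block <- config$test_plots_per_block
  assign_block <- setNames(
    rep(seq_len(n_blocks), each = per_block)[seq_along(test_ids)],
    sample(test_ids)
  )
  layout <- dplyr::bind_rows(
    tibble::tibble(
      entry = rep(check_ids, each = n_blocks),
      block = rep(seq_len(n_blocks), times = length(check_ids)),
      is_check = TRUE
    ),
    tibble::tibble(
      entry = names(assign_block),
      block = unname(assign_block),
      is_check = FALSE
    )
  )
  layout <- dplyr::arrange(layout, .data$block, .data$is_check, .data$entry)
  layout <- dplyr::mutate(
    dplyr::group_by(layout, .data$block),
    plot = sprintf("B%d_P%03d", .data$block, dplyr::row_number())
  )
  layout <- dplyr::ungroup(layout)

  gv <- purrr::map(trait_models, function(m) {
    setNames(genetic_values(pop, m)$value, pop$id)
  })
  pheno <- purrr::imap(gv, function(v, nm) {
    m <- trait_models[[nm]]
    be <- rep_len(m$block_effects, config$n_blocks)
    unname(v[layout$entry]) + be[layout$block] +
      rnorm(nrow(layout), 0, m$residual_sd)
  })
  trial <- dplyr::bind_cols(
    layout[, c("entry", "block", "plot", "is_check")],
    tibble::as_tibble(pheno)
  )

  structure(
    list(
      pop = pop, dosage = dosages(pop), trial = trial, pedigree = ped,
      trait_models = trait_models, config = config
    ),
    class = "tetra_study"
  )
}

#' @export
print.tetra_study <- function(x, ...) {
  cat("<tetra_study> ", length(x$pop$id), " individuals, ",
      nrow(x$trial), " plots in ", x$config$n_blocks, " blocks, ",
      length(x$trait_models), " traits\n", sep = "")
  invisible(x)
}

#' Family table of a study pedigree
#'
#' One row per family with its two parents (equal for selfed families);
#' used for relatedness classification in [scheme_cv()].
#'
#' @param pedigree tibble with columns `family`, `parent1`, `parent2`.
#' @return Tibble `family`, `parent1`, `parent2`, `generation`.
#' @export
family_table <- function(pedigree) {
  dplyr::distinct(
    dplyr::filter(pedigree, !is.na(.data$family)),
    .data$family, .data$parent1, .data$parent2, .data$generation
  )
}
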