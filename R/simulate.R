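#' Simulate tetraploid founder genotypes
#'
#' Draws unrelated autotetraploid founders at unlinked biallelic loci. Each
#' locus gets a true allele-1 frequency drawn uniformly on
#' `[maf_min, 1 - maf_min]`, and each founder's four allele copies are
#' independent Bernoulli draws at that frequency (Hardy-Weinberg-like
#' independence; no linkage disequilibrium). Every allele copy receives a
#' fresh founder label so that IBD can be tracked through later meioses.
#'
#' Loci that come out monomorphic across all founder copies are redrawn, so
#' every locus segregates in the sample; the *realized* sample MAF of a
#' locus is nevertheless not guaranteed to be at least `maf_min`, since
#' founders are a finite draw from the generating frequency.
#'
#' @param n_founders number of founder individuals (default 4, the number of
#'   parental cultivars in the motivating trial).
#' @param n_loci number of biallelic SNP loci (default 2000).
#' @param maf_min lower bound for the generating minor-allele frequency,
#'   strictly between 0 and 0.5 (default 0.01).
#' @param seed optional integer; when given, output is reproducible.
#' @return A [tetra_pop][new_tetra_pop] with generation `"S0"`; the true
#'   generating frequencies are kept in `$freq`.
#' @export
#' @examples
#' pop <- simulate_founders(4, 100, seed = 1)
#' range(as.matrix(dosages(pop)[-1]))
simulate_founders <- function(n_founders = 4, n_loci = 2000, maf_min = 0.01,
                              seed = NULL) {
  if (n_founders < 1 || n_loci < 1) abort("counts must be positive")
  if (!is.numeric(maf_min) || maf_min <= 0 || maf_min >= 0.5) {
    abort("`maf_min` must lie strictly between 0 and 0.5")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  p <- runif(n_loci, maf_min, 1 - maf_min)
  draw <- function(pv) {
    lapply(seq_len(n_founders), function(k) {
      matrix(rbinom(length(pv) * 4L, 1L, pv), ncol = 4L)
    })
  }
  states <- draw(p)
  # redraw monomorphic loci so every locus carries variation in the sample
  repeat {
    tot <- Reduce(`+`, lapply(states, rowSums))
    mono <- tot == 0L | tot == 4L * n_founders
    if (!any(mono)) break
    p[mono] <- runif(sum(mono), maf_min, 1 - maf_min)
    redraw <- draw(p[mono])
    for (k in seq_len(n_founders)) states[[k]][mono, ] <- redraw[[k]]
  }

  base <- (seq_len(n_loci) - 1L) * (4L * n_founders)
  labels <- lapply(seq_len(n_founders), function(k) {
    outer(base + (k - 1L) * 4L, seq_len(4L), `+`)
  })
  ids <- sprintf("S0_%d", seq_len(n_founders))
  loci <- sprintf("SNP%04d", seq_len(n_loci))
  new_tetra_pop(
    id = ids, states = states, labels = labels, loci = loci, freq = p,
    pedigree = tibble::tibble(
      id = ids, parent1 = NA_character_, parent2 = NA_character_,
      generation = "S0", family = NA_character_
    )
  )
}

# Sample one gamete (2 of 4 allele copies per locus) from state/label
# matrices. With probability 1 - alpha a locus transmits two copies sampled
# without replacement (all 6 unordered pairs equiprobable: random bivalent
# segregation); with probability alpha it transmits two copies of a single
# uniformly chosen parental copy (double reduction).
PAIRS4 <- utils::combn(4L, 2L)

sample_gamete <- function(states, labels, alpha) {
  n <- nrow(states)
  idx <- sample.int(6L, n, replace = TRUE)
  c1 <- PAIRS4[1L, idx]
  c2 <- PAIRS4[2L, idx]
  if (alpha > 0) {
    dr <- runif(n) < alpha
    if (any(dr)) {
      dcol <- sample.int(4L, sum(dr), replace = TRUE)
      c1[dr] <- dcol
      c2[dr] <- dcol
    }
  }
  rows <- seq_len(n)
  list(
    states = cbind(states[cbind(rows, c1)], states[cbind(rows, c2)]),
    labels = cbind(labels[cbind(rows, c1)], labels[cbind(rows, c2)])
  )
}

#' Draw a single gamete from a parent
#'
#' Tetrasomic segregation: at each locus, with probability `1 - alpha` the
#' gamete receives 2 of the parent's 4 allele copies sampled without
#' replacement (each of the C(4,2) = 6 pairs with probability 1/6), and with
#' probability `alpha` it receives two copies of one uniformly chosen
#' parental copy (double reduction). `alpha = 0` is pure random bivalent
#' segregation.
#'
#' @param pop a [tetra_pop][new_tetra_pop].
#' @param id id of the parent (default: first individual).
#' @param alpha per-locus double-reduction probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return A list with `states` and `labels`, each an `n_loci x 2` matrix,
#'   plus `dosage`, the per-locus gamete dosage in 0..2.
#' @export
make_gamete <- function(pop, id = pop$id[[1L]], alpha = 0, seed = NULL) {
  stopifnot(inherits(pop, "tetra_pop"))
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (!id %in% pop$id) abort(paste0("unknown parent id: ", id))
  if (!is.null(seed)) withr::local_seed(seed)
  g <- sample_gamete(pop$states[[id]], pop$labels[[id]], alpha)
  g$dosage <- rowSums(g$states)
  g
}

offspring_from <- function(pop, id1, id2, n_offspring, alpha, prefix,
                           generation, family) {
  s1 <- pop$states[[id1]]
  l1 <- pop$labels[[id1]]
  s2 <- pop$states[[id2]]
  l2 <- pop$labels[[id2]]
  states <- vector("list", n_offspring)
  labels <- vector("list", n_offspring)
  for (k in seq_len(n_offspring)) {
    ga <- sample_gamete(s1, l1, alpha)
    gb <- sample_gamete(s2, l2, alpha)
    states[[k]] <- cbind(ga$states, gb$states)
    labels[[k]] <- cbind(ga$labels, gb$labels)
  }
  ids <- sprintf("%s_%03d", prefix, seq_len(n_offspring))
  new_tetra_pop(
    id = ids, states = states, labels = labels, loci = pop$loci,
    freq = pop$freq,
    pedigree = tibble::tibble(
      id = ids, parent1 = id1, parent2 = id2,
      generation = generation, family = family
    )
  )
}

#' Self-fertilize a parent
#'
#' Each offspring is the union of two independent gametes drawn from the
#' same parent. Founder labels are preserved, so the offspring's realized
#' inbreeding ([realized_inbreeding()]) can be read off directly; for a
#' non-inbred parent and `alpha = 0` its expectation is 1/6.
#'
#' @inheritParams make_gamete
#' @param n_offspring number of S1 offspring (at least 1).
#' @param family family tag recorded in the pedigree (default
#'   `paste0("S1_", id)`).
#' @return A [tetra_pop][new_tetra_pop] of S1 offspring.
#' @export
self_fertilize <- function(pop, id = pop$id[[1L]], n_offspring, alpha = 0,
                           seed = NULL, family = paste0("S1_", id)) {
  stopifnot(inherits(pop, "tetra_pop"))
  if (n_offspring < 1) abort("`n_offspring` must be at least 1")
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (!id %in% pop$id) abort(paste0("unknown parent id: ", id))
  if (!is.null(seed)) withr::local_seed(seed)
  offspring_from(pop, id, id, n_offspring, alpha,
                 prefix = family, generation = "S1", family = family)
}

#' Cross two parents
#'
#' Each offspring is the union of one gamete from each parent.
#'
#' @inheritParams self_fertilize
#' @param id1,id2 ids of the two parents (female first).
#' @export
cross_parents <- function(pop, id1, id2, n_offspring, alpha = 0, seed = NULL,
                          family = paste0("F1_", id1, "x", id2)) {
  stopifnot(inherits(pop, "tetra_pop"))
  if (n_offspring < 1) abort("`n_offspring` must be at least 1")
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (!all(c(id1, id2) %in% pop$id)) abort("unknown parent id")
  if (!is.null(seed)) withr::local_seed(seed)
  offspring_from(pop, id1, id2, n_offspring, alpha,
                 prefix = family, generation = "F1", family = family)
}

#' Exact gamete-dosage distribution under tetrasomic segregation
#'
#' Enumerates the sampling rule of [make_gamete()] for a parent carrying
#' `parent_dosage` copies of allele 1: all 6 unordered pairs (weight
#' `1 - alpha`) plus the 4 double-reduction outcomes (weight `alpha`).
#'
#' @param parent_dosage integer 0..4.
#' @param alpha double-reduction probability.
#' @return Named numeric vector of probabilities over gamete dosage 0, 1, 2.
#' @export
gamete_dosage_distribution <- function(parent_dosage, alpha = 0) {
  stopifnot(parent_dosage %in% 0:4, alpha >= 0, alpha <= 1)
  s <- c(rep(1L, parent_dosage), rep(0L, 4L - parent_dosage))
  pr <- c(`0` = 0, `1` = 0, `2` = 0)
  for (k in seq_len(ncol(PAIRS4))) {
    d <- s[PAIRS4[1L, k]] + s[PAIRS4[2L, k]]
    pr[d + 1L] <- pr[d + 1L] + (1 - alpha) / 6
  }
  for (c in 1:4) pr[2L * s[c] + 1L] <- pr[2L * s[c] + 1L] + alpha / 4
  pr
}
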