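# shared fixtures and independent oracles, built in code at test time

# independent enumeration of the tetrasomic gamete rule for a parent with
# explicit allele states: all C(4,2) pairs (weight 1 - alpha) and the four
# single-copy duplications (weight alpha)
oracle_gamete_dist <- function(states, alpha) {
  pr <- c(`0` = 0, `1` = 0, `2` = 0)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      d <- states[i] + states[j]
      pr[d + 1] <- pr[d + 1] + (1 - alpha) / 6
    }
  }
  for (i in 1:4) {
    d <- 2 * states[i]
    pr[d + 1] <- pr[d + 1] + alpha / 4
  }
  pr
}

# a single-parent population with every locus at the same dosage class,
# so one gamete draw yields n_loci iid per-locus samples
uniform_dosage_parent <- function(dosage, n_loci, id = "P",
                                  label_offset = 0L) {
  states <- matrix(rep(c(rep(1L, dosage), rep(0L, 4L - dosage)),
                       each = n_loci), ncol = 4L)
  labels <- matrix(seq_len(4L * n_loci) + label_offset, ncol = 4L)
  tetragp:::new_tetra_pop(
    id = id, states = list(states), labels = list(labels),
    loci = sprintf("L%d", seq_len(n_loci))
  )
}

# toy augmented trial: 2 blocks x 2 checks plus one test plot, hand numbers
toy_trial_2x2 <- function() {
  tibble::tibble(
    entry = c("c1", "c2", "t1", "c1", "c2"),
    block = c(1L, 1L, 1L, 2L, 2L),
    plot = paste0("p", 1:5),
    is_check = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    y = c(10, 14, 20, 6, 10)
  )
}

# null augmented trial: iid N(0, sd) values, g checks x r blocks plus tests
null_trial <- function(g = 3, r = 9, tests_per_block = 10, sd = 1) {
  checks <- tidyr::expand_grid(entry = paste0("c", seq_len(g)),
                               block = seq_len(r))
  tests <- tibble::tibble(
    entry = paste0("t", seq_len(r * tests_per_block)),
    block = rep(seq_len(r), each = tests_per_block)
  )
  trial <- dplyr::bind_rows(
    dplyr::mutate(checks, is_check = TRUE),
    dplyr::mutate(tests, is_check = FALSE)
  )
  trial$plot <- paste0("p", seq_len(nrow(trial)))
  trial$y <- rnorm(nrow(trial), 0, sd)
  trial
}

# pedigree assigning S1/F1 generations to the test entries of null_trial()
null_pedigree <- function(trial) {
  ids <- unique(trial$entry)
  is_check <- ids %in% trial$entry[trial$is_check]
  tibble::tibble(
    id = ids, parent1 = NA_character_, parent2 = NA_character_,
    generation = ifelse(is_check, "S0",
                        rep(c("S1", "F1"), length.out = length(ids))),
    family = NA_character_
  )
}

# six-family design (4 x S1, 2 half-sib F1 sharing founder 1) built from
# exported simulation functions
six_family_pop <- function(n_loci = 400, fam_size = 40, maf_min = 0.05,
                           seed = 1, alpha = 0) {
  f <- simulate_founders(4, n_loci, maf_min = maf_min, seed = seed)
  pop <- f
  for (k in 1:4) {
    pop <- bind_pops(pop, self_fertilize(f, f$id[k], fam_size, alpha = alpha,
                                         seed = seed * 10L + k))
  }
  pop <- bind_pops(pop, cross_parents(f, "S0_1", "S0_2", fam_size,
                                      alpha = alpha, seed = seed * 10L + 5L))
  pop <- bind_pops(pop, cross_parents(f, "S0_1", "S0_3", fam_size,
                                      alpha = alpha, seed = seed * 10L + 6L))
  pop
}

# dense-grid REML oracle: restricted log-likelihood evaluated with generic
# dense linear algebra (determinants and solves), no eigendecomposition
reml_ll_dense <- function(lambda, y, G) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- lambda * G + diag(n)
  Vi <- solve(V)
  XVX <- drop(t(X) %*% Vi %*% X)
  mu <- drop(t(X) %*% Vi %*% y) / XVX
  r <- y - mu
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 1)
  -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus + log(XVX))
}

grid_search_lambda <- function(y, G, n_coarse = 2001, n_fine = 4001) {
  lg <- seq(log(1e-4), log(1e4), length.out = n_coarse)
  ll <- vapply(lg, function(l) reml_ll_dense(exp(l), y, G), numeric(1))
  k <- which.max(ll)
  lo <- lg[max(k - 2L, 1L)]
  hi <- lg[min(k + 2L, n_coarse)]
  lg2 <- seq(lo, hi, length.out = n_fine)
  ll2 <- vapply(lg2, function(l) reml_ll_dense(exp(l), y, G), numeric(1))
  exp(lg2[which.max(ll2)])
}
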