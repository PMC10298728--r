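#' Labeled tetraploid populations
#'
#' A `tetra_pop` holds, for each individual, the allelic *state* (0/1) and an
#' integer *founder label* for each of the four allele copies at every locus.
#' Labels are unique per founder allele copy at creation, so identity of two
#' labels at the same locus means identity by descent (IBD). Dosage at a locus
#' is the number of state-1 copies, i.e. an integer in 0..4 (nulliplex,
#' simplex, duplex, triplex, quadriplex).
#'
#' @param id character vector of individual ids.
#' @param states list (one element per individual) of `n_loci x 4` 0/1
#'   integer matrices.
#' @param labels list of `n_loci x 4` integer matrices, same shape as
#'   `states`.
#' @param loci character vector of locus (SNP) ids.
#' @param freq optional numeric vector of the *generating* allele-1
#'   frequencies per locus (known for simulated founders, `NULL` otherwise).
#' @param pedigree tibble with columns `id`, `parent1`, `parent2`,
#'   `generation`, `family`.
#'
#' @return An object of class `tetra_pop`.
#' @keywords internal
new_tetra_pop <- function(id, states, labels, loci, freq = NULL,
                          pedigree = NULL) {
  stopifnot(length(id) == length(states), length(id) == length(labels))
  if (anyDuplicated(id)) {
    abort("duplicate individual ids in population")
  }
  if (is.null(pedigree)) {
    pedigree <- tibble::tibble(
      id = id, parent1 = NA_character_, parent2 = NA_character_,
      generation = "S0", family = NA_character_
    )
  }
  structure(
    list(
      id = id, states = setNames(states, id), labels = setNames(labels, id),
      loci = loci, freq = freq, pedigree = pedigree
    ),
    class = "tetra_pop"
  )
}

#' @export
print.tetra_pop <- function(x, ...) {
  gens <- table(x$pedigree$generation)
  cat(
    "<tetra_pop> ", length(x$id), " individuals x ", length(x$loci),
    " loci (ploidy 4)\n", sep = ""
  )
  cat("  generations:", paste(names(gens), gens, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.tetra_pop <- function(x) length(x$id)

#' Extract allele dosages from a population
#'
#' @param pop a [tetra_pop][new_tetra_pop] object.
#' @return A wide tibble: column `id` followed by one integer column per
#'   locus, entries in 0..4.
#' @export
#' @examples
#' pop <- simulate_founders(n_founders = 2, n_loci = 5, seed = 1)
#' dosages(pop)
dosages <- function(pop) {
  stopifnot(inherits(pop, "tetra_pop"))
  mat <- t(vapply(pop$states, rowSums, numeric(length(pop$loci))))
  if (length(pop$loci) == 1L) mat <- matrix(mat, ncol = 1L)
  colnames(mat) <- pop$loci
  dplyr::bind_cols(tibble::tibble(id = pop$id), tibble::as_tibble(mat))
}

#' Realized IBD-based inbreeding coefficients
#'
#' The realized inbreeding coefficient of an individual is the proportion of
#' the 6 unordered within-individual allele pairs per locus that carry the
#' same founder label, averaged over loci. For the offspring of one
#' tetrasomic selfing of a non-inbred parent (no double reduction) its
#' expectation is 1/6.
#'
#' @param pop a [tetra_pop][new_tetra_pop] object.
#' @return A tibble with columns `id` and `f_ibd` in \[0, 1\].
#' @export
realized_inbreeding <- function(pop) {
  stopifnot(inherits(pop, "tetra_pop"))
  pairs <- utils::combn(4L, 2L)
  f <- vapply(pop$labels, function(lb) {
    hits <- 0L
    for (k in seq_len(ncol(pairs))) {
      hits <- hits + sum(lb[, pairs[1L, k]] == lb[, pairs[2L, k]])
    }
    hits / (6 * nrow(lb))
  }, numeric(1))
  tibble::tibble(id = pop$id, f_ibd = unname(f))
}

#' Combine two populations that share the same loci
#'
#' @param x,y [tetra_pop][new_tetra_pop] objects over identical loci.
#' @return A single `tetra_pop`; generating frequencies are kept when both
#'   agree.
#' @export
bind_pops <- function(x, y) {
  stopifnot(inherits(x, "tetra_pop"), inherits(y, "tetra_pop"))
  if (!identical(x$loci, y$loci)) abort("populations have different loci")
  freq <- if (identical(x$freq, y$freq)) x$freq else NULL
  new_tetra_pop(
    id = c(x$id, y$id),
    states = c(x$states, y$states),
    labels = c(x$labels, y$labels),
    loci = x$loci, freq = freq,
    pedigree = dplyr::bind_rows(x$pedigree, y$pedigree)
  )
}

#' Subset a population by individual id
#'
#' @param pop a [tetra_pop][new_tetra_pop] object.
#' @param ids character vector of ids to keep, in the order given.
#' @return A `tetra_pop` restricted to `ids`.
#' @export
subset_pop <- function(pop, ids) {
  stopifnot(inherits(pop, "tetra_pop"))
  missing <- setdiff(ids, pop$id)
  if (length(missing) > 0) {
    abort(paste0("unknown individual id(s): ", paste(missing, collapse = ", ")))
  }
  new_tetra_pop(
    id = ids, states = pop$states[ids], labels = pop$labels[ids],
    loci = pop$loci, freq = pop$freq,
    pedigree = pop$pedigree[match(ids, pop$pedigree$id), ]
  )
}
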