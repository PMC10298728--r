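#' Per-locus allele frequencies from tetraploid dosages
#'
#' The frequency of the counted (ALT) allele at a locus is the mean dosage
#' over non-missing individuals divided by the ploidy (4).
#'
#' @param dosage wide dosage tibble (`id` + SNP columns).
#' @return Tibble with columns `snp`, `p`, `maf`, `n_obs`.
#' @export
allele_frequencies <- function(dosage) {
  m <- as.matrix(dosage[-1L])
  p <- colMeans(m, na.rm = TRUE) / 4
  tibble::tibble(
    snp = colnames(m), p = unname(p), maf = pmin(p, 1 - p),
    n_obs = unname(colSums(!is.na(m)))
  )
}

#' Genomic relationship matrix for autotetraploids
#'
#' Builds an additive genomic relationship matrix from allele dosages
#' (0..4). Two scalings are available:
#'
#' * `full_tetraploid` — the tetraploid extension of VanRaden's matrix:
#'   centered scores `w_ij = dosage_ij - 4 p_j` and
#'   `G = W W' / sum_j 4 p_j (1 - p_j)`. Under Hardy-Weinberg segregation
#'   `Var(dosage) = 4pq(1 + 3F)`, so the expected diagonal is `1 + 3F`
#'   (1 for non-inbred individuals, 1.5 after one tetrasomic selfing) and
#'   a relationship entry estimates 4x the co-ancestry.
#' * `pseudodiploid` — dosages halved onto the 0..2 diploid scale and the
#'   diploid VanRaden form applied: `w_ij = dosage_ij/2 - 2 p_j`,
#'   denominator `sum_j 2 p_j (1 - p_j)`.
#'
#' Loci are filtered to `maf >= maf_min` before construction. When the true
#' generating frequencies are known (simulation), pass them via `freq`;
#' otherwise frequencies are estimated from the sample, which biases the
#' matrix slightly when the sample is small or structured.
#'
#' `repair = TRUE` clamps negative eigenvalues at zero and blends
#' `G* = 0.99 G + 0.01 I`, guaranteeing a positive-definite matrix for
#' downstream solvers; off by default and recorded in the object.
#'
#' @param dosage wide dosage tibble with no missing values (run
#'   [impute_missing()] first if needed).
#' @param method `"full_tetraploid"` (default) or `"pseudodiploid"`.
#' @param maf_min minimum minor-allele frequency for a locus to be used.
#' @param freq optional numeric vector of known allele frequencies, one per
#'   SNP column (named or in column order).
#' @param repair logical: clamp eigenvalues at 0 and blend with 0.01 I.
#' @return Object of class `tetra_grm`: list with `mat` (named square
#'   matrix), `ids`, `method`, `n_loci_used`, `freq` (frequencies of the
#'   loci used), `repaired`. Has [tidy()] and [autoplot()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(id = c("a", "b"), s1 = c(0, 4))
#' build_grm(d, maf_min = 0.4)$mat   # [[4, -4], [-4, 4]]
build_grm <- function(dosage, method = c("full_tetraploid", "pseudodiploid"),
                      maf_min = 0.01, freq = NULL, repair = FALSE) {
  method <- match.arg(method)
  m <- as.matrix(dosage[-1L])
  rownames(m) <- dosage$id
  if (anyNA(m)) {
    abort("dosage matrix contains missing values; run impute_missing() first")
  }
  if (is.null(freq)) {
    p <- colMeans(m) / 4
  } else {
    if (length(freq) != ncol(m)) {
      abort("`freq` must supply one frequency per SNP column")
    }
    p <- if (!is.null(names(freq))) freq[colnames(m)] else freq
  }
  keep <- pmin(p, 1 - p) >= maf_min
  if (!any(keep)) abort("no loci left after MAF filtering")
  m <- m[, keep, drop = FALSE]
  p <- p[keep]

  if (method == "full_tetraploid") {
    w <- sweep(m, 2L, 4 * p)
    denom <- sum(4 * p * (1 - p))
  } else {
    w <- sweep(m / 2, 2L, 2 * p)
    denom <- sum(2 * p * (1 - p))
  }
  if (denom <= 0) abort("all retained loci are monomorphic; denominator is 0")
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2

  if (repair) {
    e <- eigen(g, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    g <- e$vectors %*% (vals * t(e$vectors))
    g <- 0.99 * (g + t(g)) / 2 + 0.01 * diag(nrow(g))
    dimnames(g) <- list(dosage$id, dosage$id)
  }

  structure(
    list(mat = g, ids = dosage$id, method = method,
         n_loci_used = sum(keep), freq = p, repaired = repair),
    class = "tetra_grm"
  )
}

#' @export
print.tetra_grm <- function(x, ...) {
  cat("<tetra_grm> ", length(x$ids), " individuals, ", x$n_loci_used,
      " loci, method = ", x$method,
      if (x$repaired) ", PSD-repaired" else "", "\n", sep = "")
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.3f\n",
              mean(diag(x$mat)),
              mean(x$mat[upper.tri(x$mat)])))
  invisible(x)
}

#' @export
tidy.tetra_grm <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$mat, responseName = "value",
                                        stringsAsFactors = FALSE)) |>
    dplyr::rename(id1 = "Var1", id2 = "Var2")
}

#' @export
autoplot.tetra_grm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$id1, .data$id2, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "G") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write a relationship matrix to disk
#'
#' @param grm a [build_grm()] object.
#' @param path output path.
#' @param format `"csv"` (square, header row of ids, first column id) or
#'   `"tsv_long"` (`id1`, `id2`, `value`).
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path, format = c("csv", "tsv_long")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- dplyr::bind_cols(tibble::tibble(id = grm$ids),
                            tibble::as_tibble(grm$mat))
    readr::write_csv(out, path)
  } else {
    readr::write_tsv(tidy(grm), path)
  }
  invisible(path)
}

#' Read a square relationship matrix written by [write_grm()]
#'
#' @param path CSV path (square format).
#' @return A `tetra_grm` with method `"loaded"`.
#' @export
read_grm_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(d[-1L])
  dimnames(m) <- list(d$id, colnames(m))
  structure(
    list(mat = m, ids = d$id, method = "loaded", n_loci_used = NA_integer_,
         freq = NULL, repaired = FALSE),
    class = "tetra_grm"
  )
}

#' Compare realized relationships with pedigree expectations
#'
#' For a simulated population with known pedigree, summarizes the realized
#' `full_tetraploid` relationship entries against their IBD expectations:
#' diagonal `1 + 3F` (1 for founders and outcross F1, 1.5 for S1 at
#' F = 1/6), parent vs selfed offspring 1.0 (co-ancestry 1/4), parent vs
#' outcross offspring 0.5 (co-ancestry 1/8) and unrelated founder pairs 0.
#'
#' @param grm a [build_grm()] object over the population.
#' @param pedigree tibble `id`, `parent1`, `parent2`, `generation`.
#' @return Tibble `quantity`, `expected`, `observed`, `n`.
#' @export
expected_relationship_checks <- function(grm, pedigree) {
  g <- grm$mat
  ped <- dplyr::filter(pedigree, .data$id %in% grm$ids)
  dg <- diag(g)[ped$id]
  rows <- list()
  for (gen in c("S0", "S1", "F1")) {
    sel <- ped$generation == gen
    if (!any(sel)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = paste0("diag_", gen),
      expected = if (gen == "S1") 1.5 else 1.0,
      observed = mean(dg[sel]), n = sum(sel)
    )
  }
  kids <- dplyr::filter(ped, !is.na(.data$parent1),
                        .data$parent1 %in% grm$ids)
  if (nrow(kids) > 0) {
    selfed <- kids$parent1 == kids$parent2
    po <- g[cbind(kids$id, kids$parent1)]
    if (any(selfed)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quantity = "parent_selfed_offspring", expected = 1.0,
        observed = mean(po[selfed]), n = sum(selfed)
      )
    }
    if (any(!selfed)) {
      po2 <- c(po[!selfed], g[cbind(kids$id[!selfed], kids$parent2[!selfed])])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        quantity = "parent_outcross_offspring", expected = 0.5,
        observed = mean(po2), n = length(po2)
      )
    }
  }
  founders <- ped$id[ped$generation == "S0"]
  if (length(founders) > 1) {
    fm <- g[founders, founders]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "unrelated_founder_pair", expected = 0,
      observed = mean(fm[upper.tri(fm)]),
      n = sum(upper.tri(fm))
    )
  }
  dplyr::bind_rows(rows)
}
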