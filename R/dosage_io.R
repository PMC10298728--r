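#' Read an allele-dosage matrix from CSV
#'
#' Expects a rectangular comma-separated table: first column the individual
#' id, remaining columns one SNP each, entries integer dosages 0..4 (count
#' of alternative alleles in the tetraploid genotype) or `NA` for missing.
#' Validation is total: any out-of-range or non-integer cell aborts the read
#' with the offending individual and SNP named, and nothing is returned.
#'
#' @param path file path.
#' @return A wide tibble (`id` + one integer column per SNP) with attribute
#'   `"n_missing"`, the count of missing cells.
#' @export
read_dosage_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()
                         ),
                         name_repair = "minimal", na = character())
  names(raw)[1L] <- "id"
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L,
                                     dimnames = list(NULL, names(raw)[-1L]))
  bad <- which(is.na(num) & !(raw[-1L] == "NA" | raw[-1L] == ""),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric dosage '%s' at individual '%s', SNP '%s'",
      as.character(raw[-1L][[bad[1L, 2L]]][bad[1L, 1L]]),
      raw$id[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]
    ))
  }
  d <- dplyr::bind_cols(tibble::tibble(id = as.character(raw$id)),
                        tibble::as_tibble(num))
  validate_dosage_tbl(d)
}

validate_dosage_tbl <- function(d) {
  if (anyDuplicated(d$id)) abort("duplicate individual ids in dosage table")
  if (anyDuplicated(names(d)[-1L])) abort("duplicate SNP ids in dosage table")
  m <- as.matrix(d[-1L])
  bad <- which(!is.na(m) & (m < 0 | m > 4 | m != round(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "invalid dosage %s at individual '%s', SNP '%s' (must be integer 0..4)",
      format(m[bad[1L, , drop = FALSE]]), d$id[bad[1L, 1L]],
      colnames(m)[bad[1L, 2L]]
    ))
  }
  attr(d, "n_missing") <- sum(is.na(m))
  d
}

#' Write an allele-dosage matrix to CSV
#'
#' @param dosage wide dosage tibble as returned by [dosages()] or
#'   [read_dosage_csv()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(dosage, path) {
  readr::write_csv(dosage, path, na = "NA")
  invisible(path)
}

#' Read tetraploid genotypes from a VCF file
#'
#' Parses VCF v4.2 with tetraploid GT calls such as `0/1/1/1`; dosage is the
#' count of ALT alleles among the four calls (phasing and allele order are
#' ignored). A `DS` FORMAT field, when present, overrides the GT-derived
#' dosage. Records with more than one ALT allele are rejected, as is any GT
#' whose ploidy is not 4. Fully missing GTs (`./././.`) become `NA`.
#'
#' @param path VCF file path (plain text).
#' @return A wide dosage tibble as from [read_dosage_csv()].
#' @export
#' @examples
#' vcf <- system.file("extdata", "example_tetraploid.vcf",
#'                    package = "tetragp")
#' read_vcf_tetraploid(vcf)
read_vcf_tetraploid <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    abort(sprintf("multi-allelic record at %s:%s; only biallelic SNPs supported",
                  fix[which(grepl(",", alt))[1L], "CHROM"],
                  fix[which(grepl(",", alt))[1L], "POS"]))
  }
  snp_id <- fix[, "ID"]
  blank <- is.na(snp_id) | snp_id == "."
  snp_id[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1L,
                 dimnames = list(NULL, setdiff(colnames(v@gt), "FORMAT")))
  }
  parse_gt <- function(g, where) {
    if (is.na(g) || g == ".") return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 4L) {
      abort(sprintf("ploidy mismatch at %s: GT '%s' has %d alleles, expected 4",
                    where, g, length(al)))
    }
    if (all(al == ".")) return(NA_real_)
    if (!all(al %in% c("0", "1"))) {
      abort(sprintf("unsupported allele in GT '%s' at %s", g, where))
    }
    sum(al == "1")
  }
  dose <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      dose[i, j] <- parse_gt(gt[i, j],
                             paste0(snp_id[i], "/", colnames(gt)[j]))
    }
  }
  if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ds <- suppressWarnings(
      vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    )
    dose[!is.na(ds)] <- ds[!is.na(ds)]
  }
  out <- dplyr::bind_cols(
    tibble::tibble(id = colnames(dose)),
    tibble::as_tibble(t(dose))
  )
  names(out) <- c("id", snp_id)
  validate_dosage_tbl(out)
}

#' Write tetraploid genotypes to VCF
#'
#' Emits a minimal VCF v4.2 with one biallelic record per SNP, an unphased
#' tetraploid GT (`0/1/1/1` style, ALT copies last) and a DS dosage field.
#' Missing dosages become `./././.`.
#'
#' @param dosage wide dosage tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_tetraploid <- function(dosage, path) {
  m <- as.matrix(dosage[-1L])
  ids <- dosage$id
  snps <- colnames(m)
  gt_of <- function(d) {
    if (is.na(d)) return("./././.:.")
    paste0(paste(c(rep("0", 4 - d), rep("1", d)), collapse = "/"), ":", d)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetragp",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_along(snps), function(j) {
    dj <- round(m[, j])
    paste(c("1", j, snps[j], "A", "T", ".", ".", ".", "GT:DS",
            vapply(dj, gt_of, character(1))), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Impute missing dosages by locus mean
#'
#' Missing entries are replaced by the mean dosage of their locus over
#' non-missing individuals (so the matrix becomes real-valued). Loci that
#' are missing for every individual carry no information and are dropped
#' with a warning stating the count.
#'
#' @param dosage wide dosage tibble (may contain `NA`).
#' @return Wide dosage tibble with no missing values.
#' @export
impute_missing <- function(dosage) {
  m <- as.matrix(dosage[-1L])
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warn(sprintf("dropping %d all-missing loci", sum(all_na)))
    m <- m[, !all_na, drop = FALSE]
  }
  for (j in which(colSums(is.na(m)) > 0L)) {
    m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  dplyr::bind_cols(tibble::tibble(id = dosage$id), tibble::as_tibble(m))
}
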