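#' Genotype matrix container
#'
#' A `genotype_matrix` bundles the per-site records of a multi-sample
#' callset with aligned sites x individuals matrices of diploid genotype
#' codes and per-genotype quality annotations. Genotype codes are
#' `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate) and `NA` (missing). Sites are kept sorted by
#' (chromosome, position); coordinates are 1-based inclusive throughout.
#'
#' @param sites A tibble with one row per site and columns `chrom`,
#'   `pos`, `ref`, `alt` (`NA` for invariant sites), `site_type`
#'   (`"snp"`, `"invariant"` or `"indel"`), `qual`, and the INFO
#'   annotations `qd`, `fs`, `mq`, `mq_rank_sum`, `read_pos_rank_sum`,
#'   `dp`. Missing annotation columns are added as `NA`.
#' @param gt Integer matrix (sites x individuals) of genotype codes.
#' @param dp Numeric matrix of per-genotype sequencing depth (DP).
#' @param gq Numeric matrix of per-genotype quality: GQ at SNP sites,
#'   RGQ at invariant sites.
#' @param populations A tibble with columns `sample` and `population`
#'   covering every column of `gt`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, gt, dp = NULL, gq = NULL, populations) {
  sites <- tibble::as_tibble(sites)
  needed <- c("chrom", "pos", "ref", "alt", "site_type", "qual",
              "qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum", "dp")
  for (col in setdiff(needed, names(sites))) sites[[col]] <- NA_real_
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  stopifnot(all(sites$pos >= 1L, na.rm = TRUE))

  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites)) {
    stop("`gt` must have one row per site", call. = FALSE)
  }
  samples <- colnames(gt)
  if (is.null(samples)) stop("`gt` must have sample column names", call. = FALSE)
  if (!all(gt %in% c(0L, 1L, 2L) | is.na(gt))) {
    stop("genotype codes must be 0, 1, 2 or NA (diploid calls only)",
         call. = FALSE)
  }
  storage.mode(gt) <- "integer"

  blank <- function(m) {
    if (is.null(m)) {
      m <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    }
    m <- as.matrix(m)
    stopifnot(dim(m)[1] == nrow(gt), dim(m)[2] == ncol(gt))
    storage.mode(m) <- "double"
    colnames(m) <- samples
    m
  }
  dp <- blank(dp)
  gq <- blank(gq)
  rownames(gt) <- rownames(dp) <- rownames(gq) <- NULL

  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("sample", "population") %in% names(populations)))
  missing_pop <- setdiff(samples, populations$sample)
  if (length(missing_pop) > 0) {
    stop("sample(s) without a population label: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  populations <- populations[match(samples, populations$sample), ]

  ord <- order(sites$chrom, sites$pos)
  obj <- structure(
    list(sites = sites[ord, , drop = FALSE],
         gt = gt[ord, , drop = FALSE],
         dp = dp[ord, , drop = FALSE],
         gq = gq[ord, , drop = FALSE],
         samples = samples,
         populations = populations),
    class = "genotype_matrix")
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$sites$site_type)
  cat("<genotype_matrix> ", nrow(x$sites), " sites x ", length(x$samples),
      " individuals\n", sep = "")
  cat("  site types: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  populations: ",
      paste(sort(unique(x$populations$population)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Numbers of sites and samples
#' @param x A `genotype_matrix`.
#' @return An integer scalar.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Samples belonging to one or more populations
#' @param x A `genotype_matrix`.
#' @param populations Character vector of population labels.
#' @return Character vector of sample identifiers.
#' @export
population_samples <- function(x, populations) {
  x$populations$sample[x$populations$population %in% populations]
}

# Row-subset every aligned component; keeps class invariants.
subset_sites <- function(x, idx) {
  x$sites <- x$sites[idx, , drop = FALSE]
  x$gt <- x$gt[idx, , drop = FALSE]
  x$dp <- x$dp[idx, , drop = FALSE]
  x$gq <- x$gq[idx, , drop = FALSE]
  x
}

# Column-subset to a set of samples.
subset_samples <- function(x, samples) {
  keep <- match(samples, x$samples)
  stopifnot(!anyNA(keep))
  x$gt <- x$gt[, keep, drop = FALSE]
  x$dp <- x$dp[, keep, drop = FALSE]
  x$gq <- x$gq[, keep, drop = FALSE]
  x$samples <- x$samples[keep]
  x$populations <- x$populations[keep, , drop = FALSE]
  x
}

#' Subset a genotype matrix to a genomic region
#'
#' Returns the sites with `start <= pos <= end` on `chromosome`
#' (1-based inclusive bounds), order preserved. Used e.g. to count SNPs
#' inside candidate loci such as MHC exons.
#'
#' @param x A `genotype_matrix`.
#' @param chromosome Chromosome identifier.
#' @param start,end Inclusive 1-based bounds, `start <= end`.
#' @return A `genotype_matrix` restricted to the region (possibly with
#'   zero sites; a warning is emitted when `chromosome` is absent).
#' @export
subset_region <- function(x, chromosome, start, end) {
  stopifnot(start <= end)
  if (!chromosome %in% x$sites$chrom) {
    warning("chromosome '", chromosome, "' not present; returning empty matrix",
            call. = FALSE)
  }
  keep <- x$sites$chrom == chromosome &
    x$sites$pos >= start & x$sites$pos <= end
  subset_sites(x, which(keep))
}

#' Genotypes as a tidy tibble
#'
#' Long-format view of the genotype calls: one row per site x individual,
#' joined with the population labels.
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `pos`, `sample`, `population`,
#'   `genotype`.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  gt <- x$gt
  tibble::tibble(
    chrom = rep(x$sites$chrom, times = ncol(gt)),
    pos = rep(x$sites$pos, times = ncol(gt)),
    sample = rep(colnames(gt), each = nrow(gt)),
    genotype = as.integer(gt)
  ) |>
    dplyr::left_join(x$populations, by = "sample") |>
    dplyr::relocate("population", .after = "sample")
}
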