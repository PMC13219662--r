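#' Hard-filter configuration
#'
#' Site- and genotype-level thresholds for filtering already-called
#' variants, mirroring a GATK-style hard-filter recipe: SNP records fail
#' on `QUAL < 60`, `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `MQRankSum < -20.0` or `ReadPosRankSum < -8.0`; indels are kept only
#' when `QUAL >= 60` and then only to mask SNPs within 5 bp of them;
#' genotypes are set to missing on `GQ < 10` (SNPs), `RGQ < 10`
#' (invariant sites) or a depth outside `(mean/3, mean*2)` exclusive
#' bounds relative to that sample's mean depth; sites with more than 25%
#' missing genotypes after masking are dropped.
#'
#' Set a threshold to `NA` to disable that rule. Note one deliberate
#' departure from GATK semantics: when an enabled site rule needs an
#' INFO key that a record lacks, the record *fails* that rule (the event
#' is counted in the report) instead of passing silently.
#'
#' @param min_qual Minimum SNP (and indel) QUAL.
#' @param min_qd Minimum quality-by-depth.
#' @param max_fs Maximum Fisher-strand phred score.
#' @param min_mq Minimum RMS mapping quality.
#' @param min_mqranksum,min_readposranksum Minimum rank-sum statistics.
#' @param depth_low_factor,depth_high_factor Per-genotype depth bounds
#'   as multiples of the sample's mean depth; a genotype fails only if
#'   `DP < mean * depth_low_factor` or `DP > mean * depth_high_factor`
#'   (strict inequalities).
#' @param min_gq,min_rgq Minimum genotype quality for SNP and invariant
#'   genotypes respectively.
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   genotypes per site.
#' @param indel_window_bp SNPs within this distance of a surviving
#'   (high-quality) indel are removed.
#' @param excluded_regions Tibble of `chrom`, `start`, `end` (1-based
#'   inclusive) regions to drop, e.g. repeats or high-heterozygosity
#'   regions; see [read_bed_regions()].
#' @param excluded_chromosomes Chromosomes dropped outright (e.g. the
#'   Z and W sex chromosomes when restricting to autosomes).
#' @param missingness_before_masking If `TRUE`, evaluate the
#'   missing-data rule on the genotypes as read rather than after
#'   GQ/depth masking.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 60, min_qd = 2.0, max_fs = 60.0,
                          min_mq = 40.0, min_mqranksum = -20.0,
                          min_readposranksum = -8.0,
                          depth_low_factor = 1 / 3, depth_high_factor = 2,
                          min_gq = 10, min_rgq = 10,
                          max_missing_fraction = 0.25,
                          indel_window_bp = 5L,
                          excluded_regions = NULL,
                          excluded_chromosomes = character(),
                          missingness_before_masking = FALSE) {
  stopifnot(is.na(max_missing_fraction) ||
              (max_missing_fraction >= 0 && max_missing_fraction <= 1),
            indel_window_bp >= 0)
  structure(list(
    min_qual = min_qual, min_qd = min_qd, max_fs = max_fs, min_mq = min_mq,
    min_mqranksum = min_mqranksum, min_readposranksum = min_readposranksum,
    depth_low_factor = depth_low_factor, depth_high_factor = depth_high_factor,
    min_gq = min_gq, min_rgq = min_rgq,
    max_missing_fraction = max_missing_fraction,
    indel_window_bp = as.integer(indel_window_bp),
    excluded_regions = excluded_regions,
    excluded_chromosomes = excluded_chromosomes,
    missingness_before_masking = missingness_before_masking
  ), class = "filter_config")
}

# Site rules in report-attribution order. The order affects only which
# rule a doubly-failing site is attributed to, never the surviving set.
site_rule_order <- c("qual", "qd", "fs", "mq", "mq_rank_sum",
                     "read_pos_rank_sum", "indel_proximity",
                     "excluded_chromosome", "region_mask",
                     "indel_low_qual", "indel_site", "missingness")

#' Apply hard filters to a genotype matrix
#'
#' Runs the full site- and genotype-level filter stack configured by
#' [filter_config()]: low-quality indels are discarded, SNPs near
#' surviving indels are removed, SNP records failing any site-level
#' threshold are removed, genotypes failing GQ/RGQ or per-sample depth
#' bounds are set to missing, sites exceeding the missingness cap are
#' removed, and excluded chromosomes/regions are dropped. Indel records
#' only ever serve the proximity mask and are absent from the output.
#'
#' @param x A [genotype_matrix()].
#' @param config A [filter_config()].
#' @param mean_depths Named numeric vector of genome-wide mean depth per
#'   sample; defaults to the column means of the matrix's own DP values.
#' @return A list with elements `matrix` (the filtered
#'   `genotype_matrix`) and `report` (a `filter_report`; see
#'   [tidy.filter_report()]).
#' @export
apply_site_filters <- function(x, config = filter_config(),
                               mean_depths = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "filter_config"))
  if (is.null(mean_depths)) {
    mean_depths <- colMeans(x$dp, na.rm = TRUE)
    mean_depths[is.nan(mean_depths)] <- NA_real_
    names(mean_depths) <- x$samples
  }
  if (!all(x$samples %in% names(mean_depths))) {
    stop("mean_depths must cover every sample", call. = FALSE)
  }
  mean_depths <- mean_depths[x$samples]

  s <- x$sites
  n <- nrow(s)
  is_snp <- s$site_type == "snp"
  is_indel <- s$site_type == "indel"
  enabled <- function(thr) !is.null(thr) && !is.na(thr)
  # lt/gt comparisons where a missing annotation counts as a failure
  fail_lt <- function(v, thr) is.na(v) | v < thr
  fail_gt <- function(v, thr) is.na(v) | v > thr

  fails <- list()
  rule_fail <- function(name, flag) fails[[name]] <<- flag

  if (enabled(config$min_qual)) {
    rule_fail("qual", is_snp & fail_lt(s$qual, config$min_qual))
  }
  if (enabled(config$min_qd)) {
    rule_fail("qd", is_snp & fail_lt(s$qd, config$min_qd))
  }
  if (enabled(config$max_fs)) {
    rule_fail("fs", is_snp & fail_gt(s$fs, config$max_fs))
  }
  if (enabled(config$min_mq)) {
    rule_fail("mq", is_snp & fail_lt(s$mq, config$min_mq))
  }
  if (enabled(config$min_mqranksum)) {
    rule_fail("mq_rank_sum", is_snp & fail_lt(s$mq_rank_sum,
                                              config$min_mqranksum))
  }
  if (enabled(config$min_readposranksum)) {
    rule_fail("read_pos_rank_sum",
              is_snp & fail_lt(s$read_pos_rank_sum,
                               config$min_readposranksum))
  }

  # indel handling: low-quality indels are dropped and do not mask;
  # surviving indels mask nearby SNPs, then leave the dataset anyway
  indel_low <- is_indel & enabled(config$min_qual) &
    fail_lt(s$qual, config$min_qual)
  good_indel <- is_indel & !indel_low
  if (any(good_indel) && config$indel_window_bp >= 0 && any(is_snp)) {
    ind <- s[good_indel, c("chrom", "pos", "ref")]
    ind$start <- ind$pos - config$indel_window_bp
    ind$end <- ind$pos + pmax(nchar(ind$ref) - 1L, 0L) + config$indel_window_bp
    snp_tab <- tibble::tibble(.row = which(is_snp),
                              chrom = s$chrom[is_snp], pos = s$pos[is_snp])
    hit <- dplyr::inner_join(
      snp_tab, ind,
      by = dplyr::join_by(chrom, dplyr::between(pos, start, end)))
    prox <- rep(FALSE, n)
    prox[unique(hit$.row)] <- TRUE
    rule_fail("indel_proximity", prox)
  }
  rule_fail("indel_low_qual", indel_low)
  rule_fail("indel_site", good_indel)

  if (length(config$excluded_chromosomes) > 0) {
    rule_fail("excluded_chromosome",
              s$chrom %in% config$excluded_chromosomes)
  }
  if (!is.null(config$excluded_regions) &&
      nrow(config$excluded_regions) > 0) {
    reg <- tibble::as_tibble(config$excluded_regions)
    site_tab <- tibble::tibble(.row = seq_len(n),
                               chrom = s$chrom, pos = s$pos)
    hit <- dplyr::inner_join(
      site_tab, reg,
      by = dplyr::join_by(chrom, dplyr::between(pos, start, end)))
    inreg <- rep(FALSE, n)
    inreg[unique(hit$.row)] <- TRUE
    rule_fail("region_mask", inreg)
  }

  # genotype-level masking on sites not already removed
  removed_so_far <- Reduce(`|`, fails, rep(FALSE, n))
  gt <- x$gt
  called <- !is.na(gt)
  active <- !removed_so_far

  masked <- list(genotype_quality = 0L, depth = 0L)
  gq_fail <- matrix(FALSE, n, ncol(gt))
  if (enabled(config$min_gq)) {
    gq_fail[is_snp, ] <- is.na(x$gq[is_snp, , drop = FALSE]) |
      x$gq[is_snp, , drop = FALSE] < config$min_gq
  }
  if (enabled(config$min_rgq)) {
    inv <- s$site_type == "invariant"
    gq_fail[inv, ] <- is.na(x$gq[inv, , drop = FALSE]) |
      x$gq[inv, , drop = FALSE] < config$min_rgq
  }
  gq_fail <- gq_fail & called & active
  masked$genotype_quality <- sum(gq_fail)

  dp_fail <- matrix(FALSE, n, ncol(gt))
  if (enabled(config$depth_low_factor) || enabled(config$depth_high_factor)) {
    lo <- rep(mean_depths * config$depth_low_factor, each = n)
    hi <- rep(mean_depths * config$depth_high_factor, each = n)
    dpv <- x$dp
    dp_fail <- is.na(dpv) | dpv < lo | dpv > hi
    dp_fail[is.na(lo) | is.na(hi)] <- FALSE
  }
  dp_fail <- dp_fail & called & active & !gq_fail
  masked$depth <- sum(dp_fail)

  if (config$missingness_before_masking) {
    miss_frac <- rowMeans(!called)
  }
  gt[gq_fail | dp_fail] <- NA_integer_
  if (!config$missingness_before_masking) {
    miss_frac <- rowMeans(is.na(gt))
  }
  if (enabled(config$max_missing_fraction)) {
    rule_fail("missingness",
              active & miss_frac > config$max_missing_fraction)
  }

  # attribute each removed site to the first failing rule in fixed order
  order_here <- intersect(site_rule_order, names(fails))
  attributed <- rep(NA_character_, n)
  for (rule in order_here) {
    hitr <- fails[[rule]] & is.na(attributed)
    attributed[hitr] <- rule
  }
  keep <- is.na(attributed)

  out <- subset_sites(x, which(keep))
  out$gt <- gt[keep, , drop = FALSE]

  counts <- table(factor(attributed, levels = site_rule_order))
  report <- structure(list(
    sites_in = n,
    sites_surviving = sum(keep),
    sites_removed = tibble::tibble(
      rule = site_rule_order,
      sites_removed = as.integer(counts)),
    genotypes_masked = tibble::tibble(
      rule = c("genotype_quality", "depth"),
      genotypes_masked = c(masked$genotype_quality, masked$depth))
  ), class = "filter_report")

  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$sites_in, " sites in, ", x$sites_surviving,
      " surviving\n", sep = "")
  rem <- x$sites_removed[x$sites_removed$sites_removed > 0, ]
  if (nrow(rem) > 0) {
    cat(paste0("  ", rem$rule, ": ", rem$sites_removed, " removed",
               collapse = "\n"), "\n")
  }
  gm <- x$genotypes_masked
  cat("  genotypes masked: ",
      paste(gm$rule, gm$genotypes_masked, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a filter report
#'
#' @param x A `filter_report` from [apply_site_filters()].
#' @param ... Unused.
#' @return A tibble with one row per rule: `rule`, `kind`
#'   (`"site"`/`"genotype"`), `count`.
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$sites_removed, count = "sites_removed"),
                  kind = "site"),
    dplyr::mutate(dplyr::rename(x$genotypes_masked,
                                count = "genotypes_masked"),
                  kind = "genotype")
  ) |> dplyr::relocate("kind", .after = "rule")
}

#' @rdname tidy.filter_report
#' @method glance filter_report
#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(
    sites_in = x$sites_in,
    sites_surviving = x$sites_surviving,
    sites_removed = sum(x$sites_removed$sites_removed),
    genotypes_masked = sum(x$genotypes_masked$genotypes_masked)
  )
}

#' Write a filter report to JSON
#' @param x A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  jsonlite::write_json(list(
    sites_in = x$sites_in,
    sites_surviving = x$sites_surviving,
    sites_removed = x$sites_removed,
    genotypes_masked = x$genotypes_masked
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
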