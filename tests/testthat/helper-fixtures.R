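# In-code fixtures shared across test files.

# Small genotype matrix with explicit genotype codes.
# gt: matrix or vector (sites x samples); all QC annotations passing by
# default so filter tests can perturb single fields.
make_gm <- function(gt, chrom = "chr1", pos = NULL, site_type = NULL,
                    populations = NULL, dp = NULL, gq = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(colnames(gt))) {
    colnames(gt) <- sprintf("S%02d", seq_len(ncol(gt)))
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(site_type)) site_type <- rep("snp", n)
  sites <- tibble::tibble(
    chrom = rep_len(chrom, n), pos = pos,
    ref = rep("A", n),
    alt = ifelse(site_type == "invariant", NA_character_, "T"),
    site_type = site_type,
    qual = ifelse(site_type == "snp", 1000, NA_real_),
    qd = ifelse(site_type == "snp", 25, NA_real_),
    fs = ifelse(site_type == "snp", 1, NA_real_),
    mq = ifelse(site_type == "snp", 55, NA_real_),
    mq_rank_sum = ifelse(site_type == "snp", 0, NA_real_),
    read_pos_rank_sum = ifelse(site_type == "snp", 0, NA_real_),
    dp = 20 * ncol(gt))
  if (is.null(populations)) {
    populations <- tibble::tibble(sample = colnames(gt), population = "P1")
  }
  if (is.null(dp)) dp <- matrix(20, n, ncol(gt), dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(99, n, ncol(gt), dimnames = dimnames(gt))
  genotype_matrix(sites, gt, dp, gq, populations)
}

# Write a VCF from raw record lines (header supplied here).
write_tiny_vcf <- function(records, samples, path,
                           format = "GT:DP:GQ") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"r\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"g\">",
    "##FORMAT=<ID=RGQ,Number=1,Type=Integer,Description=\"r\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

write_pop_table <- function(samples, populations, path) {
  writeLines(paste(samples, populations, sep = "\t"), path)
  path
}

# Independent brute-force evaluator of the ancestral-assignment rules,
# written as literal per-individual loops (the oracle for
# assign_ancestral).
oracle_assign <- function(gt_a, gt_b, min_support_a = 3, require_all_b = TRUE) {
  for (g in c(gt_a, gt_b)) {
    if (!is.na(g) && g == 1) {
      return(list(allele = NA_character_, status = "discarded_het_outgroup"))
    }
  }
  candidates <- character(0)
  for (allele in c("ref", "alt")) {
    code <- c(ref = 0, alt = 2)[[allele]]
    na <- 0
    for (g in gt_a) if (!is.na(g) && g == code) na <- na + 1
    nb_called <- 0
    nb_agree <- 0
    for (g in gt_b) {
      if (!is.na(g)) {
        nb_called <- nb_called + 1
        if (g == code) nb_agree <- nb_agree + 1
      }
    }
    b_ok <- if (require_all_b) {
      nb_called >= 1 && nb_agree == nb_called
    } else {
      nb_agree >= 1
    }
    if (na >= min_support_a && b_ok) candidates <- c(candidates, allele)
  }
  if (length(candidates) == 1) {
    list(allele = candidates, status = "polarized")
  } else {
    list(allele = NA_character_, status = "discarded_no_consensus")
  }
}

# Crafted 21-record callset: 20 SNP/invariant sites of which exactly 6
# fail (QUAL, QD, MQ, indel proximity, missingness, region mask), plus
# one high-quality indel that serves the proximity mask and then leaves
# the dataset.
crafted_matrix <- function() {
  gt <- matrix(rep(c(0L, 1L, 0L, 0L), 21), 21, 4, byrow = TRUE,
               dimnames = list(NULL, c("S01", "S02", "S03", "S04")))
  st <- rep("snp", 21)
  st[21] <- "indel"
  gm <- make_gm(gt, pos = c(seq(100L, 2000L, by = 100L), 1004L),
                site_type = st)
  gm$sites$ref[gm$sites$site_type == "indel"] <- "AT"
  gm$sites$alt[gm$sites$site_type == "indel"] <- "A"
  gm$sites$qual[gm$sites$pos == 1004] <- 100       # high-quality indel
  gm$sites$qual[gm$sites$pos == 100] <- 10         # QUAL fail
  gm$sites$qd[gm$sites$pos == 200] <- 1            # QD fail
  gm$sites$mq[gm$sites$pos == 300] <- 30           # MQ fail
  gm$gt[gm$sites$pos == 400, c("S01", "S02")] <- NA # 50% missing
  gm
}

crafted_config <- function() {
  filter_config(excluded_regions = tibble::tibble(
    chrom = "chr1", start = 490L, end = 510L))
}

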