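#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF containing biallelic SNPs, indels and invariant sites
#' (GVCF-style non-variant blocks must be pre-expanded to one record per
#' position) together with a sample-to-population table. Multi-allelic
#' records are excluded with a logged count: downstream analyses use
#' biallelic SNPs only. Invariant records (missing or `.` ALT) are
#' preserved because they form the denominator of heterozygosity and the
#' RGQ-filtered callable set.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param populations_path Path to a two-column TSV mapping `sample` to
#'   `population` (header optional). Every VCF sample must be present.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, populations_path) {
  populations <- read_population_table(populations_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)

  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  alt <- fix$ALT
  alt[alt %in% c(".", "")] <- NA_character_

  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    message("excluded ", sum(multi), " multi-allelic record(s)")
  }

  site_type <- dplyr::case_when(
    is.na(alt) | alt == fix$REF ~ "invariant",
    nchar(fix$REF) > 1L | nchar(alt) > 1L | alt == "*" ~ "indel",
    TRUE ~ "snp"
  )

  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }

  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = alt,
    site_type = site_type,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = info_num("QD"),
    fs = info_num("FS"),
    mq = info_num("MQ"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum"),
    dp = info_num("DP")
  )

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt <- parse_gt_codes(gt_raw)
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  rgq <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "RGQ", as.numeric = TRUE))
  if (!is.null(rgq)) {
    use_rgq <- is.na(gq) & !is.na(rgq)
    gq[use_rgq] <- rgq[use_rgq]
  }

  extra <- setdiff(colnames(gt), populations$sample)
  if (length(extra) > 0) {
    stop("VCF sample(s) absent from the population table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }

  keep <- which(!multi)
  genotype_matrix(
    sites = sites[keep, , drop = FALSE],
    gt = gt[keep, , drop = FALSE],
    dp = dp[keep, , drop = FALSE],
    gq = gq[keep, , drop = FALSE],
    populations = populations
  )
}

read_population_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (identical(tolower(tab$sample[1]), "sample")) {
    tab <- tab[-1, , drop = FALSE]
  }
  tibble::as_tibble(tab)
}

# "0/0" style diploid GT strings -> integer allele-count codes.
# Anything other than a diploid combination of alleles 0/1 (or fully
# missing "./." / ".") is a hard error reported with its record number.
parse_gt_codes <- function(gt_raw) {
  dims <- dim(gt_raw)
  dn <- dimnames(gt_raw)
  v <- as.character(gt_raw)
  code <- rep(NA_integer_, length(v))
  lookup <- c("0/0" = 0L, "0|0" = 0L,
              "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
              "1/1" = 2L, "1|1" = 2L)
  known <- v %in% names(lookup)
  miss <- is.na(v) | v %in% c(".", "./.", ".|.")
  half <- !known & !miss & v %in% c("0/.", "./0", "1/.", "./1")
  bad <- !(known | miss | half)
  if (any(bad)) {
    rec <- ((which(bad)[1] - 1L) %% dims[1]) + 1L
    stop("malformed GT '", v[which(bad)[1]], "' at record ", rec,
         call. = FALSE)
  }
  code[known] <- lookup[v[known]]
  # half-calls carry one missing allele: treated as missing diploid calls
  out <- matrix(code, nrow = dims[1], ncol = dims[2], dimnames = dn)
  out
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with the INFO annotations
#' (`QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `DP`) and
#' per-genotype `GT:DP:GQ` fields (`GT:DP:RGQ` at invariant sites) that
#' [read_genotypes()] consumes, so that a matrix round-trips losslessly.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  s <- x$sites
  fmt_num <- function(v) ifelse(is.na(v), NA, format(v, trim = TRUE,
                                                     scientific = FALSE))
  info_part <- function(key, v) {
    out <- paste0(key, "=", fmt_num(v))
    out[is.na(v)] <- NA
    out
  }
  info_cols <- cbind(info_part("QD", s$qd), info_part("FS", s$fs),
                     info_part("MQ", s$mq), info_part("MQRankSum", s$mq_rank_sum),
                     info_part("ReadPosRankSum", s$read_pos_rank_sum),
                     info_part("DP", s$dp))
  info <- apply(info_cols, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })

  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L],
                   nrow = nrow(x$gt), dimnames = dimnames(x$gt))
  gt_str[is.na(x$gt)] <- "./."
  num_or_dot <- function(m) {
    o <- fmt_num(m)
    o[is.na(m)] <- "."
    matrix(o, nrow = nrow(m))
  }
  dp_str <- num_or_dot(x$dp)
  gq_str <- num_or_dot(x$gq)
  cells <- matrix(paste(gt_str, dp_str, gq_str, sep = ":"),
                  nrow = nrow(gt_str))
  body <- apply(cells, 1, paste, collapse = "\t")

  fmt <- ifelse(s$site_type == "invariant", "GT:DP:RGQ", "GT:DP:GQ")
  qual <- fmt_num(s$qual)
  qual[is.na(s$qual)] <- "."
  alt <- s$alt
  alt[is.na(alt)] <- "."

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand phred p\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=RGQ,Number=1,Type=Integer,Description=\"Reference genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  records <- paste(s$chrom, s$pos, ".", s$ref, alt, qual, "PASS", info,
                   fmt, body, sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read BED intervals as 1-based inclusive regions
#'
#' BED input is 0-based half-open; internal coordinates are 1-based
#' inclusive, so `start` gains 1 and `end` is kept.
#'
#' @param path Path to a BED(-like) file; first three columns are
#'   chromosome, start, end.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed_regions <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  tibble::tibble(chrom = as.character(tab$chrom),
                 start = as.integer(tab$start) + 1L,
                 end = as.integer(tab$end))
}
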