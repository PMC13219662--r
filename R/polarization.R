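#' Outgroup specification for ancestral-allele assignment
#'
#' Two outgroup species anchor the polarization: a more distant species
#' A (four individuals by default) and a nearer species B (two
#' individuals). An allele is called ancestral when it is carried
#' homozygously by at least `min_support_a` outgroup-A individuals and
#' by every non-missing outgroup-B individual (with at least one B
#' called). Any heterozygous outgroup genotype discards the site.
#'
#' @param outgroup_a_samples,outgroup_b_samples Character vectors of
#'   sample identifiers; must be disjoint from the ingroup.
#' @param min_support_a Absolute number of outgroup-A individuals that
#'   must carry the candidate allele homozygously (default 3 of 4).
#' @param require_all_b If `TRUE` (default) every non-missing B
#'   individual must agree; if `FALSE` a single agreeing B suffices.
#' @return A list of class `outgroup_spec`.
#' @export
outgroup_spec <- function(outgroup_a_samples, outgroup_b_samples,
                          min_support_a = 3L, require_all_b = TRUE) {
  stopifnot(length(intersect(outgroup_a_samples, outgroup_b_samples)) == 0,
            min_support_a <= length(outgroup_a_samples))
  structure(list(outgroup_a_samples = outgroup_a_samples,
                 outgroup_b_samples = outgroup_b_samples,
                 min_support_a = as.integer(min_support_a),
                 require_all_b = require_all_b),
            class = "outgroup_spec")
}

#' Assign the ancestral allele at one site from outgroup genotypes
#'
#' @param gt_a,gt_b Integer genotype codes (0/1/2/NA, relative to the
#'   site's ref allele) of the outgroup-A and outgroup-B individuals.
#' @param spec An [outgroup_spec()] (only `min_support_a` and
#'   `require_all_b` are used here).
#' @return A list with `allele` (`"ref"`, `"alt"` or `NA`) and `status`
#'   (`"polarized"`, `"discarded_het_outgroup"` or
#'   `"discarded_no_consensus"`).
#' @export
assign_ancestral <- function(gt_a, gt_b, spec) {
  if (any(gt_a == 1L, na.rm = TRUE) || any(gt_b == 1L, na.rm = TRUE)) {
    return(list(allele = NA_character_, status = "discarded_het_outgroup"))
  }
  n_b_called <- sum(!is.na(gt_b))
  winner <- NA_character_
  for (allele in c("ref", "alt")) {
    code <- if (allele == "ref") 0L else 2L
    support_a <- sum(gt_a == code, na.rm = TRUE)
    b_agree <- sum(gt_b == code, na.rm = TRUE)
    ok_b <- if (spec$require_all_b) {
      n_b_called >= 1L && b_agree == n_b_called
    } else {
      b_agree >= 1L
    }
    if (support_a >= spec$min_support_a && ok_b) {
      if (!is.na(winner)) {
        return(list(allele = NA_character_,
                    status = "discarded_no_consensus"))
      }
      winner <- allele
    }
  }
  if (is.na(winner)) {
    list(allele = NA_character_, status = "discarded_no_consensus")
  } else {
    list(allele = winner, status = "polarized")
  }
}

#' Polarize every site of a genotype matrix
#'
#' Assigns ancestral/derived alleles from the outgroup samples and
#' applies the analyzable-site selection: a site is kept
#' (`status = "polarized"`) only when an ancestral allele could be
#' called, at least one derived allele is present in the pooled ingroup,
#' and the pooled ingroup derived-allele frequency is below 1. All other
#' sites are retained with a discard status for accounting, so the
#' statuses partition the input.
#'
#' @param x A filtered [genotype_matrix()] containing both ingroup and
#'   outgroup samples.
#' @param spec An [outgroup_spec()].
#' @param ingroup_populations Character vector of population labels
#'   forming the ingroup; each must have at least one sample.
#' @return A tibble with one row per SNP or invariant site: `chrom`,
#'   `pos`, `ref`, `alt`, `ancestral_allele`, `derived_allele`,
#'   `status`, and per-ingroup-population derived/called allele counts
#'   `derived_<pop>`, `called_<pop>`.
#' @export
polarize_dataset <- function(x, spec, ingroup_populations) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(spec, "outgroup_spec"),
            length(ingroup_populations) > 0)
  out_samples <- c(spec$outgroup_a_samples, spec$outgroup_b_samples)
  missing_out <- setdiff(out_samples, x$samples)
  if (length(missing_out) > 0) {
    stop("outgroup sample(s) absent from matrix: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  for (pop in ingroup_populations) {
    if (length(population_samples(x, pop)) == 0) {
      stop("ingroup population '", pop, "' has zero samples", call. = FALSE)
    }
  }
  keep <- x$sites$site_type %in% c("snp", "invariant")
  x <- subset_sites(x, which(keep))
  n <- n_sites(x)

  ga <- x$gt[, spec$outgroup_a_samples, drop = FALSE]
  gb <- x$gt[, spec$outgroup_b_samples, drop = FALSE]

  any_het <- rowSums(ga == 1L, na.rm = TRUE) +
    rowSums(gb == 1L, na.rm = TRUE) > 0
  n_b_called <- rowSums(!is.na(gb))
  support <- function(code) {
    a <- rowSums(ga == code, na.rm = TRUE)
    b <- rowSums(gb == code, na.rm = TRUE)
    ok_b <- if (spec$require_all_b) n_b_called >= 1L & b == n_b_called
            else b >= 1L
    a >= spec$min_support_a & ok_b
  }
  ref_ok <- support(0L)
  alt_ok <- support(2L)

  ancestral <- rep(NA_character_, n)
  ancestral[ref_ok & !alt_ok] <- "ref"
  ancestral[alt_ok & !ref_ok] <- "alt"
  status <- dplyr::case_when(
    any_het ~ "discarded_het_outgroup",
    is.na(ancestral) ~ "discarded_no_consensus",
    TRUE ~ "polarized"
  )
  ancestral[status != "polarized"] <- NA_character_

  # derived counts per ingroup population over non-missing alleles
  pols <- ingroup_populations
  derived <- matrix(0L, n, length(pols),
                    dimnames = list(NULL, pols))
  called <- derived
  flip <- !is.na(ancestral) & ancestral == "alt"
  for (j in seq_along(pols)) {
    gp <- x$gt[, population_samples(x, pols[j]), drop = FALSE]
    cnt <- rowSums(gp, na.rm = TRUE)
    ncall <- 2L * rowSums(!is.na(gp))
    cnt[flip] <- ncall[flip] - cnt[flip]
    derived[, j] <- as.integer(cnt)
    called[, j] <- as.integer(ncall)
  }
  derived[is.na(ancestral), ] <- NA_integer_

  tot_d <- rowSums(derived)
  tot_c <- rowSums(called)
  status <- dplyr::case_when(
    status != "polarized" ~ status,
    tot_d == 0L | tot_c == 0L ~ "discarded_no_derived",
    tot_d == tot_c ~ "discarded_fixed_derived",
    TRUE ~ "polarized"
  )

  s <- x$sites
  base_of <- function(which_allele) {
    ifelse(is.na(ancestral), NA_character_,
           ifelse(ancestral == which_allele, s$ref, s$alt))
  }
  res <- tibble::tibble(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    ancestral_allele = base_of("ref"),
    derived_allele = base_of("alt"),
    ancestral_is = ancestral,
    status = status
  )
  for (j in seq_along(pols)) {
    res[[paste0("derived_", pols[j])]] <- derived[, j]
    res[[paste0("called_", pols[j])]] <- called[, j]
  }
  res
}

#' Status accounting of a polarized dataset
#'
#' @param polarized Output of [polarize_dataset()].
#' @return A tibble of `status`, `n` covering every input site.
#' @export
polarization_summary <- function(polarized) {
  dplyr::count(polarized, .data$status, name = "n")
}

#' Write a polarized-site table as TSV
#' @param polarized Output of [polarize_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polarized <- function(polarized, path) {
  readr::write_tsv(polarized, path)
  invisible(path)
}
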