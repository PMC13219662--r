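#' Classify per-site effect annotations
#'
#' Maps SnpEff-style effect terms to an effect class and impact
#' category. When a site carries multiple effects (several genes or
#' transcripts), the first term decides, matching annotator output
#' ordered by putative impact and canonical transcript. The fixed
#' mapping is: synonymous -> LOW; missense -> MODERATE; the nonsense set
#' (stop-gained, start-gained, start-lost, splice-acceptor,
#' splice-donor) -> HIGH; anything unrecognized (or an empty
#' annotation) -> other.
#'
#' @param effects Character vector, one element per site; multiple
#'   effect terms separated by `","` or `"&"` (as in VCF ANN fields).
#'   A list of character vectors is also accepted.
#' @return A tibble with columns `effect_class`
#'   (`synonymous`/`missense`/`nonsense`/`other`) and `impact`
#'   (`LOW`/`MODERATE`/`HIGH`/`other`).
#' @export
classify_effects <- function(effects) {
  if (is.list(effects)) {
    first <- vapply(effects, function(e) {
      e <- e[!is.na(e) & nzchar(e)]
      if (length(e) == 0) NA_character_ else e[[1]]
    }, character(1))
  } else {
    first <- stringr::str_split_i(as.character(effects), "[,&]", 1)
    first[!is.na(first) & !nzchar(first)] <- NA_character_
  }
  cls <- effect_term_table()
  idx <- match(first, cls$term)
  tibble::tibble(
    effect_class = ifelse(is.na(idx), "other", cls$effect_class[idx]),
    impact = ifelse(is.na(idx), "other", cls$impact[idx])
  )
}

effect_term_table <- function() {
  tibble::tibble(
    term = c("synonymous_variant",
             "missense_variant",
             "stop_gained", "start_gained", "start_lost",
             "splice_acceptor_variant", "splice_donor_variant"),
    effect_class = c("synonymous", "missense", rep("nonsense", 5)),
    impact = c("LOW", "MODERATE", rep("HIGH", 5))
  )
}

#' Read site annotations from a TSV
#'
#' Expects columns `chrom`, `pos`, `effects` (first-listed term wins,
#' see [classify_effects()]) and optionally `gerp`.
#'
#' @param path Path to a tab-separated annotation file with a header.
#' @return A tibble `chrom`, `pos`, `effect_class`, `impact`, `gerp`.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  out <- dplyr::bind_cols(
    tab[c("chrom", "pos")],
    classify_effects(tab$effects)
  )
  out$gerp <- if ("gerp" %in% names(tab)) tab$gerp else NA_real_
  out
}

#' Read GERP scores from a 3-column TSV
#' @param path Path to a headerless or headered TSV of chromosome,
#'   position, score.
#' @return A tibble `chrom`, `pos`, `gerp`.
#' @export
read_gerp <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[, 1:3]
  names(tab) <- c("chrom", "pos", "gerp")
  if (identical(tolower(as.character(tab$chrom[1])), "chrom")) {
    tab <- tab[-1, , drop = FALSE]
  }
  tibble::tibble(chrom = as.character(tab$chrom),
                 pos = as.integer(tab$pos),
                 gerp = as.numeric(tab$gerp))
}

#' Attach effect classes and GERP scores to polarized sites
#'
#' @param polarized Output of [polarize_dataset()].
#' @param annotations Tibble from [read_annotations()] or with columns
#'   `chrom`, `pos`, `effect_class` (and optionally `gerp`).
#' @param gerp Optional tibble from [read_gerp()]; overrides any `gerp`
#'   column already present in `annotations`.
#' @return `polarized` with `effect_class`, `impact` and `gerp` columns.
#' @export
annotate_polarized <- function(polarized, annotations, gerp = NULL) {
  ann <- annotations
  if (!is.null(gerp)) {
    ann <- dplyr::select(ann, -dplyr::any_of("gerp")) |>
      dplyr::left_join(gerp, by = c("chrom", "pos"))
  }
  out <- dplyr::left_join(polarized, ann, by = c("chrom", "pos"))
  out$effect_class[is.na(out$effect_class)] <- "other"
  if (!"gerp" %in% names(out)) out$gerp <- NA_real_
  out
}

#' Mutation deleteriousness classes
#'
#' The standard set of (deliberately overlapping) mutation classes used
#' for load partitioning: annotation classes `synonymous` (the neutral
#' baseline), `missense` (mildly deleterious) and `nonsense` (highly
#' deleterious); conservation class `high_gerp` (GERP score strictly
#' greater than `gerp_threshold`); and the combined classes
#' `high_gerp_missense` and `high_gerp_nonsense`.
#'
#' @param gerp_threshold Strict lower bound on the GERP score (default 4).
#' @return A named list of predicate functions over an annotated site
#'   tibble, each returning a logical vector.
#' @export
mutation_classes <- function(gerp_threshold = 4) {
  gerp_high <- function(sites) {
    !is.na(sites$gerp) & sites$gerp > gerp_threshold
  }
  list(
    synonymous = function(sites) sites$effect_class == "synonymous",
    missense = function(sites) sites$effect_class == "missense",
    nonsense = function(sites) sites$effect_class == "nonsense",
    high_gerp = gerp_high,
    high_gerp_missense = function(sites) {
      sites$effect_class == "missense" & gerp_high(sites)
    },
    high_gerp_nonsense = function(sites) {
      sites$effect_class == "nonsense" & gerp_high(sites)
    }
  )
}

# Restrict an annotated polarized table to analyzable sites of a class.
class_sites <- function(annotated, class_fun) {
  annotated[annotated$status == "polarized" & class_fun(annotated), ,
            drop = FALSE]
}

#' Individual masked and realized load
#'
#' For each individual and mutation class, counts heterozygous genotypes
#' (the masked load: deleterious alleles hidden from selection under
#' recessivity) and genotypes homozygous for the derived allele (the
#' realized load, expressed in the current generation). Missing
#' genotypes contribute to neither; `derived_total = masked +
#' 2 * realized` always holds.
#'
#' @param annotated Annotated polarized sites from [annotate_polarized()].
#' @param x The [genotype_matrix()] the sites were polarized from.
#' @param classes Named list of class predicates, see
#'   [mutation_classes()].
#' @param samples Samples to report (default: all ingroup samples, i.e.
#'   those whose population appears in the derived-count columns).
#' @return A tibble `individual`, `population`, `class`, `n_sites`,
#'   `masked`, `realized`, `derived_total`, `n_callable`.
#' @export
individual_load <- function(annotated, x, classes = mutation_classes(),
                            samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(samples)) {
    samples <- population_samples(x, polarized_pops(annotated))
  }
  key <- paste(x$sites$chrom, x$sites$pos)
  purrr::imap(classes, function(f, cname) {
    sites <- class_sites(annotated, f)
    if (nrow(sites) == 0) {
      warning("class '", cname, "' has zero polarized sites", call. = FALSE)
    }
    idx <- match(paste(sites$chrom, sites$pos), key)
    stopifnot(!anyNA(idx))
    gt <- x$gt[idx, samples, drop = FALSE]
    # genotype code counts the alt allele; flip where ancestral is alt
    flip <- sites$ancestral_is == "alt"
    gtd <- gt
    gtd[flip, ] <- 2L - gt[flip, , drop = FALSE]
    tibble::tibble(
      individual = samples,
      class = cname,
      n_sites = nrow(sites),
      masked = unname(colSums(gtd == 1L, na.rm = TRUE)),
      realized = unname(colSums(gtd == 2L, na.rm = TRUE)),
      derived_total = unname(colSums(gtd, na.rm = TRUE)),
      n_callable = unname(colSums(!is.na(gtd)))
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(x$populations, by = c(individual = "sample")) |>
    dplyr::relocate("population", .after = "individual")
}

#' Population-level high-frequency load
#'
#' Counts, per population and mutation class, the polarized sites whose
#' within-population derived-allele frequency (over non-missing alleles)
#' strictly exceeds `freq_threshold`. Sites with zero called alleles in
#' a population are skipped for that population.
#'
#' @param annotated Annotated polarized sites.
#' @param classes Named list of class predicates.
#' @param freq_threshold Strict frequency threshold (default 0.9).
#' @return A tibble `population`, `class`, `high_freq_count`.
#' @export
population_load <- function(annotated, classes = mutation_classes(),
                            freq_threshold = 0.9) {
  pops <- polarized_pops(annotated)
  purrr::imap(classes, function(f, cname) {
    sites <- class_sites(annotated, f)
    purrr::map(pops, function(pop) {
      d <- sites[[paste0("derived_", pop)]]
      m <- sites[[paste0("called_", pop)]]
      ok <- m > 0
      tibble::tibble(population = pop, class = cname,
                     high_freq_count = sum(d[ok] / m[ok] > freq_threshold))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Per-population totals of derived alleles
#'
#' Total number of derived-allele copies per population for each
#' mutation class; the synonymous class serves as the neutral baseline
#' when comparing populations.
#'
#' @inheritParams population_load
#' @return A tibble `population`, `class`, `total_derived`, `n_sites`.
#' @export
derived_allele_totals <- function(annotated, classes = mutation_classes()) {
  pops <- polarized_pops(annotated)
  purrr::imap(classes, function(f, cname) {
    sites <- class_sites(annotated, f)
    purrr::map(pops, function(pop) {
      tibble::tibble(population = pop, class = cname,
                     total_derived = sum(sites[[paste0("derived_", pop)]]),
                     n_sites = nrow(sites))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

# Population labels encoded in a polarized table's called_<pop> columns.
polarized_pops <- function(polarized) {
  sub("^called_", "", grep("^called_", names(polarized), value = TRUE))
}
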