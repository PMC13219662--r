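#' Percent reduction in derived-allele totals between populations
#'
#' The primary purging contrast: for each mutation class, the
#' percentage by which the focal (small, inbred) population's total
#' number of derived alleles falls short of the reference (large)
#' population's, `100 * (total_ref - total_focal) / total_ref`. Under
#' purging, reductions for highly deleterious classes exceed the
#' mildly deleterious and synonymous-baseline reductions.
#'
#' @param totals Tibble from [derived_allele_totals()].
#' @param reference_pop,focal_pop Population labels.
#' @return A tibble `class`, `reference`, `focal`, `total_reference`,
#'   `total_focal`, `percent_reduction` (`NA` with a warning when the
#'   reference total is zero).
#' @export
percent_reduction <- function(totals, reference_pop, focal_pop) {
  ref <- dplyr::filter(totals, .data$population == reference_pop)
  foc <- dplyr::filter(totals, .data$population == focal_pop)
  out <- dplyr::inner_join(
    dplyr::select(ref, "class", total_reference = "total_derived"),
    dplyr::select(foc, "class", total_focal = "total_derived"),
    by = "class")
  if (any(out$total_reference == 0)) {
    warning("zero reference total for class(es): ",
            paste(out$class[out$total_reference == 0], collapse = ", "),
            "; percent reduction undefined", call. = FALSE)
  }
  dplyr::mutate(
    out,
    reference = reference_pop, focal = focal_pop,
    percent_reduction = ifelse(
      .data$total_reference > 0,
      100 * (.data$total_reference - .data$total_focal) /
        .data$total_reference,
      NA_real_)
  ) |>
    dplyr::relocate("reference", "focal", .after = "class")
}

#' GERP score profile of a population's derived alleles
#'
#' Summarizes the deleteriousness-score distribution over the set of
#' derived alleles present in a population: each polarized site with at
#' least one derived copy in the population contributes its GERP score
#' once (set semantics); with `frequency_weighted = TRUE` each site
#' contributes with multiplicity equal to its derived-allele count.
#'
#' @param annotated Annotated polarized sites from
#'   [annotate_polarized()] (GERP scores required).
#' @param population Population label.
#' @param gerp_threshold Strict threshold defining putatively
#'   deleterious scores (default 4).
#' @param frequency_weighted Weight scores by derived-allele count.
#' @return A list of class `gerp_profile`: `population`, `mean_score`,
#'   `prop_above_threshold`, `n_above`, `n_below`, `scores`.
#' @export
gerp_profile <- function(annotated, population, gerp_threshold = 4,
                         frequency_weighted = FALSE) {
  d <- annotated[[paste0("derived_", population)]]
  ok <- annotated$status == "polarized" & !is.na(annotated$gerp) & d > 0
  scores <- annotated$gerp[ok]
  if (frequency_weighted) scores <- rep(scores, times = d[ok])
  if (length(scores) == 0) {
    warning("no scored derived alleles in population '", population, "'",
            call. = FALSE)
    return(structure(list(population = population, mean_score = NA_real_,
                          prop_above_threshold = NA_real_, n_above = 0L,
                          n_below = 0L, scores = numeric(0),
                          gerp_threshold = gerp_threshold),
                     class = "gerp_profile"))
  }
  structure(list(
    population = population,
    mean_score = mean(scores),
    prop_above_threshold = mean(scores > gerp_threshold),
    n_above = sum(scores > gerp_threshold),
    n_below = sum(scores <= gerp_threshold),
    scores = scores,
    gerp_threshold = gerp_threshold
  ), class = "gerp_profile")
}

#' @export
print.gerp_profile <- function(x, ...) {
  cat("<gerp_profile> ", x$population, ": mean ",
      format(x$mean_score, digits = 4), ", P(score > ", x$gerp_threshold,
      ") = ", format(x$prop_above_threshold, digits = 4), " (n = ",
      length(x$scores), ")\n", sep = "")
  invisible(x)
}

#' @rdname gerp_profile
#' @param x A `gerp_profile`.
#' @param ... Unused.
#' @method glance gerp_profile
#' @export
glance.gerp_profile <- function(x, ...) {
  tibble::tibble(population = x$population,
                 mean_score = x$mean_score,
                 prop_above_threshold = x$prop_above_threshold,
                 n_scores = length(x$scores))
}

#' Group-comparison statistics for load and purging
#'
#' Runs the battery of two-tailed nonparametric tests used to compare
#' populations: pairwise Wilcoxon rank-sum tests on per-individual
#' masked and realized counts (per mutation class), a Kruskal-Wallis
#' test and pairwise two-sample Kolmogorov-Smirnov tests on the GERP
#' score distributions, and a chi-squared test (no continuity
#' correction) on the counts of derived alleles above/below the GERP
#' threshold per population. No multiple-testing correction is applied.
#'
#' @param load Tibble from [individual_load()] (or `NULL` to skip the
#'   Wilcoxon tests).
#' @param profiles List of [gerp_profile()] objects, one per population
#'   (or `NULL` to skip the score tests).
#' @return A tibble `test`, `metric`, `group1`, `group2`, `statistic`,
#'   `df`, `p_value` (`df` is `NA` where undefined). Rank tests on
#'   groups with fewer than two individuals are skipped with a warning.
#' @export
compare_groups <- function(load = NULL, profiles = NULL) {
  rows <- list()
  add <- function(test, metric, g1, g2, statistic, df, p) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      test = test, metric = metric, group1 = g1, group2 = g2,
      statistic = unname(statistic), df = df, p_value = p)
  }

  if (!is.null(load)) {
    pops <- sort(unique(load$population))
    pairs <- utils::combn(pops, 2, simplify = FALSE)
    for (cls in unique(load$class)) {
      for (metric in c("masked", "realized")) {
        for (pr in pairs) {
          a <- load[[metric]][load$class == cls & load$population == pr[1]]
          b <- load[[metric]][load$class == cls & load$population == pr[2]]
          if (length(a) < 2 || length(b) < 2) {
            warning("skipping Wilcoxon (", cls, "/", metric, ") for ",
                    pr[1], " vs ", pr[2], ": fewer than 2 individuals",
                    call. = FALSE)
            next
          }
          w <- suppressWarnings(
            stats::wilcox.test(a, b, alternative = "two.sided"))
          add("wilcoxon", paste(cls, metric, sep = "_"), pr[1], pr[2],
              w$statistic, NA_real_, w$p.value)
        }
      }
    }
  }

  if (!is.null(profiles) && length(profiles) >= 2) {
    names(profiles) <- vapply(profiles, `[[`, character(1), "population")
    score_sets <- lapply(profiles, `[[`, "scores")
    nonempty <- lengths(score_sets) > 0
    if (sum(nonempty) >= 2) {
      kw <- stats::kruskal.test(score_sets[nonempty])
      add("kruskal_wallis", "gerp_scores", NA_character_, NA_character_,
          kw$statistic, unname(kw$parameter), kw$p.value)
    } else {
      warning("fewer than two populations with scored derived alleles; ",
              "score tests skipped", call. = FALSE)
    }
    prs <- utils::combn(names(profiles), 2, simplify = FALSE)
    for (pr in prs) {
      if (!nonempty[[pr[1]]] || !nonempty[[pr[2]]]) next
      ks <- suppressWarnings(
        stats::ks.test(score_sets[[pr[1]]], score_sets[[pr[2]]],
                       alternative = "two.sided"))
      add("kolmogorov_smirnov", "gerp_scores", pr[1], pr[2],
          ks$statistic, NA_real_, ks$p.value)
    }
    tab <- t(vapply(profiles,
                    function(p) c(above = p$n_above, below = p$n_below),
                    numeric(2)))
    if (all(rowSums(tab) > 0)) {
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      add("chi_squared", "prop_gerp_above_threshold", NA_character_,
          NA_character_, cs$statistic, unname(cs$parameter), cs$p.value)
    }
  }

  purrr::list_rbind(rows)
}

#' Purging summary across populations
#'
#' Convenience wrapper assembling the three purging contrasts: class-wise
#' percent reductions from each focal population against the reference,
#' GERP profiles per population, and the group-comparison tests.
#'
#' @param totals Tibble from [derived_allele_totals()].
#' @param annotated Annotated polarized sites.
#' @param load Tibble from [individual_load()].
#' @param reference_pop Reference (large) population label.
#' @param focal_pops Focal population labels (default: all others).
#' @param gerp_threshold Strict GERP threshold (default 4).
#' @return A list of class `purging_summary` with elements `reductions`,
#'   `profiles`, `tests`.
#' @export
purging_summary <- function(totals, annotated, load, reference_pop,
                            focal_pops = NULL, gerp_threshold = 4) {
  pops <- unique(totals$population)
  if (is.null(focal_pops)) focal_pops <- setdiff(pops, reference_pop)
  reductions <- purrr::map(
    focal_pops, ~percent_reduction(totals, reference_pop, .x)) |>
    purrr::list_rbind()
  profiles <- purrr::map(
    pops, ~gerp_profile(annotated, .x, gerp_threshold = gerp_threshold))
  tests <- compare_groups(load, profiles)
  structure(list(reductions = reductions, profiles = profiles,
                 tests = tests),
            class = "purging_summary")
}

#' @export
print.purging_summary <- function(x, ...) {
  cat("<purging_summary>\n")
  print(x$reductions)
  for (p in x$profiles) print(p)
  cat(nrow(x$tests), "group-comparison tests\n")
  invisible(x)
}

#' Tidy a purging summary
#' @param x A `purging_summary`.
#' @param ... Unused.
#' @return The percent-reduction tibble.
#' @method tidy purging_summary
#' @export
tidy.purging_summary <- function(x, ...) x$reductions

#' @rdname tidy.purging_summary
#' @method glance purging_summary
#' @export
glance.purging_summary <- function(x, ...) {
  purrr::map(x$profiles, glance) |> purrr::list_rbind()
}
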