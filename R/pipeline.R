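#' Run the full analysis pipeline
#'
#' Orchestrates filter -> polarize -> load -> purging -> ROH ->
#' diversity as one reproducible run with plain-file handoff: every
#' stage writes its table into the output directory, so any stage can
#' be re-run standalone or fed external tool outputs (e.g. HMM-caller
#' ROH intervals). A manifest with input checksums and a consolidated
#' summary are written last; re-running with identical config and
#' inputs reproduces identical outputs.
#'
#' @param config A named list, or the path of a YAML file holding one,
#'   with elements: `vcf`, `populations` (paths); `annotations` (TSV
#'   path, see [read_annotations()]); optional `gerp` (TSV path);
#'   optional `roh` (interval TSV path; otherwise the window caller
#'   runs on the filtered heterozygous positions); `ingroup_populations`
#'   (character); `outgroups` (list: `a_samples`, `b_samples`, optional
#'   `min_support_a`, `require_all_b`); optional `filter` and `roh_config`
#'   (argument lists for [filter_config()] / [roh_config()]);
#'   `chrom_lengths` (named list, required when the window caller is
#'   used or `genome_length` is unset); `reference_pop`; `out_dir`;
#'   optional `seed` (default 1).
#' @return A list of class `pipeline_result` with the per-stage tibbles
#'   and the output paths, invisibly writable via its `paths` element.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("vcf", "populations", "annotations",
                "ingroup_populations", "outgroups", "reference_pop",
                "out_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0) {
    stop("config lacks required key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  for (key in c("vcf", "populations", "annotations", "gerp", "roh")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("input path for '", key, "' does not exist: ", config[[key]],
           call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 1L)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    paths[[name]] <<- p
    x
  }

  gm <- stage("read", read_genotypes(config$vcf, config$populations))

  fcfg <- do.call(filter_config, config$filter %||% list())
  filt <- stage("filter", apply_site_filters(gm, fcfg))
  gm <- filt$matrix
  write_filter_report(filt$report, file.path(out_dir, "filter_report.json"))
  paths[["filter_report.json"]] <- file.path(out_dir, "filter_report.json")

  og <- config$outgroups
  spec <- outgroup_spec(og$a_samples, og$b_samples,
                        min_support_a = og$min_support_a %||% 3L,
                        require_all_b = og$require_all_b %||% TRUE)
  polarized <- stage("polarize",
                     polarize_dataset(gm, spec, config$ingroup_populations))
  emit(polarized, "polarized.tsv")

  ann <- stage("annotate", {
    a <- read_annotations(config$annotations)
    g <- if (!is.null(config$gerp)) read_gerp(config$gerp) else NULL
    annotate_polarized(polarized, a, gerp = g)
  })

  classes <- mutation_classes()
  load_ind <- stage("load", suppressWarnings(
    individual_load(ann, gm, classes)))
  emit(load_ind, "load_individual.tsv")
  emit(population_load(ann, classes), "load_population.tsv")
  totals <- emit(derived_allele_totals(ann, classes), "derived_totals.tsv")

  purging <- stage("purging", suppressWarnings(
    purging_summary(totals, ann, load_ind, config$reference_pop)))
  emit(purging$reductions, "purging_reductions.tsv")
  emit(purging$tests, "purging_tests.tsv")

  chrom_lengths <- unlist(config$chrom_lengths %||% list())
  rcfg_args <- config$roh_config %||% list()
  if (is.null(rcfg_args$genome_length) && length(chrom_lengths) > 0) {
    rcfg_args$genome_length <- sum(chrom_lengths)
  }
  rcfg <- do.call(roh_config, rcfg_args)

  roh <- stage("roh", {
    if (!is.null(config$roh)) {
      read_roh(config$roh)
    } else {
      ing <- population_samples(gm, config$ingroup_populations)
      het <- tidy(gm) |>
        dplyr::filter(.data$sample %in% ing, .data$genotype == 1L) |>
        dplyr::select(sample = "sample", "chrom", "pos")
      call_roh_windows(het, chrom_lengths,
                       window_bp = config$roh_window_bp %||% 1e5,
                       max_het_per_window =
                         config$roh_max_het_per_window %||% 0L,
                       samples = ing)
    }
  })
  emit(roh, "roh_intervals.tsv")
  froh_tab <- stage("froh", froh(roh, rcfg)) |>
    dplyr::left_join(gm$populations, by = "sample")
  emit(froh_tab, "froh.tsv")

  traj <- stage("ne_trajectory", {
    purrr::map(config$ingroup_populations, function(pop) {
      iv <- roh[roh$sample %in% population_samples(gm, pop), ]
      dplyr::mutate(ne_trajectory(iv, rcfg), population = pop)
    }) |> purrr::list_rbind()
  })
  emit(traj, "ne_trajectory.tsv")

  het_tab <- stage("diversity", heterozygosity(gm))
  emit(het_tab, "heterozygosity.tsv")
  snps <- emit(snp_count(gm), "snp_counts.tsv")

  tree <- stage("tree", {
    thin <- thin_sites(gm, config$thin_bp %||% 50000)
    nj_tree(distance_matrix(thin))
  })
  write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
  paths[["tree.nwk"]] <- file.path(out_dir, "tree.nwk")

  inputs <- purrr::compact(config[c("vcf", "populations", "annotations",
                                    "gerp", "roh")])
  manifest <- list(
    inputs = purrr::map(inputs, ~list(path = .x,
                                      md5 = unname(tools::md5sum(.x)))),
    seed = config$seed %||% 1L)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  summary <- list(
    sites_surviving = filt$report$sites_surviving,
    polarization = polarization_summary(polarized),
    heterozygosity = het_tab,
    snp_counts = snps,
    froh = froh_tab,
    load_individual = load_ind,
    derived_totals = totals,
    purging_reductions = purging$reductions,
    ne_trajectory = traj)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths[["summary.json"]] <- file.path(out_dir, "summary.json")

  structure(list(matrix = gm, report = filt$report,
                 polarized = polarized, annotated = ann,
                 load_individual = load_ind, derived_totals = totals,
                 purging = purging, roh = roh, froh = froh_tab,
                 ne_trajectory = traj, heterozygosity = het_tab,
                 snp_counts = snps, tree = tree, paths = paths,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> outputs in ", x$out_dir, "\n", sep = "")
  cat("  ", n_sites(x$matrix), " sites surviving filters; ",
      sum(x$polarized$status == "polarized"), " polarized sites\n",
      sep = "")
  invisible(x)
}
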