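#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' three-population island study design at desk scale: three ingroup
#' populations whose per-site heterozygosity targets stand in the
#' 1 : 40 : 1400 ratio of a tiny islet population, a small islet
#' population and a large mainland population; two outgroup species
#' (four distant-outgroup and two near-outgroup individuals) fixed for
#' the ancestral allele except at a known fraction of
#' post-divergence-substitution sites; effect classes with
#' class-dependent Gaussian GERP scores (means -0.87 / 1.9 / 2.3 for
#' synonymous / missense / nonsense); and planted ROH tracts of known
#' per-population genome fraction.
#'
#' @param seed Integer seed; identical config + seed give identical
#'   outputs.
#' @param n_chromosomes,chromosome_length Genome layout (bp).
#' @param n_sites Total candidate sites placed uniformly.
#' @param frac_invariant Fraction of sites emitted as invariant records.
#' @param populations Tibble with columns `name`, `n_samples`, `theta`
#'   (target per-site heterozygosity at polymorphic sites) and
#'   optionally `roh_f` (planted ROH genome fraction).
#' @param n_outgroup_a,n_outgroup_b Outgroup sample counts.
#' @param outgroup_mut_prob Probability per species and site that the
#'   outgroup carries a post-divergence substitution (is fixed for the
#'   derived allele instead of the ancestral one).
#' @param effect_proportions Named proportions of
#'   synonymous/missense/nonsense/other sites (must sum to 1).
#' @param gerp_means,gerp_sd Class-wise Gaussian GERP score parameters.
#' @param selection Named per-class selection coefficients used by
#'   [simulate_purging_pair()].
#' @param mean_depth Mean per-genotype sequencing depth (Poisson).
#' @param roh_mean_tract,roh_min_tract Planted ROH tract length model
#'   (exponential mean and hard minimum, bp).
#' @param frequency_samplers Optional named list (by population) of
#'   functions `n -> derived-allele frequencies`, overriding the
#'   symmetric-Beta model for those populations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_chromosomes = 2L,
    chromosome_length = 1e7,
    n_sites = 20000L,
    frac_invariant = 0.2,
    populations = tibble::tibble(
      name = c("LC", "ST", "SI"),
      n_samples = c(8L, 8L, 8L),
      theta = c(2e-4, 8e-3, 0.28),
      roh_f = c(0.9, 0.5, 0)),
    n_outgroup_a = 4L,
    n_outgroup_b = 2L,
    outgroup_mut_prob = 0.02,
    effect_proportions = c(synonymous = 0.45, missense = 0.45,
                           nonsense = 0.05, other = 0.05),
    gerp_means = c(synonymous = -0.87, missense = 1.9, nonsense = 2.3,
                   other = 0),
    gerp_sd = 1.5,
    selection = c(synonymous = 0, missense = 0.05, nonsense = 0.3,
                  other = 0),
    mean_depth = 20,
    roh_mean_tract = 2e6,
    roh_min_tract = 1.2e6,
    frequency_samplers = NULL) {
  stopifnot(abs(sum(effect_proportions) - 1) < 1e-8,
            all(populations$theta > 0), all(populations$theta < 1),
            n_chromosomes >= 1, chromosome_length > 0)
  if (!"roh_f" %in% names(populations)) populations$roh_f <- 0
  structure(as.list(environment()), class = "sim_config")
}

# Symmetric Beta(a, a) with E[2q(1-q)] = theta  =>  a = theta/(1 - 2 theta)
theta_to_alpha <- function(theta) {
  stopifnot(theta > 0, theta < 0.5)
  theta / (1 - 2 * theta)
}

#' Simulate a fully labelled multi-population dataset
#'
#' Places sites uniformly over the genome; fixes both outgroup species
#' for the ancestral allele except at outgroup-branch substitution
#' sites; draws per-population derived-allele frequencies from a
#' symmetric Beta parameterized to hit the population's target
#' heterozygosity; draws Hardy-Weinberg genotypes outside planted ROH
#' tracts and forces homozygosity (derived with probability q) inside
#' them; and assigns effect classes and class-dependent GERP scores.
#' All truth is recorded.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, writes `sim.vcf`,
#'   `populations.tsv`, `annotations.tsv`, `gerp.tsv` and
#'   `roh_truth.bed` (plus the truth table as TSV) and returns the
#'   paths.
#' @return A list with elements `matrix` (a [genotype_matrix()]
#'   containing ingroup and outgroup samples), `annotations` (tibble
#'   `chrom`, `pos`, `effects`, `gerp`), `truth` (list: `sites` with
#'   the true ancestral allele/class/score/per-population frequencies,
#'   `roh` planted intervals, `derived_totals` generator-side
#'   bookkeeping), `outgroups` (an [outgroup_spec()]) and `paths`
#'   (when `dir` is given).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(
    rep(config$chromosome_length, config$n_chromosomes), chroms)
  genome_length <- sum(chrom_lengths)

  # site placement, uniform without replacement per chromosome
  n_per_chrom <- as.vector(stats::rmultinom(
    1, config$n_sites, rep(1, config$n_chromosomes)))
  sites <- purrr::map2(chroms, n_per_chrom, function(ch, k) {
    tibble::tibble(chrom = ch,
                   pos = sort(sample.int(chrom_lengths[[ch]], k)))
  }) |> purrr::list_rbind()
  n <- nrow(sites)

  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, n, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(b) sample(setdiff(bases, b), 1), "x")
  sites$site_type <- ifelse(stats::runif(n) < config$frac_invariant,
                            "invariant", "snp")
  sites$alt[sites$site_type == "invariant"] <- NA_character_
  is_snp <- sites$site_type == "snp"

  # ancestral truth and outgroup genotypes
  ancestral_is <- ifelse(is_snp,
                         ifelse(stats::runif(n) < 0.5, "ref", "alt"),
                         "ref")
  anc_code <- ifelse(ancestral_is == "ref", 0L, 2L)
  der_code <- 2L - anc_code

  a_samples <- paste0("OGA", seq_len(config$n_outgroup_a))
  b_samples <- paste0("OGB", seq_len(config$n_outgroup_b))
  og_gt <- matrix(rep(anc_code, config$n_outgroup_a + config$n_outgroup_b),
                  nrow = n,
                  dimnames = list(NULL, c(a_samples, b_samples)))
  mut_a <- is_snp & stats::runif(n) < config$outgroup_mut_prob
  mut_b <- is_snp & stats::runif(n) < config$outgroup_mut_prob
  og_gt[mut_a, a_samples] <- rep(der_code[mut_a], config$n_outgroup_a)
  og_gt[mut_b, b_samples] <- rep(der_code[mut_b], config$n_outgroup_b)

  # per-population derived-allele frequencies
  pops <- config$populations
  freqs <- matrix(0, n, nrow(pops), dimnames = list(NULL, pops$name))
  for (j in seq_len(nrow(pops))) {
    sampler <- config$frequency_samplers[[pops$name[j]]]
    q <- if (!is.null(sampler)) {
      sampler(sum(is_snp))
    } else {
      a <- theta_to_alpha(pops$theta[j])
      stats::rbeta(sum(is_snp), a, a)
    }
    freqs[is_snp, j] <- q
  }

  # planted ROH tracts per ingroup sample
  roh_truth <- list()
  ing_gt <- NULL
  pop_labels <- character(0)
  for (j in seq_len(nrow(pops))) {
    pop <- pops$name[j]
    for (k in seq_len(pops$n_samples[j])) {
      smp <- sprintf("%s%02d", pop, k)
      pop_labels <- c(pop_labels, pop)
      q <- freqs[, j]
      gt <- stats::rbinom(n, 2L, q)
      if (pops$roh_f[j] > 0) {
        tr <- plant_roh_tracts(pops$roh_f[j], chrom_lengths,
                               config$roh_mean_tract, config$roh_min_tract)
        tr$sample <- smp
        roh_truth[[smp]] <- tr
        in_roh <- sites_in_intervals(sites$chrom, sites$pos, tr)
        gt[in_roh] <- 2L * stats::rbinom(sum(in_roh), 1L, q[in_roh])
      }
      # genotype codes count the alt allele
      flip <- ancestral_is == "alt"
      gt[flip] <- 2L - gt[flip]
      gt[!is_snp] <- 0L
      ing_gt <- cbind(ing_gt, gt)
      colnames(ing_gt)[ncol(ing_gt)] <- smp
    }
  }
  roh_truth <- purrr::list_rbind(roh_truth) |>
    (\(d) if (is.null(d) || nrow(d) == 0) {
      tibble::tibble(sample = character(), chrom = character(),
                     start = numeric(), end = numeric())
    } else dplyr::select(d, "sample", "chrom", "start", "end"))()

  gt <- cbind(ing_gt, og_gt)
  all_samples <- colnames(gt)
  populations_tab <- tibble::tibble(
    sample = all_samples,
    population = c(pop_labels,
                   rep("outgroupA", config$n_outgroup_a),
                   rep("outgroupB", config$n_outgroup_b)))

  dp <- matrix(stats::rpois(n * length(all_samples), config$mean_depth),
               n, dimnames = list(NULL, all_samples))
  gq <- matrix(99, n, length(all_samples),
               dimnames = list(NULL, all_samples))

  site_tab <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
    alt = sites$alt, site_type = sites$site_type,
    qual = ifelse(is_snp, round(stats::runif(n, 200, 2000), 1), NA_real_),
    qd = ifelse(is_snp, round(stats::runif(n, 15, 35), 2), NA_real_),
    fs = ifelse(is_snp, round(stats::runif(n, 0, 10), 3), NA_real_),
    mq = ifelse(is_snp, round(stats::runif(n, 45, 60), 2), NA_real_),
    mq_rank_sum = ifelse(is_snp, round(stats::rnorm(n, 0, 2), 3), NA_real_),
    read_pos_rank_sum = ifelse(is_snp, round(stats::rnorm(n, 0, 2), 3),
                               NA_real_),
    dp = rowSums(dp))

  gm <- genotype_matrix(site_tab, gt, dp, gq, populations_tab)

  # effect classes and GERP scores
  class_names <- names(config$effect_proportions)
  eff_class <- sample(class_names, n, replace = TRUE,
                      prob = config$effect_proportions)
  term_of <- c(synonymous = "synonymous_variant",
               missense = "missense_variant",
               nonsense = "stop_gained",
               other = "intergenic_region")
  gerp <- round(stats::rnorm(n, config$gerp_means[eff_class],
                             config$gerp_sd), 3)
  annotations <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    effects = unname(term_of[eff_class]), gerp = gerp)

  # generator-side bookkeeping of derived totals per population/class
  der_dosage <- gt[, seq_along(pop_labels), drop = FALSE]
  flip <- ancestral_is == "alt"
  der_dosage[flip, ] <- 2L - der_dosage[flip, , drop = FALSE]
  derived_totals <- purrr::map(unique(pop_labels), function(pop) {
    cols <- which(pop_labels == pop)
    per_site <- rowSums(der_dosage[, cols, drop = FALSE])
    tibble::tibble(population = pop, class = eff_class,
                   derived = per_site) |>
      dplyr::group_by(.data$population, .data$class) |>
      dplyr::summarise(total_derived = sum(.data$derived),
                       .groups = "drop")
  }) |> purrr::list_rbind()

  truth <- list(
    sites = tibble::tibble(
      chrom = sites$chrom, pos = sites$pos,
      site_type = sites$site_type,
      ancestral_is = ancestral_is,
      ancestral_allele = ifelse(ancestral_is == "ref", sites$ref,
                                sites$alt),
      outgroup_mutated = mut_a | mut_b,
      effect_class = eff_class, gerp = gerp) |>
      dplyr::bind_cols(tibble::as_tibble(freqs) |>
                         stats::setNames(paste0("freq_", pops$name))),
    roh = roh_truth,
    derived_totals = derived_totals,
    chrom_lengths = chrom_lengths,
    genome_length = genome_length)

  outgroups <- outgroup_spec(a_samples, b_samples)

  out <- list(matrix = gm, annotations = annotations, truth = truth,
              outgroups = outgroups, populations = populations_tab)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "sim.vcf"),
      populations = file.path(dir, "populations.tsv"),
      annotations = file.path(dir, "annotations.tsv"),
      gerp = file.path(dir, "gerp.tsv"),
      roh_truth = file.path(dir, "roh_truth.bed"),
      truth_sites = file.path(dir, "truth_sites.tsv"))
    write_genotypes(gm, paths$vcf)
    readr::write_tsv(populations_tab, paths$populations,
                     col_names = FALSE)
    readr::write_tsv(annotations, paths$annotations)
    readr::write_tsv(annotations[c("chrom", "pos", "gerp")], paths$gerp,
                     col_names = FALSE)
    readr::write_tsv(roh_truth, paths$roh_truth, col_names = FALSE)
    readr::write_tsv(truth$sites, paths$truth_sites)
    out$paths <- paths
  }
  out
}

# logical: which (chrom, pos) fall inside 0-based half-open intervals
sites_in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(pos))
  if (nrow(intervals) == 0) return(hit)
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    pos > intervals$start[i] & pos <= intervals$end[i])
  }
  hit
}

#' Plant ROH tracts hitting a target genome fraction
#'
#' Draws exponential tract lengths (with a hard minimum) until their
#' total equals `round(f_target * genome)` (the last tract is trimmed),
#' then scatters them over the chromosomes with proportionally
#' broken-stick gaps so that the realized fraction equals the target by
#' construction.
#'
#' @param f_target Target genome fraction in ROH, in (0, 1).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param mean_tract,min_tract Tract-length model (bp).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
plant_roh_tracts <- function(f_target, chrom_lengths, mean_tract = 2e6,
                             min_tract = 1.2e6) {
  stopifnot(f_target > 0, f_target < 1)
  genome <- sum(chrom_lengths)
  target_bp <- round(f_target * genome)
  if (min_tract > target_bp) {
    stop("infeasible ROH spec: minimum tract length ", min_tract,
         " exceeds the target ROH total ", target_bp, " bp", call. = FALSE)
  }
  lens <- numeric(0)
  while (sum(lens) < target_bp) {
    lens <- c(lens, round(min_tract +
                            stats::rexp(1, 1 / (mean_tract - min_tract))))
  }
  excess <- sum(lens) - target_bp
  lens[length(lens)] <- lens[length(lens)] - excess
  if (lens[length(lens)] < min_tract / 2 && length(lens) > 1) {
    # fold a degenerate trimmed remainder into the previous tract
    lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }

  # allocate tracts to chromosomes by capacity, then place with
  # broken-stick gaps
  chrom_of <- character(length(lens))
  remaining <- chrom_lengths
  ord <- order(lens, decreasing = TRUE)
  for (i in ord) {
    fit <- names(remaining)[remaining >= lens[i]]
    if (length(fit) == 0) {
      stop("infeasible ROH spec: tract of ", lens[i],
           " bp exceeds every chromosome's remaining capacity",
           call. = FALSE)
    }
    pick <- if (length(fit) == 1) fit else
      sample(fit, 1, prob = remaining[fit])
    chrom_of[i] <- pick
    remaining[pick] <- remaining[pick] - lens[i]
  }

  purrr::map(names(chrom_lengths), function(ch) {
    ls <- lens[chrom_of == ch]
    if (length(ls) == 0) return(NULL)
    slack <- chrom_lengths[[ch]] - sum(ls)
    cuts <- sort(stats::runif(length(ls)))
    gaps <- round(c(cuts, 1) * slack) - round(c(0, cuts) * slack)
    starts <- cumsum(gaps[seq_along(ls)] + dplyr::lag(ls, default = 0))
    tibble::tibble(chrom = ch, start = starts, end = starts + ls)
  }) |> purrr::list_rbind() |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Simulate one genome with planted ROH and heterozygous sites
#'
#' Convenience generator for testing ROH recovery: plants tracts at a
#' target genome fraction and scatters heterozygous sites as a Poisson
#' process with different densities inside and outside the tracts.
#'
#' @param f_target Target ROH genome fraction.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param het_rate_outside,het_rate_inside Heterozygous sites per bp.
#' @param sample Sample identifier for the emitted tables.
#' @param ... Passed to [plant_roh_tracts()].
#' @return A list `het_positions` (tibble `sample`, `chrom`, `pos`),
#'   `truth` (tibble of planted intervals), `realized_f`.
#' @export
simulate_planted_roh <- function(f_target, chrom_lengths,
                                 het_rate_outside = 1e-3,
                                 het_rate_inside = 0,
                                 sample = "S1", ...) {
  tracts <- plant_roh_tracts(f_target, chrom_lengths, ...)
  het <- purrr::map(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_out <- stats::rpois(1, het_rate_outside * len)
    pos <- sort(sample.int(len, min(n_out, len)))
    tr <- tracts[tracts$chrom == ch, ]
    inside <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(tr))) {
      inside <- inside | (pos > tr$start[i] & pos <= tr$end[i])
    }
    pos <- pos[!inside]
    if (het_rate_inside > 0 && nrow(tr) > 0) {
      for (i in seq_len(nrow(tr))) {
        k <- stats::rpois(1, het_rate_inside * (tr$end[i] - tr$start[i]))
        if (k > 0) {
          pos <- c(pos, tr$start[i] + sample.int(tr$end[i] - tr$start[i], k))
        }
      }
      pos <- sort(unique(pos))
    }
    tibble::tibble(sample = sample, chrom = ch, pos = pos)
  }) |> purrr::list_rbind()
  tracts$sample <- sample
  list(het_positions = het,
       truth = dplyr::select(tracts, "sample", "chrom", "start", "end"),
       realized_f = sum(tracts$end - tracts$start) / sum(chrom_lengths))
}

#' Simulate ROH segments of one genome under constant Ne
#'
#' Sequential-Markov-coalescent segment model: the genome is a renewal
#' sequence of IBD segments; each segment's pairwise coalescence age T
#' is drawn so that the point-wise age marginal is Geometric(1/(2Ne))
#' (size-biased draw: `T = G1 + G2 - 1` with `Gi ~ Geom(1/(2Ne))`), and
#' its length is the recombination-clock expectation `100 / (2 r T)` Mb
#' for that age. The point-wise probability of coalescing within t
#' generations is then `1 - (1 - 1/(2Ne))^t`, the model inverted by
#' [ne_trajectory()]. Tract-length dispersion around the clock
#' expectation is deliberately not modelled: it is what makes the
#' length-to-age mapping of the estimator identifiable, and real data
#' carry an additional (caller- and mutation-dependent) blurring that
#' no desk-scale generator reproduces.
#'
#' @param ne Constant effective population size.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param recombination_rate r in cM/Mb.
#' @param min_length_bp Segments shorter than this are dropped from the
#'   output (unobservable as ROH).
#' @param sample Sample identifier.
#' @return A tibble `sample`, `chrom`, `start`, `end`, `p_roh`,
#'   `age_generations` (0-based half-open coordinates).
#' @export
simulate_roh_coalescent <- function(ne, chrom_lengths,
                                    recombination_rate = 2.8,
                                    min_length_bp = 1e5,
                                    sample = "S1") {
  stopifnot(ne > 0.5)
  p <- 1 / (2 * ne)
  purrr::map(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    pos <- 0
    starts <- ends <- ages <- numeric(0)
    # draw segments in chunks for speed
    while (pos < len) {
      m <- 256L
      t_seg <- stats::rgeom(m, p) + stats::rgeom(m, p) + 1
      l_seg <- pmax(100 / (2 * recombination_rate * t_seg) * 1e6, 1)
      stop_at <- cumsum(l_seg) + pos
      keep <- which(stop_at - l_seg < len)
      starts <- c(starts, (stop_at - l_seg)[keep])
      ends <- c(ends, pmin(stop_at[keep], len))
      ages <- c(ages, t_seg[keep])
      pos <- stop_at[m]
    }
    tibble::tibble(sample = sample, chrom = ch,
                   start = round(starts), end = round(ends),
                   p_roh = 1, age_generations = ages)
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(.data$end - .data$start >= min_length_bp)
}

#' Deterministic selection step against a recessive deleterious allele
#'
#' Post-selection frequency of a derived allele at frequency `q` under
#' recessive selection with genotype fitnesses 1, 1, 1 - s:
#' `q' = q (1 - s q) / (1 - s q^2)`. When mean fitness is zero (a fixed
#' lethal: `s = 1`, `q = 1`) the homozygotes contribute nothing and the
#' frequency is 0.
#'
#' @param q Derived-allele frequency in `[0, 1]`.
#' @param s Selection coefficient in `[0, 1]`.
#' @return Post-selection frequency.
#' @export
wf_select_freq <- function(q, s) {
  w_bar <- 1 - s * q^2
  ifelse(w_bar > 0, q * (1 - s * q) / w_bar, 0)
}

#' Forward Wright-Fisher simulation of a purging contrast
#'
#' Simulates, per mutation class, unlinked derived alleles evolving in
#' two populations split from a common pool: a large reference
#' population and a small focal population in which inbreeding exposes
#' recessive deleterious alleles to selection. Selection is recessive
#' multiplicative (genotype fitnesses 1, 1, 1 - s) with class-specific
#' coefficients; each generation applies deterministic selection
#' followed by binomial drift. Derived-allele totals are then counted
#' in equal-sized samples from both populations, the input to
#' [percent_reduction()].
#'
#' @param config A [sim_config()]; `selection` supplies the per-class
#'   coefficients (the synonymous class must be neutral).
#' @param n_sites_per_class Unlinked sites simulated per class.
#' @param ne_reference,ne_focal Diploid population sizes.
#' @param generations Number of generations after the split.
#' @param n_sample Individuals sampled per population for the totals.
#' @param init_alpha,init_beta Beta parameters of the shared initial
#'   derived-allele frequencies (skewed low by default).
#' @param dir Optional directory: when given, the sampled individuals
#'   are also emitted as a VCF + annotation/population files (the same
#'   file set as [simulate_dataset()]).
#' @return A list with `totals` (tibble `population`, `class`,
#'   `total_derived`, `n_sites`), `frequencies` (final per-site
#'   frequencies), and `paths` when `dir` is given.
#' @export
simulate_purging_pair <- function(config = sim_config(),
                                  n_sites_per_class = 1000L,
                                  ne_reference = 500L, ne_focal = 25L,
                                  generations = 100L, n_sample = 20L,
                                  init_alpha = 0.5, init_beta = 5,
                                  dir = NULL) {
  stopifnot(ne_reference > 0, ne_focal > 0, generations > 0)
  sel <- config$selection
  stopifnot(sel[["synonymous"]] == 0)
  classes <- names(sel)

  evolve <- function(q0, s, n_dip, gens) {
    q <- q0
    for (g in seq_len(gens)) {
      q <- stats::rbinom(length(q), 2L * n_dip,
                         wf_select_freq(q, s)) / (2 * n_dip)
    }
    q
  }

  res <- purrr::map(classes, function(cls) {
    q0 <- stats::rbeta(n_sites_per_class, init_alpha, init_beta)
    q_ref <- evolve(q0, sel[[cls]], ne_reference, generations)
    q_foc <- evolve(q0, sel[[cls]], ne_focal, generations)
    cnt_ref <- stats::rbinom(length(q_ref), 2L * n_sample, q_ref)
    cnt_foc <- stats::rbinom(length(q_foc), 2L * n_sample, q_foc)
    list(
      totals = tibble::tibble(
        population = c("reference", "focal"), class = cls,
        total_derived = c(sum(cnt_ref), sum(cnt_foc)),
        n_sites = n_sites_per_class),
      freqs = tibble::tibble(class = cls, site = seq_along(q0),
                             q_init = q0, q_reference = q_ref,
                             q_focal = q_foc))
  })
  totals <- purrr::list_rbind(purrr::map(res, "totals"))
  freqs <- purrr::list_rbind(purrr::map(res, "freqs"))

  out <- list(totals = totals, frequencies = freqs)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    n_total <- nrow(freqs)
    sites <- tibble::tibble(
      chrom = "chr1", pos = seq_len(n_total) * 1000L,
      ref = "A", alt = "T", site_type = "snp",
      qual = 1000, qd = 25, fs = 1, mq = 55,
      mq_rank_sum = 0, read_pos_rank_sum = 0, dp = NA_real_)
    draw <- function(q) {
      matrix(stats::rbinom(n_total * n_sample, 2L, rep(q, n_sample)),
             nrow = n_total)
    }
    gt <- cbind(draw(freqs$q_reference), draw(freqs$q_focal))
    colnames(gt) <- c(sprintf("REF%02d", seq_len(n_sample)),
                      sprintf("FOC%02d", seq_len(n_sample)))
    pops_tab <- tibble::tibble(
      sample = colnames(gt),
      population = rep(c("reference", "focal"), each = n_sample))
    gm <- genotype_matrix(sites, gt, populations = pops_tab)
    term_of <- c(synonymous = "synonymous_variant",
                 missense = "missense_variant",
                 nonsense = "stop_gained",
                 other = "intergenic_region")
    ann <- tibble::tibble(chrom = "chr1", pos = sites$pos,
                          effects = unname(term_of[freqs$class]),
                          gerp = NA_real_)
    paths <- list(vcf = file.path(dir, "purging.vcf"),
                  populations = file.path(dir, "populations.tsv"),
                  annotations = file.path(dir, "annotations.tsv"))
    write_genotypes(gm, paths$vcf)
    readr::write_tsv(pops_tab, paths$populations, col_names = FALSE)
    readr::write_tsv(ann, paths$annotations)
    out$paths <- paths
  }
  out
}
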