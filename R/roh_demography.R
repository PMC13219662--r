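#' ROH and demography configuration
#'
#' Parameters for runs-of-homozygosity based inbreeding and recent-Ne
#' inference. Defaults follow standard practice for squamates lacking a
#' species-specific genetic map: the chicken recombination rate of
#' 2.8 cM/Mb, a generation time of 2 years, ROHs counted from 1 Mb at a
#' posterior threshold of 0.9.
#'
#' @param min_roh_length Minimum ROH length (bp) entering F_ROH
#'   (default 1 Mb).
#' @param p_threshold Strict lower bound on the ROH posterior
#'   probability (default 0.9).
#' @param recombination_rate Recombination rate r in cM/Mb (default 2.8).
#' @param generation_time Years per generation (default 2).
#' @param length_bins Matrix-like list of ROH length bins in Mb,
#'   half-open `[low, high)`; default `[1,4), [4,16), [16,64)`.
#' @param genome_length Callable autosomal genome length in bp.
#' @param bin_representative `"geometric"` (default) or `"midpoint"`:
#'   how the representative length of a bin is formed.
#' @return A list of class `roh_config`.
#' @export
roh_config <- function(min_roh_length = 1e6, p_threshold = 0.9,
                       recombination_rate = 2.8, generation_time = 2,
                       length_bins = list(c(1, 4), c(4, 16), c(16, 64)),
                       genome_length = NULL,
                       bin_representative = c("geometric", "midpoint")) {
  stopifnot(recombination_rate > 0, generation_time > 0,
            is.null(genome_length) || genome_length > 0)
  bins <- do.call(rbind, length_bins)
  if (!is.null(bins)) {
    stopifnot(ncol(bins) == 2, all(bins[, 2] > bins[, 1]),
              !is.unsorted(as.vector(t(bins))))
  }
  structure(list(
    min_roh_length = min_roh_length,
    p_threshold = p_threshold,
    recombination_rate = recombination_rate,
    generation_time = generation_time,
    length_bins = bins,
    genome_length = genome_length,
    bin_representative = match.arg(bin_representative)
  ), class = "roh_config")
}

#' Read/write ROH intervals
#'
#' BED-like TSV with columns `sample`, `chrom`, `start`, `end`
#' (0-based half-open) and optionally `p_roh` (assumed 1 when absent),
#' e.g. as produced by an external HMM-based ROH caller.
#'
#' @param path File path.
#' @return A tibble of ROH intervals.
#' @export
read_roh <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample", "chrom", "start", "end") %in% names(tab)))
  if (!"p_roh" %in% names(tab)) tab$p_roh <- 1
  stopifnot(all(tab$end > tab$start))
  tab
}

#' @rdname read_roh
#' @param intervals A tibble of ROH intervals.
#' @export
write_roh <- function(intervals, path) {
  readr::write_tsv(intervals, path)
  invisible(path)
}

# Merge strictly overlapping intervals within (sample, chrom); abutting
# tracts (start == previous end) are distinct ROHs and stay separate.
merge_roh <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  intervals |>
    dplyr::mutate(start = as.numeric(.data$start),
                  end = as.numeric(.data$end)) |>
    dplyr::arrange(.data$sample, .data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::mutate(
      new_run = cumsum(.data$start >=
                         dplyr::lag(cummax(.data$end), default = -Inf))) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$new_run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     p_roh = min(.data$p_roh), .groups = "drop") |>
    dplyr::select(-dplyr::any_of("new_run")) |>
    dplyr::select("sample", "chrom", "start", "end", "p_roh")
}

#' Window-based ROH delineation
#'
#' A simple deterministic stand-in for probabilistic HMM-based ROH
#' callers: each chromosome is tiled into fixed non-overlapping windows
#' and a window is called ROH when it contains at most
#' `max_het_per_window` heterozygous sites; adjacent ROH windows are
#' merged. Called intervals get `p_roh = 1`. Externally called
#' intervals (with true posteriors) can be supplied to the downstream
#' functions instead via [read_roh()].
#'
#' @param het_positions Tibble of heterozygous-site positions with
#'   columns `sample`, `chrom`, `pos` (1-based).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_bp Window size in bp (> 0).
#' @param max_het_per_window Maximum heterozygous sites tolerated per
#'   ROH window.
#' @param samples Samples to call; defaults to those present in
#'   `het_positions` (pass explicitly to call ROH for samples with no
#'   het sites at all).
#' @return A tibble `sample`, `chrom`, `start`, `end` (0-based
#'   half-open), `p_roh`.
#' @export
call_roh_windows <- function(het_positions, chrom_lengths, window_bp = 1e5,
                             max_het_per_window = 0L, samples = NULL) {
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  if (is.null(samples)) samples <- unique(het_positions$sample)
  chroms <- names(chrom_lengths)
  grid <- tidyr::expand_grid(sample = samples, chrom = chroms)
  purrr::pmap(grid, function(sample, chrom) {
    len <- chrom_lengths[[chrom]]
    n_win <- ceiling(len / window_bp)
    pos <- het_positions$pos[het_positions$sample == sample &
                               het_positions$chrom == chrom]
    win <- pmin(floor((pos - 1) / window_bp), n_win - 1)
    counts <- tabulate(win + 1L, nbins = n_win)
    is_roh <- counts <= max_het_per_window
    if (!any(is_roh)) return(NULL)
    r <- rle(is_roh)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- r$values
    tibble::tibble(
      sample = sample, chrom = chrom,
      start = (starts[keep] - 1) * window_bp,
      end = pmin(stops[keep] * window_bp, len),
      p_roh = 1)
  }) |> purrr::list_rbind()
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Fraction of the genome lying in merged ROHs longer than the minimum
#' length, at posterior probability above the threshold — a genomic
#' estimate of the inbreeding coefficient F.
#'
#' @param intervals Tibble of ROH intervals (`sample`, `chrom`,
#'   `start`, `end`, `p_roh`), 0-based half-open.
#' @param config An [roh_config()] with `genome_length` set.
#' @return A tibble `sample`, `froh`, `n_roh`, `roh_bp` (one row per
#'   sample present in `intervals`).
#' @export
froh <- function(intervals, config = roh_config()) {
  stopifnot(inherits(config, "roh_config"), !is.null(config$genome_length))
  if (nrow(intervals) > 0 &&
      any(intervals$end - intervals$start > config$genome_length)) {
    stop("interval longer than genome_length: coordinate mismatch",
         call. = FALSE)
  }
  kept <- intervals |>
    dplyr::filter(.data$p_roh > config$p_threshold) |>
    merge_roh() |>
    dplyr::filter(.data$end - .data$start >= config$min_roh_length)
  out <- kept |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_roh = dplyr::n(),
                     roh_bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::mutate(froh = .data$roh_bp / config$genome_length)
  all_samples <- unique(intervals$sample)
  dplyr::left_join(tibble::tibble(sample = all_samples), out,
                   by = "sample") |>
    tidyr::replace_na(list(n_roh = 0L, roh_bp = 0, froh = 0)) |>
    dplyr::select("sample", "froh", "n_roh", "roh_bp")
}

#' Genome fraction in ROH length classes
#'
#' @param intervals Tibble of ROH intervals.
#' @param config An [roh_config()] with `length_bins` and
#'   `genome_length` set; bins are `[low, high)` in Mb.
#' @return A tibble `sample`, `bin_low_mb`, `bin_high_mb`, `n_roh`,
#'   `fraction`.
#' @export
roh_length_classes <- function(intervals, config = roh_config()) {
  stopifnot(!is.null(config$length_bins), !is.null(config$genome_length))
  kept <- intervals |>
    dplyr::filter(.data$p_roh > config$p_threshold) |>
    merge_roh() |>
    dplyr::mutate(length_mb = (.data$end - .data$start) / 1e6)
  bins <- config$length_bins
  samples <- unique(intervals$sample)
  purrr::map(seq_len(nrow(bins)), function(b) {
    inbin <- kept$length_mb >= bins[b, 1] & kept$length_mb < bins[b, 2]
    kept[inbin, ] |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(n_roh = dplyr::n(),
                       bp = sum(.data$end - .data$start),
                       .groups = "drop") |>
      dplyr::right_join(tibble::tibble(sample = samples), by = "sample") |>
      tidyr::replace_na(list(n_roh = 0L, bp = 0)) |>
      dplyr::mutate(bin_low_mb = bins[b, 1], bin_high_mb = bins[b, 2],
                    fraction = .data$bp / config$genome_length)
  }) |>
    purrr::list_rbind() |>
    dplyr::select("sample", "bin_low_mb", "bin_high_mb", "n_roh",
                  "fraction")
}

#' Expected coalescent age of an ROH of a given length
#'
#' `g = 100 / (2 r L)`: the expected number of generations back to the
#' common ancestor of the two IBD haplotypes forming an ROH of length
#' `L` Mb under recombination rate `r` cM/Mb.
#'
#' @param length_mb ROH length in Mb (> 0).
#' @param recombination_rate r in cM/Mb (> 0; default 2.8).
#' @return Age in generations.
#' @export
roh_age <- function(length_mb, recombination_rate = 2.8) {
  if (any(length_mb <= 0) || any(recombination_rate <= 0)) {
    stop("length and recombination rate must be positive", call. = FALSE)
  }
  100 / (2 * recombination_rate * length_mb)
}

#' Effective population size from an ROH genome fraction
#'
#' Inverts `F_ROH,t = 1 - (1 - 1/(2 Ne))^t`: the expected fraction of
#' the genome that has coalesced within the last `t` generations in a
#' population of constant size `Ne`, giving
#' `Ne = 1 / (2 (1 - (1 - F)^(1/t)))`.
#'
#' @param f ROH genome fraction, strictly between 0 and 1 (`f = 0`
#'   returns `Inf`, `f = 1` returns the 0.5 limit, with a warning).
#' @param t Age in generations (> 0).
#' @param complement Optional precomputed `1 - f`; supply it (e.g. from
#'   [froh_survival()]) when `f` is so close to 1 that forming `1 - f`
#'   from `f` would lose precision.
#' @return Effective population size.
#' @export
ne_from_froh <- function(f, t, complement = NULL) {
  stopifnot(all(t > 0))
  if (is.null(complement)) complement <- 1 - f
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  if (any(f == 0 | f == 1)) {
    warning("f at the boundary: Ne is Inf at f = 0 and 0.5 at f = 1",
            call. = FALSE)
  }
  1 / (2 * -expm1(log(complement) / t))
}

#' Forward model: expected ROH fraction under constant Ne
#'
#' `F_ROH,t = 1 - (1 - 1/(2 Ne))^t`; the inverse of [ne_from_froh()].
#' `froh_survival()` returns the complementary fraction
#' `(1 - 1/(2 Ne))^t` at full precision, useful when `F` is within
#' rounding distance of 1.
#'
#' @param ne Effective population size (> 0.5).
#' @param t Age in generations.
#' @return Expected genome fraction coalesced within `t` generations.
#' @export
froh_expected <- function(ne, t) -expm1(t * log1p(-1 / (2 * ne)))

#' @rdname froh_expected
#' @export
froh_survival <- function(ne, t) exp(t * log1p(-1 / (2 * ne)))

#' Recent-Ne trajectory from ROH length classes
#'
#' For each ROH length bin `[L_low, L_high)`: the genome fraction in
#' ROHs of that length (averaged over the samples present), a
#' representative length L (geometric mean of the bounds by default),
#' its age `t = roh_age(L)` (reported in generations and years), and
#' `Ne = ne_from_froh(F_bin, t)`. Bins with zero fraction are reported
#' with `ne = NA` (undetermined). The composition uses exactly
#' [roh_age()] and [ne_from_froh()], with no hidden transforms.
#'
#' @param intervals Tibble of ROH intervals for the samples of one
#'   population.
#' @param config An [roh_config()] with bins and `genome_length` set.
#' @return A tibble `bin_low_mb`, `bin_high_mb`, `length_mb`,
#'   `age_generations`, `age_years`, `n_roh`, `f_bin`, `ne`.
#' @export
ne_trajectory <- function(intervals, config = roh_config()) {
  if (is.null(config$length_bins) || nrow(config$length_bins) == 0) {
    stop("length_bins must be non-empty", call. = FALSE)
  }
  classes <- roh_length_classes(intervals, config)
  bins <- config$length_bins
  if (nrow(classes) == 0) {
    # no samples at all: report every bin as empty/undetermined
    classes <- tibble::tibble(
      sample = "none", bin_low_mb = bins[, 1], bin_high_mb = bins[, 2],
      n_roh = 0L, fraction = 0)
  }
  rep_l <- if (config$bin_representative == "geometric") {
    sqrt(bins[, 1] * bins[, 2])
  } else {
    (bins[, 1] + bins[, 2]) / 2
  }
  classes |>
    dplyr::group_by(.data$bin_low_mb, .data$bin_high_mb) |>
    dplyr::summarise(f_bin = mean(.data$fraction),
                     n_roh = sum(.data$n_roh), .groups = "drop") |>
    dplyr::arrange(.data$bin_low_mb) |>
    dplyr::mutate(
      length_mb = rep_l,
      age_generations = roh_age(.data$length_mb,
                                config$recombination_rate),
      age_years = .data$age_generations * config$generation_time,
      ne = ifelse(.data$f_bin > 0 & .data$f_bin < 1,
                  suppressWarnings(ne_from_froh(.data$f_bin,
                                                .data$age_generations)),
                  NA_real_)
    ) |>
    dplyr::select("bin_low_mb", "bin_high_mb", "length_mb",
                  "age_generations", "age_years", "n_roh", "f_bin", "ne")
}
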