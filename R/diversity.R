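#' Per-individual genome-wide heterozygosity
#'
#' Heterozygous genotype count divided by the number of non-missing
#' called sites (variant plus invariant), per individual. The matrix
#' must retain invariant callable sites, otherwise the denominator (and
#' thus the rate) is inflated.
#'
#' @param x A [genotype_matrix()].
#' @return A tibble `individual`, `population`, `n_het`, `n_called`,
#'   `heterozygosity` (`NA` when no sites are callable).
#' @export
heterozygosity <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  n_het <- colSums(x$gt == 1L, na.rm = TRUE)
  n_called <- colSums(!is.na(x$gt))
  tibble::tibble(
    individual = x$samples,
    population = x$populations$population,
    n_het = unname(n_het),
    n_called = unname(n_called),
    heterozygosity = ifelse(n_called > 0, n_het / n_called, NA_real_)
  )
}

#' Count biallelic SNPs segregating within populations
#'
#' A site counts for a population when both alleles are observed among
#' that population's non-missing genotypes (a heterozygote suffices);
#' sites monomorphic within the population do not count even if they
#' are polymorphic elsewhere.
#'
#' @param x A [genotype_matrix()].
#' @param populations Population labels (default: all).
#' @return A tibble `population`, `n_snps`.
#' @export
snp_count <- function(x, populations = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(populations)) {
    populations <- sort(unique(x$populations$population))
  }
  is_snp <- x$sites$site_type == "snp"
  purrr::map(populations, function(pop) {
    gp <- x$gt[is_snp, population_samples(x, pop), drop = FALSE]
    any_het <- rowSums(gp == 1L, na.rm = TRUE) > 0
    has_ref <- rowSums(gp == 0L, na.rm = TRUE) > 0
    has_alt <- rowSums(gp == 2L, na.rm = TRUE) > 0
    tibble::tibble(population = pop,
                   n_snps = sum(any_het | (has_ref & has_alt)))
  }) |> purrr::list_rbind()
}

#' Thin sites to a minimum pairwise distance
#'
#' Greedy left-to-right retention to obtain approximately independent
#' markers: a site is kept iff it lies at least `min_distance_bp` from
#' the last kept site on the same chromosome.
#'
#' @param x A [genotype_matrix()].
#' @param min_distance_bp Minimum distance in bp (default 50 kb).
#' @return A thinned `genotype_matrix`.
#' @export
thin_sites <- function(x, min_distance_bp = 50000) {
  stopifnot(inherits(x, "genotype_matrix"))
  keep <- logical(n_sites(x))
  last_chrom <- ""
  last_pos <- -Inf
  for (i in seq_len(n_sites(x))) {
    ch <- x$sites$chrom[i]
    p <- x$sites$pos[i]
    if (ch != last_chrom || p - last_pos >= min_distance_bp) {
      keep[i] <- TRUE
      last_chrom <- ch
      last_pos <- p
    }
  }
  subset_sites(x, which(keep))
}

#' Pairwise identity-by-state distance matrix
#'
#' For each pair of individuals, across sites where both are genotyped:
#' `IBS = (sum of shared allele counts) / (2 * shared sites)`, where a
#' site contributes `2 - |g_i - g_j|` shared alleles for genotype codes
#' `g`. The distance is `1 - IBS`, in `[0, 1]`. An alternative per-site
#' Hamming distance on genotype codes is available via `method`.
#'
#' @param x A [genotype_matrix()] with at least two samples.
#' @param method `"ibs"` (default) or `"hamming"`.
#' @return An object of class `ibs_dist`: list with `d` (symmetric
#'   distance matrix, zero diagonal), `n_sites` (shared-site counts) and
#'   `labels`.
#' @export
distance_matrix <- function(x, method = c("ibs", "hamming")) {
  stopifnot(inherits(x, "genotype_matrix"), n_samples(x) >= 2)
  method <- match.arg(method)
  gt <- x$gt
  ns <- ncol(gt)
  d <- matrix(0, ns, ns, dimnames = list(x$samples, x$samples))
  nshared <- matrix(0L, ns, ns, dimnames = dimnames(d))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      both <- !is.na(gt[, i]) & !is.na(gt[, j])
      n <- sum(both)
      if (n == 0) {
        stop("samples ", x$samples[i], " and ", x$samples[j],
             " share no genotyped sites: distance undefined",
             call. = FALSE)
      }
      diffs <- abs(gt[both, i] - gt[both, j])
      dij <- if (method == "ibs") {
        1 - sum(2 - diffs) / (2 * n)
      } else {
        mean(diffs > 0)
      }
      d[i, j] <- d[j, i] <- dij
      nshared[i, j] <- nshared[j, i] <- n
    }
  }
  structure(list(d = d, n_sites = nshared, labels = x$samples),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat("<ibs_dist> ", length(x$labels), " individuals\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Tidy a distance matrix
#' @param x An `ibs_dist`.
#' @param ... Unused.
#' @return A tibble `sample1`, `sample2`, `distance`, `n_sites` (one
#'   row per unordered pair).
#' @method tidy ibs_dist
#' @export
tidy.ibs_dist <- function(x, ...) {
  pairs <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    sample1 = x$labels[pairs[, 1]],
    sample2 = x$labels[pairs[, 2]],
    distance = x$d[pairs],
    n_sites = x$n_sites[pairs]
  )
}

#' Write a distance matrix as square TSV
#' @param x An `ibs_dist` (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(x, path) {
  m <- if (inherits(x, "ibs_dist")) x$d else x
  readr::write_tsv(
    tibble::as_tibble(cbind(sample = rownames(m), as.data.frame(m))),
    path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration with two deterministic
#' refinements: ties on the Q criterion are broken by the lowest index
#' pair (row-major over the current matrix), and negative branch
#' lengths are clamped to zero with the deficit transferred to the
#' sister branch (their sum — the joined pair's distance split — is
#' preserved). On additive matrices NJ reconstructs the generating tree
#' exactly. The result is unrooted.
#'
#' @param dm An `ibs_dist` from [distance_matrix()], or a symmetric
#'   numeric matrix with labelled rows, with at least 3 taxa.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "ibs_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  nodes <- labels  # newick fragment per active node

  while (length(nodes) > 3) {
    n <- length(nodes)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    hit <- which(q == min(q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]

    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    new_node <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], li, nodes[j], lj)
    nodes <- c(nodes[keep], new_node)
    dimnames(d_new) <- NULL
    d <- d_new
  }

  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- d[1, 2] - la
  lc <- d[1, 3] - la
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    nodes[1], la, nodes[2], lb, nodes[3], lc)
  ape::read.tree(text = newick)
}

#' Write a tree in Newick format
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
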