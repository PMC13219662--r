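test_that("effect classification takes the first term and maps impacts", {
  got <- classify_effects(c("missense_variant&synonymous_variant",
                            "stop_gained",
                            "synonymous_variant",
                            "intron_variant",
                            ""))
  expect_equal(got$effect_class,
               c("missense", "nonsense", "synonymous", "other", "other"))
  expect_equal(got$impact, c("MODERATE", "HIGH", "LOW", "other", "other"))

  # random annotation lists vs a table-lookup oracle
  set.seed(9)
  terms <- c("synonymous_variant", "missense_variant", "stop_gained",
             "start_gained", "start_lost", "splice_acceptor_variant",
             "splice_donor_variant", "intron_variant", "upstream_gene")
  lookup <- c(synonymous_variant = "synonymous",
              missense_variant = "missense",
              stop_gained = "nonsense", start_gained = "nonsense",
              start_lost = "nonsense",
              splice_acceptor_variant = "nonsense",
              splice_donor_variant = "nonsense")
  lists <- replicate(1000, sample(terms, sample(1:4, 1), replace = TRUE),
                     simplify = FALSE)
  got <- classify_effects(vapply(lists, paste, "", collapse = "&"))
  want <- vapply(lists, function(l) {
    cls <- lookup[l[[1]]]
    if (is.na(cls)) "other" else unname(cls)
  }, "")
  expect_equal(got$effect_class, want)
})

# 3 class sites, 2 individuals in one population; ancestral mixes ref/alt
load_fixture <- function(gt) {
  gm <- polar_fixture_load(gt)
  pol <- polarize_dataset(gm, outgroup_spec(paste0("OGA", 1:4),
                                            paste0("OGB", 1:2)),
                          c("P1"))
  ann <- annotate_polarized(
    pol, tibble::tibble(chrom = "chr1", pos = pol$pos,
                        effect_class = "missense", impact = "MODERATE",
                        gerp = 5))
  list(gm = gm, ann = ann)
}

polar_fixture_load <- function(ing_gt) {
  ing_gt <- as.matrix(ing_gt)
  og <- matrix(0L, nrow(ing_gt), 6)
  gt <- cbind(ing_gt, og)
  colnames(gt) <- c("I1", "I2", paste0("OGA", 1:4), paste0("OGB", 1:2))
  pops <- tibble::tibble(
    sample = colnames(gt),
    population = c("P1", "P1", rep("outgroupA", 4), rep("outgroupB", 2)))
  make_gm(gt, populations = pops)
}

test_that("individual load counts het and homozygous-derived genotypes", {
  fx <- load_fixture(rbind(c(1L, 1L),
                           c(1L, 2L),
                           c(2L, 0L)))
  cls <- list(missense = function(s) s$effect_class == "missense")
  li <- individual_load(fx$ann, fx$gm, cls, samples = c("I1", "I2"))
  i1 <- li[li$individual == "I1", ]
  i2 <- li[li$individual == "I2", ]
  expect_equal(c(i1$masked, i1$realized), c(2L, 1L))
  expect_equal(i1$derived_total, 2L + 2L * 1L)
  expect_equal(c(i2$masked, i2$realized), c(1L, 1L))
  # hom-ancestral contributes to neither component
  expect_equal(i2$derived_total, i2$masked + 2L * i2$realized)
})

test_that("individual load equals a brute-force per-genotype recount", {
  cfg <- sim_config(seed = 17, n_sites = 2000)
  d <- simulate_dataset(cfg)
  pol <- polarize_dataset(d$matrix, d$outgroups, c("LC", "ST", "SI"))
  ann <- annotate_polarized(
    pol, dplyr::mutate(classify_effects(d$annotations$effects),
                       chrom = d$annotations$chrom,
                       pos = d$annotations$pos,
                       gerp = d$annotations$gerp))
  li <- suppressWarnings(individual_load(ann, d$matrix))

  # oracle: literal loop over polarized missense sites
  keep <- ann$status == "polarized" & ann$effect_class == "missense"
  sub <- ann[keep, ]
  key <- paste(d$matrix$sites$chrom, d$matrix$sites$pos)
  idx <- match(paste(sub$chrom, sub$pos), key)
  for (smp in c("LC01", "SI05")) {
    m <- 0L; r <- 0L
    for (i in seq_along(idx)) {
      g <- d$matrix$gt[idx[i], smp]
      if (is.na(g)) next
      der <- if (sub$ancestral_is[i] == "ref") g else 2L - g
      if (der == 1L) m <- m + 1L
      if (der == 2L) r <- r + 1L
    }
    row <- li[li$individual == smp & li$class == "missense", ]
    expect_equal(row$masked, m)
    expect_equal(row$realized, r)
  }
  # conservation identity for every individual and class
  expect_true(all(li$derived_total == li$masked + 2L * li$realized))
})

test_that("population load uses a strict frequency threshold over called alleles", {
  # 10 diploids: derived count 19/20 counts, 18/20 does not
  ing <- rbind(c(rep(2L, 9), 1L),   # 19/20 = 0.95
               c(rep(2L, 9), 0L))   # 18/20 = 0.90
  og <- matrix(0L, 2, 6)
  gt <- cbind(ing, og)
  colnames(gt) <- c(paste0("I", 1:10), paste0("OGA", 1:4),
                    paste0("OGB", 1:2))
  pops <- tibble::tibble(
    sample = colnames(gt),
    population = c(rep("P1", 10), rep("outgroupA", 4),
                   rep("outgroupB", 2)))
  gm <- make_gm(gt, populations = pops)
  pol <- polarize_dataset(gm, outgroup_spec(paste0("OGA", 1:4),
                                            paste0("OGB", 1:2)), "P1")
  ann <- annotate_polarized(
    pol, tibble::tibble(chrom = "chr1", pos = pol$pos,
                        effect_class = "missense", gerp = NA_real_))
  pl <- population_load(ann, list(missense = function(s)
    s$effect_class == "missense"))
  expect_equal(pl$high_freq_count, 1L)

  # monotone non-increasing in the threshold
  th <- c(0.5, 0.7, 0.9, 0.94, 0.96)
  counts <- vapply(th, function(t) {
    population_load(ann, list(m = function(s) rep(TRUE, nrow(s))),
                    freq_threshold = t)$high_freq_count
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("derived-allele totals are additive over disjoint classes", {
  cfg <- sim_config(seed = 23, n_sites = 1500)
  d <- simulate_dataset(cfg)
  pol <- polarize_dataset(d$matrix, d$outgroups, c("LC", "ST", "SI"))
  ann <- annotate_polarized(
    pol, dplyr::mutate(classify_effects(d$annotations$effects),
                       chrom = d$annotations$chrom,
                       pos = d$annotations$pos,
                       gerp = d$annotations$gerp))
  cls <- list(
    synonymous = function(s) s$effect_class == "synonymous",
    missense = function(s) s$effect_class == "missense",
    union = function(s) s$effect_class %in% c("synonymous", "missense"))
  tot <- derived_allele_totals(ann, cls)
  wide <- tidyr::pivot_wider(tot[c("population", "class", "total_derived")],
                             names_from = "class",
                             values_from = "total_derived")
  expect_equal(wide$union, wide$synonymous + wide$missense)
  # single-site sanity: totals equal the sum of per-population counts
  one <- ann[ann$status == "polarized", ][1, ]
  single <- derived_allele_totals(
    one, list(all = function(s) rep(TRUE, nrow(s))))
  expect_equal(single$total_derived,
               c(one$derived_LC, one$derived_ST, one$derived_SI))
})
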