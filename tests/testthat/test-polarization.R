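spec <- outgroup_spec(paste0("OGA", 1:4), paste0("OGB", 1:2))

test_that("ancestral assignment follows the outgroup support rules", {
  # unanimity
  r <- assign_ancestral(c(0L, 0L, 0L, 0L), c(0L, 0L), spec)
  expect_equal(r$allele, "ref")
  # 3-of-4 support in the distant outgroup suffices
  r <- assign_ancestral(c(0L, 0L, 0L, 2L), c(0L, 0L), spec)
  expect_equal(r$allele, "ref")
  # 2-2 split: no consensus
  r <- assign_ancestral(c(0L, 0L, 2L, 2L), c(0L, 0L), spec)
  expect_equal(r$status, "discarded_no_consensus")
  # any heterozygous outgroup discards the site
  r <- assign_ancestral(c(0L, 0L, 0L, 0L), c(1L, 0L), spec)
  expect_equal(r$status, "discarded_het_outgroup")
  # near outgroup must agree over its called individuals
  r <- assign_ancestral(c(0L, 0L, 0L, 0L), c(2L, 2L), spec)
  expect_equal(r$status, "discarded_no_consensus")
  # all outgroups missing
  r <- assign_ancestral(rep(NA_integer_, 4), rep(NA_integer_, 2), spec)
  expect_equal(r$status, "discarded_no_consensus")
})

test_that("assignment agrees with the brute-force evaluator on random configurations", {
  set.seed(3)
  states <- c(0L, 1L, 2L, NA_integer_)
  for (k in 1:300) {
    ga <- sample(states, 4, replace = TRUE)
    gb <- sample(states, 2, replace = TRUE)
    got <- assign_ancestral(ga, gb, spec)
    want <- oracle_assign(ga, gb)
    expect_equal(got$status == "polarized", want$status == "polarized")
    expect_equal(got$allele, want$allele)
  }
})

polar_fixture <- function(ing_gt, og_code = 0L) {
  # 4 ingroup samples (2 pops) + 6 outgroups, one site per row of ing_gt
  ing_gt <- as.matrix(ing_gt)
  og <- matrix(og_code, nrow(ing_gt), 6)
  gt <- cbind(ing_gt, og)
  colnames(gt) <- c("I1", "I2", "I3", "I4",
                    paste0("OGA", 1:4), paste0("OGB", 1:2))
  pops <- tibble::tibble(
    sample = colnames(gt),
    population = c("P1", "P1", "P2", "P2",
                   rep("outgroupA", 4), rep("outgroupB", 2)))
  make_gm(gt, populations = pops)
}

test_that("site selection discards no-derived and fixed-derived sites", {
  gm <- polar_fixture(rbind(
    c(0L, 0L, 0L, 0L),   # no derived allele in the ingroup
    c(2L, 2L, 2L, 2L),   # derived fixed across the pooled ingroup
    c(0L, 1L, 2L, 0L)))  # segregating: analyzable
  pol <- polarize_dataset(gm, spec, c("P1", "P2"))
  expect_equal(pol$status, c("discarded_no_derived",
                             "discarded_fixed_derived", "polarized"))
  expect_equal(pol$derived_P1[3], 1L)
  expect_equal(pol$derived_P2[3], 2L)
  expect_equal(pol$called_P1[3], 4L)
  # statuses partition the input
  expect_equal(sum(polarization_summary(pol)$n), n_sites(gm))
})

test_that("derived counts are invariant under ref/alt relabelling", {
  set.seed(5)
  gt <- matrix(sample(c(0L, 1L, 2L), 40, replace = TRUE), 10, 4)
  gm <- polar_fixture(gt, og_code = 0L)
  pol <- polarize_dataset(gm, spec, c("P1", "P2"))

  flipped <- gm
  flipped$gt <- 2L - gm$gt
  tmp <- flipped$sites$ref
  flipped$sites$ref <- ifelse(is.na(flipped$sites$alt), tmp,
                              flipped$sites$alt)
  flipped$sites$alt[!is.na(flipped$sites$alt)] <-
    tmp[!is.na(flipped$sites$alt)]
  pol2 <- polarize_dataset(flipped, spec, c("P1", "P2"))
  expect_equal(pol2$status, pol$status)
  expect_equal(pol2$derived_P1, pol$derived_P1)
  expect_equal(pol2$derived_P2, pol$derived_P2)
  expect_equal(pol2$ancestral_allele, pol$ancestral_allele)
})

test_that("polarization recovers planted truth and degrades with outgroup mutation", {
  run_err <- function(m, seed) {
    cfg <- sim_config(seed = seed, n_sites = 4000, outgroup_mut_prob = m,
                      populations = tibble::tibble(
                        name = c("P1", "P2"), n_samples = c(6L, 6L),
                        theta = c(0.05, 0.2), roh_f = c(0, 0)))
    d <- simulate_dataset(cfg)
    pol <- polarize_dataset(d$matrix, d$outgroups, c("P1", "P2"))
    hit <- dplyr::inner_join(
      pol[pol$status == "polarized",
          c("chrom", "pos", "ancestral_allele")],
      d$truth$sites[, c("chrom", "pos", "ancestral_allele",
                        "outgroup_mutated")],
      by = c("chrom", "pos"), suffix = c("", "_truth"))
    list(err = mean(hit$ancestral_allele != hit$ancestral_allele_truth),
         mismatch_explained = all(
           hit$outgroup_mutated[hit$ancestral_allele !=
                                  hit$ancestral_allele_truth]))
  }
  r0 <- run_err(0, 21)
  r1 <- run_err(0.05, 21)
  r2 <- run_err(0.3, 21)
  expect_equal(r0$err, 0)            # no-noise limit: exact recovery
  expect_lt(r1$err, 0.01)            # >= 99% accuracy at realistic noise
  expect_true(r1$mismatch_explained) # every error traces to a mutation
  expect_true(r2$mismatch_explained)
  expect_lte(r0$err, r1$err)
  expect_lte(r1$err, r2$err)         # error monotone in branch mutation
})

test_that("empty ingroup population is a hard error", {
  gm <- polar_fixture(rbind(c(0L, 1L, 0L, 0L)))
  expect_error(polarize_dataset(gm, spec, c("P1", "P3")), "P3")
})
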