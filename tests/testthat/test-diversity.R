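test_that("heterozygosity counts hets over callable sites", {
  gt <- cbind(S1 = c(0L, 0L, 0L), S2 = c(1L, 0L, NA))
  gm <- make_gm(gt, site_type = c("snp", "invariant", "invariant"))
  h <- heterozygosity(gm)
  expect_equal(h$heterozygosity[h$individual == "S1"], 0)
  expect_equal(h$heterozygosity[h$individual == "S2"], 1 / 2)
  expect_equal(h$n_called[h$individual == "S2"], 2L)

  # the low-diversity regime: 1 het per 300 kb of callable genome
  expect_equal(1 / 300000, 3.33e-6, tolerance = 1e-3)

  # binomial oracle: estimates within 3 SD of the generating rate
  set.seed(19)
  n <- 30000
  for (p in c(1e-3, 1e-2)) {
    gt <- matrix(stats::rbinom(n, 1L, p), ncol = 1,
                 dimnames = list(NULL, "S1"))
    gm <- make_gm(gt)
    est <- heterozygosity(gm)$heterozygosity
    expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("per-population SNP counts require both alleles within the population", {
  gt <- cbind(A1 = c(1L, 2L, 0L, 2L), A2 = c(0L, 2L, 0L, NA),
              B1 = c(0L, 0L, 2L, 0L), B2 = c(0L, 0L, 0L, 0L))
  pops <- tibble::tibble(sample = colnames(gt),
                         population = c("A", "A", "B", "B"))
  gm <- make_gm(gt, populations = pops)
  sc <- snp_count(gm)
  # A: site1 het counts, site2 hom-alt in all -> monomorphic, site4 single
  # non-missing hom-alt -> monomorphic
  expect_equal(sc$n_snps[sc$population == "A"], 1L)
  expect_equal(sc$n_snps[sc$population == "B"], 1L)
  expect_equal(snp_count(gm, "C")$n_snps, 0L)

  # random matrices vs a brute-force per-population scan
  set.seed(29)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 4, replace = TRUE),
               200, 4, dimnames = list(NULL, colnames(gt)))
  gm <- make_gm(gt, populations = pops)
  sc <- snp_count(gm)
  for (pop in c("A", "B")) {
    cols <- pops$sample[pops$population == pop]
    want <- 0L
    for (i in 1:200) {
      g <- gt[i, cols]
      g <- g[!is.na(g)]
      alleles <- unique(c(if (any(g <= 1)) 0L, if (any(g >= 1)) 1L))
      if (length(alleles) == 2) want <- want + 1L
    }
    expect_equal(sc$n_snps[sc$population == pop], want)
  }
})

test_that("greedy thinning keeps sites at the minimum spacing", {
  gm <- make_gm(matrix(0L, 5, 1, dimnames = list(NULL, "S1")),
                pos = c(1L, 10000L, 60000L, 70000L, 120000L))
  thin <- thin_sites(gm, 50000)
  expect_equal(thin$sites$pos, c(1L, 60000L, 120000L))
  expect_identical(thin_sites(gm, 0)$sites$pos, gm$sites$pos)

  set.seed(37)
  pos <- sort(sample.int(1e6, 300))
  gm2 <- make_gm(matrix(0L, 300, 1, dimnames = list(NULL, "S1")),
                 pos = pos)
  kept <- thin_sites(gm2, 25000)$sites$pos
  expect_true(all(diff(kept) >= 25000))
})

test_that("IBS distances match the allele-sharing definition", {
  gt <- cbind(S1 = c(0L, 2L, 1L), S2 = c(0L, 2L, 1L),
              S3 = c(2L, 0L, 1L), S4 = c(1L, 1L, 1L))
  gm <- make_gm(gt)
  dm <- distance_matrix(gm)
  expect_equal(dm$d["S1", "S2"], 0)         # identical vectors
  expect_equal(dm$d["S1", "S3"], 2 / 3)     # two opposite homs + one match
  expect_equal(dm$d, t(dm$d))
  expect_equal(diag(dm$d), stats::setNames(rep(0, 4), colnames(gt)))

  one <- make_gm(cbind(S1 = 0L, S2 = 2L))
  expect_equal(distance_matrix(one)$d["S1", "S2"], 1)
  het <- make_gm(cbind(S1 = 1L, S2 = 0L))
  expect_equal(distance_matrix(het)$d["S1", "S2"], 0.5)

  # random matrices vs a per-site tally oracle; site order irrelevant
  set.seed(41)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), 100 * 3, replace = TRUE),
               100, 3, dimnames = list(NULL, c("S1", "S2", "S3")))
  gm2 <- make_gm(gt)
  dm2 <- distance_matrix(gm2)
  shuf <- make_gm(gt[sample.int(100), , drop = FALSE])
  expect_equal(distance_matrix(shuf)$d, dm2$d)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    shared <- 0; nn <- 0
    for (i in 1:100) {
      a <- gt[i, pr[1]]; b <- gt[i, pr[2]]
      if (is.na(a) || is.na(b)) next
      nn <- nn + 1
      shared <- shared + 2 - abs(a - b)
    }
    expect_equal(dm2$d[pr[1], pr[2]], unname(1 - shared / (2 * nn)))
  }

  # zero shared sites is an error
  gt0 <- cbind(S1 = c(0L, NA), S2 = c(NA, 0L))
  expect_error(distance_matrix(make_gm(gt0)), "share no genotyped sites")
})

test_that("neighbor joining is exact on additive matrices", {
  # matrix generated by ((A:1,B:2):1,(C:3,D:4))
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- nj_tree(dm)
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(dm),
                                                      rownames(dm)],
               dm)
  # topology: A,B form a cherry
  ab <- ape::getMRCA(ape::root(tree, "D"), c("A", "B"))
  expect_equal(length(ape::extract.clade(ape::root(tree, "D"),
                                         ab)$tip.label), 2L)

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  t3 <- nj_tree(d3)
  len <- stats::setNames(t3$edge.length,
                         t3$tip.label[t3$edge[, 2]])
  expect_equal(len[c("X", "Y", "Z")],
               c(X = 0, Y = 2, Z = 3))

  # random additive matrices from random trees: exact reconstruction and
  # agreement with the reference NJ implementation
  set.seed(43)
  for (k in 1:5) {
    ref <- ape::rtree(8)
    ref$edge.length <- stats::runif(nrow(ref$edge), 0.5, 3)
    dmat <- as.matrix(ape::cophenetic.phylo(ref))
    ours <- nj_tree(dmat)
    expect_equal(as.matrix(ape::cophenetic.phylo(ours))[rownames(dmat),
                                                        colnames(dmat)],
                 dmat, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(ref), ours), 0,
                 ignore_attr = TRUE)
    theirs <- ape::nj(dmat)
    expect_equal(ape::dist.topo(theirs, ours), 0, ignore_attr = TRUE)
  }

  # equidistant matrix: deterministic lowest-index tie-break
  deq <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(deq) <- 0
  t_eq1 <- nj_tree(deq)
  t_eq2 <- nj_tree(deq)
  expect_equal(ape::write.tree(t_eq1), ape::write.tree(t_eq2))
  expect_true(grepl("^\\(C:", ape::write.tree(t_eq1)))  # A,B joined first

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- matrix(c(0, 1, 2, 1, 0, 3, 9, 3, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})
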