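test_that("weighted UniFrac reproduces closed-form cases", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  a <- c(A = 10, B = 0)
  b <- c(A = 0, B = 5)
  expect_equal(weighted_unifrac(a, a, tree), 0)
  expect_equal(weighted_unifrac(a, b, tree, normalized = FALSE), 2)
  expect_equal(weighted_unifrac(a, b, tree, normalized = TRUE), 1)
  expect_error(weighted_unifrac(c(A = 1, C = 1), b, tree), "C")
  expect_error(weighted_unifrac(c(A = 0, B = 0), b, tree), "zero-total")
})

test_that("weighted UniFrac equals the branch-enumeration oracle", {
  set.seed(101)
  for (i in 1:120) {
    tree <- random_tip_tree(10)
    a <- setNames(rgamma(10, 0.8), tree$tip.label)
    b <- setNames(rgamma(10, 0.8), tree$tip.label)
    expect_lt(abs(weighted_unifrac(a, b, tree, normalized = FALSE) -
                  unifrac_oracle(a, b, tree, normalized = FALSE)), 1e-12)
    expect_lt(abs(weighted_unifrac(a, b, tree, normalized = TRUE) -
                  unifrac_oracle(a, b, tree, normalized = TRUE)), 1e-12)
  }
})

test_that("weighted UniFrac behaves as a metric on random instances", {
  set.seed(202)
  for (i in 1:40) {
    tree <- random_tip_tree(10)
    x <- setNames(rgamma(10, 0.8), tree$tip.label)
    y <- setNames(rgamma(10, 0.8), tree$tip.label)
    z <- setNames(rgamma(10, 0.8), tree$tip.label)
    dxy <- weighted_unifrac(x, y, tree, normalized = FALSE)
    dyx <- weighted_unifrac(y, x, tree, normalized = FALSE)
    dxz <- weighted_unifrac(x, z, tree, normalized = FALSE)
    dzy <- weighted_unifrac(z, y, tree, normalized = FALSE)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_lte(dxy, dxz + dzy + 1e-12)
    expect_lt(weighted_unifrac(x, x * 3, tree), 1e-12)  # same composition
    n <- weighted_unifrac(x, y, tree, normalized = TRUE)
    expect_gte(n, 0)
    expect_lte(n, 1)
  }
})

test_that("weighted UniFrac agrees with phyloseq on a shared instance", {
  skip_if_not_installed("phyloseq")
  set.seed(5)
  tree <- random_tip_tree(20)
  counts <- matrix(rpois(5 * 20, 40), 5,
                   dimnames = list(paste0("S", 1:5), tree$tip.label))
  tab <- otu_table(counts)
  d <- distance_matrix(tab, tree, metric = "wunifrac", normalized = TRUE)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = FALSE), tree)
  dps <- phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)
  expect_equal(as.matrix(d), as.matrix(dps)[rownames(counts), rownames(counts)],
               tolerance = 1e-10)
})

test_that("Jensen-Shannon divergence matches closed forms and hand values", {
  expect_equal(jensen_shannon(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jensen_shannon(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  # frozen from an independent evaluation of JSD((.5,.5),(.9,.1)), natural log
  expect_equal(jensen_shannon(c(0.5, 0.5), c(0.9, 0.1)), 0.10174922507919676,
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:30) {
    p <- random_composition(12, sparse = TRUE)
    q <- random_composition(12, sparse = TRUE)
    r <- random_composition(12, sparse = TRUE)
    j <- jensen_shannon(p, q)
    expect_gte(j, 0)
    expect_lte(j, log(2) + 1e-12)
    expect_equal(j, jensen_shannon(q, p), tolerance = 1e-12)
    # sqrt(JSD) triangle inequality
    expect_lte(sqrt(j),
               sqrt(jensen_shannon(p, r)) + sqrt(jensen_shannon(r, q)) + 1e-12)
  }
})

test_that("distance_matrix agrees with the pairwise kernels", {
  set.seed(33)
  tree <- random_tip_tree(12)
  counts <- matrix(rpois(20 * 12, 15), 20,
                   dimnames = list(paste0("S", 1:20), tree$tip.label))
  counts[3, ] <- counts[1, ]                    # duplicated composition
  tab <- otu_table(counts)
  for (metric in c("wunifrac", "jsd")) {
    d <- distance_matrix(tab, tree, metric = metric)
    m <- as.matrix(d)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_true(all(diag(m) == 0))
    expect_lt(m["S1", "S3"], 1e-12)
    pick <- rbind(c(1, 2), c(4, 17), c(9, 20), c(5, 13))
    for (r in seq_len(nrow(pick))) {
      i <- pick[r, 1]; j <- pick[r, 2]
      ref <- if (metric == "wunifrac")
        weighted_unifrac(counts[i, ], counts[j, ], tree)
      else jensen_shannon(counts[i, ], counts[j, ])
      expect_equal(m[i, j], ref, tolerance = 1e-10)
    }
  }
  one <- distance_matrix(tab[1, ], tree, metric = "wunifrac")
  expect_identical(dim(as.matrix(one)), c(1L, 1L))
  expect_error(distance_matrix(tab, NULL, metric = "wunifrac"), "tree")
})
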