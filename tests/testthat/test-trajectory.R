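test_that("transition counts tally label movements", {
  asg <- make_assignments(c("I", "I", "II"), c("II", "II", "II"),
                          c("II", "II", "II"))
  m <- transition_counts(asg, "W1", "M1")
  expect_identical(m["I", "II"], 2L)
  expect_identical(m["II", "II"], 1L)
  expect_identical(sum(m), 3L)

  stay <- make_assignments(rep("I", 4), rep("I", 4), rep("I", 4))
  ms <- transition_counts(stay, "W1", "M1", levels = c("I", "II"))
  expect_identical(unname(diag(ms)), c(4L, 0L))
  expect_identical(sum(ms) - sum(diag(ms)), 0L)

  # empirical transition rows approach the generator's Markov rows
  coh <- small_cohort(n_subjects = 400, seed = 10)
  path <- coh$truth$path
  asg2 <- data.frame(subject_id = rep(rownames(path), 3),
                     timepoint = rep(colnames(path), each = nrow(path)),
                     label = as.vector(path))
  m2 <- transition_counts(asg2, "W1", "M1", levels = c("I", "II", "III", "IV", "V"))
  T1 <- coh$truth$config$transitions$W1_M1
  emp <- m2 / rowSums(m2)
  for (k in 1:5) {
    nk <- rowSums(m2)[k]
    se <- sqrt(T1[k, ] * (1 - T1[k, ]) / nk)
    expect_true(all(abs(emp[k, ] - T1[k, ]) < 4 * se + 1e-9))
  }
})

test_that("dependence test matches hand chi-squared and extremes", {
  tab <- matrix(c(10, 0, 0, 10), 2)
  res <- dependence_test(tab, correct = FALSE)
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  # Yates correction is the 2x2 default
  expect_lt(dependence_test(tab)$statistic, 20)

  block <- rbind(c(40, 0, 0), c(0, 40, 0), c(0, 0, 40))
  expect_lt(dependence_test(block)$p_value, 1e-6)

  withzero <- rbind(c(10, 5, 0), c(7, 8, 0), c(0, 0, 0))
  expect_warning(res0 <- dependence_test(withzero), "zero-margin")
  expect_identical(dim(res0$expected), c(2L, 2L))
})

test_that("agreement comparison contrasts the two time spans", {
  allstable <- make_assignments(rep("I", 30), rep("I", 30), rep("I", 30))
  res <- agreement_comparison(allstable)
  expect_equal(unname(res$agreement), c(1, 1))
  expect_equal(res$p_value, 1)

  # stickier M1->M3 than W1->M1 is detected
  set.seed(19)
  n <- 430
  w1 <- sample(c("I", "II"), n, replace = TRUE)
  m1 <- ifelse(runif(n) < 0.28, w1, sample(c("I", "II"), n, replace = TRUE))
  m3 <- ifelse(runif(n) < 0.55, m1, sample(c("I", "II"), n, replace = TRUE))
  res2 <- agreement_comparison(make_assignments(w1, m1, m3))
  expect_gt(res2$agreement[["M1_M3"]], res2$agreement[["W1_M1"]])
  expect_lt(res2$p_value, 0.05)
})

test_that("stability test uses the product-of-marginals null", {
  # balanced labels at every visit: expected stable = 5 * (1/5)^3 = 0.04
  lab <- rep(c("I", "II", "III", "IV", "V"), 20)
  asg <- make_assignments(lab, sample(lab), sample(lab))
  res <- stability_test(asg)
  expect_equal(res$expected, 5 * (1 / 5)^3, tolerance = 1e-12)
  expect_identical(res$n, 100L)
  expect_equal(sum(res$per_pneumotype$expected), res$expected, tolerance = 1e-12)

  # identity transitions: everyone stable, p ~ 0
  ident <- make_assignments(lab, lab, lab)
  res2 <- stability_test(ident)
  expect_equal(res2$observed, 1)
  expect_lt(res2$p_value, 1e-10)

  coh <- small_cohort(n_subjects = 150, seed = 2,
                      transitions = list(W1_M1 = diag(5), M1_M3 = diag(5)))
  path <- coh$truth$path
  asg3 <- data.frame(subject_id = rep(rownames(path), 3),
                     timepoint = rep(colnames(path), each = nrow(path)),
                     label = as.vector(path))
  expect_equal(stability_test(asg3)$observed, 1)
})

test_that("distance ratios compare own to cross-subject distances", {
  # constant distances: every ratio 1
  n <- 12
  ids <- paste0("P", 1:n)
  md <- data.frame(sample_id = c(paste0(ids, "_a"), paste0(ids, "_b")),
                   subject_id = rep(ids, 2),
                   timepoint = rep(c("W1", "M1"), each = n))
  m <- matrix(1, 2 * n, 2 * n,
              dimnames = list(md$sample_id, md$sample_id))
  diag(m) <- 0
  res <- distance_ratio(as.dist(m), md, "W1", "M1")
  expect_equal(res$median_ratio, 1)
  expect_equal(unname(res$ratios), rep(1, n))

  # one subject's own distance halved
  m2 <- m
  m2["P1_a", "P1_b"] <- m2["P1_b", "P1_a"] <- 0.5
  res2 <- distance_ratio(as.dist(m2), md, "W1", "M1")
  expect_equal(unname(res2$ratios["P1"]), 0.5)

  # invariant to global rescaling of the distance matrix
  res3 <- distance_ratio(as.dist(m2 * 13), md, "W1", "M1")
  expect_equal(res3$ratios, res2$ratios, tolerance = 1e-12)
})

test_that("leave-one-out medians match brute force", {
  set.seed(44)
  for (n in c(11, 12)) {
    X <- matrix(runif(3 * n), 3)
    L <- pneumotyper:::row_loo_medians(X)
    for (i in 1:3) for (j in seq_len(n))
      expect_equal(L[i, j], median(X[i, -j]), tolerance = 1e-12)
  }
})

test_that("ratio permutation test attains its floor and detects persistence", {
  set.seed(61)
  n <- 30
  ids <- paste0("P", 1:n)
  md <- data.frame(sample_id = c(paste0(ids, "_a"), paste0(ids, "_b")),
                   subject_id = rep(ids, 2),
                   timepoint = rep(c("W1", "M1"), each = n))
  # subject-specific signatures persisting across time
  base <- matrix(rnorm(n * 6), n)
  pts <- rbind(base + rnorm(n * 6, 0, 0.1), base + rnorm(n * 6, 0, 0.1))
  rownames(pts) <- md$sample_id
  d <- dist(pts)
  res <- ratio_permutation_test(d, md, "W1", "M1", n_perm = 999, seed = 5)
  expect_lt(res$median_ratio, 1)
  expect_equal(res$p_value, 1 / 1000)         # maximal signal -> floor
  expect_error(ratio_permutation_test(d, md, "W1", "M1", n_perm = 50), "100")

  # two-sided p doubles the smaller tail
  res2 <- ratio_permutation_test(d, md, "W1", "M1", n_perm = 999, seed = 5,
                                 tail = "two")
  expect_equal(res2$p_value, 2 / 1000)
})
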