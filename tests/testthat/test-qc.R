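test_that("depth filter keeps samples at or above the threshold", {
  m <- rbind(S1 = c(1000L, 999L), S2 = c(1000L, 1000L), S3 = c(50000L, 2749L))
  colnames(m) <- c("OTU1", "OTU2")
  res <- filter_min_depth(otu_table(m), 2000)
  expect_identical(sample_ids(res$table), c("S2", "S3"))   # 2000 exactly is kept
  expect_identical(res$excluded$sample_id, "S1")
  expect_identical(res$excluded$depth, 1999)

  all_deep <- filter_min_depth(otu_table(m), 10)
  expect_identical(sample_ids(all_deep$table), rownames(m))
  expect_identical(nrow(all_deep$excluded), 0L)
})

test_that("depth filter exclusion rate matches the generator's depth model", {
  coh <- small_cohort(n_subjects = 300, seed = 2)
  res <- filter_min_depth(coh$table, 2000)
  frac <- nrow(res$excluded) / n_samples(coh$table)
  # P(depth < 2000) under lognormal(9.25, 1) is pnorm((log(2000)-9.25)/1)
  expected <- pnorm((log(2000) - 9.25) / 1)
  se <- sqrt(expected * (1 - expected) / n_samples(coh$table))
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("diversity-outlier exclusion removes only the high tail, one pass", {
  # identical compositions: sd = 0, nothing removed
  m <- matrix(rep(c(10L, 5L, 1L), 4), 4, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), paste0("OTU", 1:3)))
  res <- exclude_diversity_outliers(otu_table(m), z = 5)
  expect_identical(nrow(res$excluded), 0L)
  expect_identical(n_samples(res$table), 4L)

  # planted high-diversity sample among tight moderate-diversity ones
  set.seed(42)
  n_otus <- 40
  p0 <- c(0.7, rep(0.3 / (n_otus - 1), n_otus - 1))
  base <- t(vapply(1:100, function(i)
    as.integer(rmultinom(1, 5000, p0)), integer(n_otus)))
  planted <- as.integer(rmultinom(1, 5000, rep(1 / n_otus, n_otus)))
  m <- rbind(base, planted)
  dimnames(m) <- list(paste0("S", seq_len(nrow(m))), paste0("OTU", seq_len(n_otus)))
  sdi <- apply(m, 1, shannon)
  stopifnot(sdi[101] > mean(sdi[1:100]) + 5 * sd(sdi[1:100]))  # scenario sanity
  res <- exclude_diversity_outliers(otu_table(m), z = 5)
  expect_identical(res$excluded$sample_id, "S101")

  # infinite z never removes
  res_inf <- exclude_diversity_outliers(otu_table(m), z = Inf)
  expect_identical(nrow(res_inf$excluded), 0L)
})

test_that("rarefaction conserves depth, is seeded, and is hypergeometric", {
  m <- rbind(S1 = c(5000L, 0L), S2 = c(9000L, 1000L))
  colnames(m) <- c("A", "B")
  tab <- otu_table(m)
  r <- rarefy_table(tab, 2000, seed = 7)
  expect_identical(unname(r$counts["S1", ]), c(2000L, 0L))   # forced outcome
  expect_true(all(rowSums(r$counts) == 2000L))
  expect_identical(rarefy_table(tab, 2000, seed = 7)$counts, r$counts)
  expect_false(identical(rarefy_table(tab, 2000, seed = 8)$counts, r$counts))

  shallow <- otu_table(matrix(c(100L, 5L), 1,
                              dimnames = list("S1", c("A", "B"))))
  expect_error(rarefy_table(shallow, 2000), "S1")

  # mean rarefied count of the minor OTU matches the hypergeometric mean 200
  bs <- vapply(1:300, function(s) rarefy_table(tab, 2000, seed = s)$counts["S2", "B"],
               integer(1))
  hyper_sd <- sqrt(2000 * 0.1 * 0.9 * (10000 - 2000) / (10000 - 1))
  expect_lt(abs(mean(bs) - 200), 4 * hyper_sd / sqrt(300))
})

test_that("rank aggregation is additive, conservative, and pools unclassified", {
  m <- rbind(S1 = c(3L, 4L, 2L), S2 = c(1L, 0L, 5L))
  colnames(m) <- paste0("OTU", 1:3)
  tax <- parse_lineage(c(OTU1 = "Bacteria;Firmicutes;;;;Streptococcus",
                         OTU2 = "Bacteria;Firmicutes;;;;Streptococcus",
                         OTU3 = "Bacteria"))
  tab <- otu_table(m, taxonomy = tax)
  agg <- aggregate_rank(tab, "genus")
  expect_identical(unname(agg$counts[, "Streptococcus"]), c(7L, 1L))
  expect_identical(unname(agg$counts[, "unclassified"]), c(2L, 5L))
  expect_identical(rowSums(agg$counts), rowSums(tab$counts))
})

test_that("generator genus trajectories match the configured succession", {
  # expected values are exact by construction of the default profiles
  cfg <- default_config()
  for (t in c("W1", "M1", "M3")) {
    mix <- drop(cfg$marginals[t, ] %*% cfg$profiles[[t]])
    expect_equal(unname(mix[c("Staphylococcus", "Streptococcus", "Moraxella")]),
                 unname(cfg$genus_targets[t, c("Staphylococcus", "Streptococcus",
                                               "Moraxella")]),
                 tolerance = 1e-12)
  }
  # and the realised cohort means track them within 2 percentage points
  coh <- small_cohort(n_subjects = 1000, seed = 5)
  rare <- rarefied_cohort(coh)
  gen <- aggregate_rank(rare, "genus")
  R <- rel_abund(gen)
  md <- coh$metadata[match(sample_ids(gen), coh$metadata$sample_id), ]
  for (t in c("W1", "M1", "M3")) {
    obs <- colMeans(R[md$timepoint == t,
                      c("Staphylococcus", "Streptococcus", "Moraxella")])
    expect_lt(max(abs(obs - cfg$genus_targets[t, names(obs)])), 0.02)
  }
})

test_that("DNA concentration bins follow the published cut-points", {
  expect_identical(as.character(categorize_dna_concentration(0.05)), "extremely_low")
  expect_identical(as.character(categorize_dna_concentration(4.58)), "very_high")
  expect_identical(as.character(categorize_dna_concentration(0.33)), "low")
  expect_identical(as.character(categorize_dna_concentration(
    c(0, 0.1, 0.32, 0.8, 1.78, 1.79, 10))),
    c("extremely_low", "very_low", "very_low", "medium", "medium", "high",
      "very_high"))
  expect_error(categorize_dna_concentration(-0.1), "negative")
})

test_that("cohort summaries print counts with table-style percentages", {
  expect_identical(percent_label(356, 695, 0), "356 (51%)")
  expect_identical(percent_label(126, 165, 1), "126 (76.4%)")
  expect_identical(percent_label(0, 53, 1), "0 (0.0%)")
  # half-away-from-zero rounding, not banker's
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(76.45, 1), 76.5)

  md <- data.frame(sample_id = paste0("x", 1:6),
                   subject_id = rep(c("s1", "s2"), each = 3),
                   timepoint = rep(c("W1", "M1", "M3"), 2),
                   sex = rep(c("male", "female"), each = 3),
                   siblings = rep(c(TRUE, FALSE), each = 3),
                   antibiotics = c(FALSE, FALSE, TRUE, FALSE, TRUE, NA))
  sm <- cohort_summary(md, digits = 1)
  sib <- sm[sm$field == "siblings", ]
  expect_identical(sib$label, "1 (50.0%)")
  ab_m3 <- sm[sm$field == "antibiotics" & sm$timepoint == "M3", ]
  expect_identical(ab_m3$denom, 1L)    # NA excluded from the denominator
  # explicit denominator override for fields with known missingness
  sm2 <- cohort_summary(md, digits = 1, denominators = c(siblings = 4))
  expect_identical(sm2[sm2$field == "siblings", "label"], "1 (25.0%)")
})
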