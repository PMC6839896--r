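make_cohort <- function(majors, status = NULL, tissues = NULL,
                        individual = NULL, line = NULL) {
  # majors: site x sample matrix of predominant alleles
  k <- ncol(majors)
  n <- nrow(majors)
  samples <- paste0("s", seq_len(k))
  calls <- do.call(rbind, lapply(seq_len(k), function(j) {
    data.frame(sample = samples[j], pos = seq_len(n), ref = "A",
               major = majors[, j],
               minor = NA_character_, minor_count = 0L, maf = 0,
               depth_used = 1000L,
               status = if (is.null(status)) "homoplasmic" else status[, j],
               stringsAsFactors = FALSE)
  }))
  meta <- data.frame(sample = samples,
                     individual = if (is.null(individual)) samples else individual,
                     tissue = if (is.null(tissues)) "blood" else tissues,
                     maternal_line = if (is.null(line)) "L1" else line,
                     generation = "F1")
  cohort_matrix(calls, meta)
}

test_that("polymorphic sites need two predominant alleles among detectable samples", {
  majors <- cbind(c("A", "A", "A"), c("A", "G", "A"), c("A", "G", "A"))
  cm <- make_cohort(majors)
  pc <- classify_polymorphic(cm)
  expect_equal(pc$is_polymorphic, c(FALSE, TRUE, FALSE))

  # an undetectable dissenting cell does not make a site polymorphic
  status <- matrix("homoplasmic", 3, 3)
  status[2, 2:3] <- "undetectable"
  cm <- make_cohort(majors, status = status)
  pc <- classify_polymorphic(cm)
  expect_equal(pc$is_polymorphic, c(FALSE, FALSE, FALSE))
  expect_equal(pc$n_samples_detectable, c(3L, 1L, 3L))

  # invariant to sample order
  cm2 <- make_cohort(majors[, c(3, 1, 2)])
  expect_equal(classify_polymorphic(cm2)$is_polymorphic,
               classify_polymorphic(make_cohort(majors))$is_polymorphic)
  expect_error(classify_polymorphic(make_cohort(majors[, 1, drop = FALSE])),
               ">= 2 samples")
})

test_that("tissue specificity counts tissues per heteroplasmic site", {
  # 10 tissues of one individual; site 1 het in one tissue, site 2 in seven
  status <- matrix("homoplasmic", 3, 10)
  status[1, 4] <- "heteroplasmic"
  status[2, 1:7] <- "heteroplasmic"
  majors <- matrix("A", 3, 10)
  cm <- make_cohort(majors, status = status, tissues = paste0("t", 1:10),
                    individual = rep("ind1", 10))
  ts <- tissue_specificity(cm, "ind1")
  expect_equal(ts$site_counts$n_tissues_het, c(1L, 7L, 0L))
  expect_equal(ts$tss_sites, 1L)
  expect_equal(unname(ts$tss_per_tissue["t4"]), 1L)
  expect_equal(as.integer(ts$histogram[c("1", "7")]), c(1L, 1L))
  expect_error(tissue_specificity(cm, "nope"), "< 2 tissues")
})

test_that("maternal concordance is symmetric with unit diagonal and line structure", {
  # two lines differing at 42 of 56 polymorphic sites
  n <- 56
  majors <- cbind(l1a = rep("A", n), l1b = rep("A", n),
                  l2 = c(rep("G", 42), rep("A", 14)))
  cm <- make_cohort(majors, line = c("L1", "L1", "L2"))
  mc <- maternal_concordance(cm)
  expect_equal(diag(mc$concordance), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(mc$concordance, t(mc$concordance))
  expect_equal(mc$concordance["s1", "s2"], 1)
  expect_equal(mc$concordance["s1", "s3"], 14 / 56)
  expect_equal(mc$n_compared["s1", "s3"], 56L)

  # undetectable cells drop out of the comparison
  status <- matrix("homoplasmic", n, 3); status[1:6, 3] <- "undetectable"
  cm <- make_cohort(majors, status = status, line = c("L1", "L1", "L2"))
  mc <- maternal_concordance(cm)
  expect_equal(mc$n_compared["s1", "s3"], 50L)
  expect_error(maternal_concordance(cm, sites = 999), "absent")
})

test_that("genotype frequencies pool strata to the printed survey values", {
  geno <- read.delim(mitohet_example("rflp_genotype_counts.tsv"))
  gf <- genotype_frequencies(geno)
  pooled <- gf$pooled
  pick <- function(site, g) pooled$frequency[pooled$site == site & pooled$genotype == g]
  expect_equal(pick("mt.G8682A", "GA"), 0.02)
  expect_equal(pick("mt.G8682A", "GG"), 0.98)
  expect_equal(pick("mt.G16121A", "AA"), 0.66)
  expect_equal(pick("mt.G16121A", "GG"), 0.30)
  # per-stratum frequencies sum to 1 within each site
  per <- gf$per_stratum
  sums <- aggregate(frequency ~ site + stratum, per, sum)
  expect_true(all(abs(sums$frequency - 1) < 1e-12))
  # single-genotype stratum has frequency 1
  one <- genotype_frequencies(data.frame(site = "x", genotype = "AA",
                                         stratum = "b", count = 7))
  expect_equal(one$pooled$frequency, 1)
  expect_error(genotype_frequencies(data.frame(site = "x", genotype = "AA",
                                               stratum = "b", count = 0)),
               "zero total")
})

test_that("transmission summaries reproduce the pedigree margins", {
  ped <- read.delim(mitohet_example("pedigree_allele_ratios_synthetic.tsv"))
  ts <- transmission_summary(ped, "mt.T5718G")
  occ <- ts$occurrence
  expect_equal(occ$heteroplasmic[occ$generation == "F0"], 17L)
  expect_equal(occ$n[occ$generation == "F0"], 26L)
  # 52 of 53 offspring of heteroplasmic mothers reverted to homoplasmy
  expect_equal(nrow(ts$offspring_outcomes), 53L)
  expect_equal(sum(ts$offspring_outcomes$offspring_homoplasmic), 52L)
  ts2 <- transmission_summary(ped, "mt.A5694T")
  expect_equal(sum(ts2$offspring_outcomes$offspring_homoplasmic), 48L)

  # a 3.75%-minor mother with an offspring at ratio 100 -> homoplasmic child
  out <- ts$offspring_outcomes
  m1 <- out[out$mother_ratio == 3.75, ]
  expect_true(all(m1$offspring_homoplasmic))
  # all ratios exactly 100 -> zero occurrence
  flat <- data.frame(individual = c("a", "b"), mother = NA, generation = "F0",
                     site = "s", allele_ratio_percent = 100)
  expect_equal(transmission_summary(flat, "s")$occurrence$heteroplasmic, 0L)
  expect_error(transmission_summary(ped, "missing_site"), "no pedigree")
})

test_that("fisher_exact_2x2 matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  # brute-force enumeration over all tables with the observed margins
  set.seed(13)
  for (k in 1:40) {
    t <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    p <- fisher_exact_2x2(t)
    expect_equal(p, oracle_fisher_2x2(t), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(t)$p.value, tolerance = 1e-7)
  }
  # the printed survey comparisons
  expect_equal(fisher_exact_2x2(matrix(c(54, 149, 2, 29), 2)),
               stats::fisher.test(matrix(c(54, 149, 2, 29), 2))$p.value,
               tolerance = 1e-10)
  expect_lt(fisher_exact_2x2(matrix(c(24, 4, 26, 99), 2)), 0.001)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 1), 2)), "degenerate")
})

test_that("chi_square_2x2 computes the Pearson statistic", {
  # perfectly proportional table: statistic 0, p 1
  res <- chi_square_2x2(matrix(c(10, 20, 30, 60), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # closed form: diagonal table [[10,0],[0,10]] gives N = 20
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  # agreement with stats::chisq.test without correction
  t <- matrix(c(130, 15, 48, 41), 2)
  ref <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  res <- chi_square_2x2(t)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
  expect_lt(res$p_value, 0.001)
  expect_error(chi_square_2x2(matrix(c(0, 0, 1, 1), 2)), "zero expected")
})
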