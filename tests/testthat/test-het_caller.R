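test_that("allele frequencies and status follow the MAF thresholds", {
  # 20 alt reads over 10000 -> MAF 0.2%, potential tier
  bc <- make_bc(ref = "A", A = c(4990, 4990), G = c(10, 10))
  call <- call_site(bc)
  expect_equal(call$aaf_G, 0.2)
  expect_equal(call$maf, 0.2)
  expect_equal(call$status, "potential")

  # boundary: MAF exactly 0.5% is heteroplasmic ("at least")
  bc <- make_bc(ref = "A", A = c(4975, 4975), G = c(25, 25))
  expect_equal(call_site(bc)$maf, 0.5)
  expect_equal(call_site(bc)$status, "heteroplasmic")

  # zero depth -> undetectable with MAF 0
  call <- call_site(make_bc(ref = "A"))
  expect_equal(call$status, "undetectable")
  expect_equal(call$maf, 0)

  # 50/50 tie breaks toward the reference base
  call <- call_site(make_bc(ref = "G", A = c(2500, 2500), G = c(2500, 2500)))
  expect_equal(call$major, "G")
  expect_equal(call$minor, "A")
  expect_equal(call$maf, 50)

  # frequencies sum to 100 whenever depth > 0
  set.seed(3)
  for (k in 1:20) {
    bc <- make_bc(ref = "C", A = sample(0:99, 2), C = sample(0:99, 2),
                  G = sample(0:99, 2), T = sample(0:99, 2))
    if (bc$depth_used == 0) next
    call <- call_site(bc)
    expect_equal(call$aaf_A + call$aaf_C + call$aaf_G + call$aaf_T, 100)
    expect_lte(call$maf, 50)
  }
})

test_that("frequencies are invariant under strand swap", {
  set.seed(5)
  for (k in 1:20) {
    a <- sample(0:200, 2); c2 <- sample(0:200, 2)
    g <- sample(0:200, 2); t <- sample(0:200, 2)
    x <- call_site(make_bc(ref = "A", A = a, C = c2, G = g, T = t))
    y <- call_site(make_bc(ref = "A", A = rev(a), C = rev(c2),
                           G = rev(g), T = rev(t)))
    expect_equal(x$maf, y$maf)
    expect_equal(x$major, y$major)
    expect_equal(x$status, y$status)
  }
})

test_that("minor-count and strand-bias guards demote calls, and can be disabled", {
  # one minor read at MAF 0.6%: above threshold but below min_minor_count
  bc <- make_bc(ref = "A", A = c(83, 83), G = c(1, 0))
  expect_equal(call_site(bc)$status, "potential")
  expect_equal(call_site(bc, caller_config(min_minor_count = 0))$status,
               "heteroplasmic")
  # all minor reads on one strand fail a strand-bias cap
  bc <- make_bc(ref = "A", A = c(490, 490), G = c(20, 0))
  expect_equal(call_site(bc, caller_config(strand_bias_max = 5))$status,
               "potential")
  expect_equal(call_site(bc)$status, "heteroplasmic")
  expect_error(caller_config(het_threshold = 0.05, potential_floor = 0.1),
               "potential_floor")
})

test_that("call_sample preserves order and rejects duplicates", {
  counts <- rbind(
    make_bc(pos = 1, ref = "A", A = c(5000, 4995), G = c(2, 3)),    # 0.05% hom
    make_bc(pos = 2, ref = "A", A = c(4992, 4993), G = c(7, 8)),    # 0.15% pot
    make_bc(pos = 3, ref = "A", A = c(4900, 4900), G = c(100, 100)),# 2% het
    make_bc(pos = 4, ref = "A"))                                    # depth 0
  calls <- call_sample(counts)
  expect_equal(calls$status,
               c("homoplasmic", "potential", "heteroplasmic", "undetectable"))
  expect_equal(calls$pos, 1:4)
  expect_equal(nrow(call_sample(counts[0, ])), 0L)
  expect_error(call_sample(rbind(counts, counts[1, ])), "duplicate")
  sm <- summarize_sample(calls)
  expect_equal(unname(sm["UN"]), 1L)
  expect_equal(unname(sm["MAF>=0.5%"]), 1L)
})

test_that("tier counts are monotone and recover generator truth", {
  # truth: 10 sites at 12%, 10 sites at 2%, 20 sites at 0.7%
  set.seed(9)
  fracs <- c(rep(0.12, 10), rep(0.02, 10), rep(0.007, 20))
  counts <- do.call(rbind, lapply(seq_along(fracs), function(i)
    simulate_counts_at_site(fracs[i], coverage = 20000, e = 0, ref = "A",
                            alt = "G", pos = i)))
  sm <- summarize_sample(call_sample(counts))
  expect_equal(unname(sm["MAF>=10%"]), 10L)
  expect_equal(unname(sm["MAF>=1%"]), 20L)
  expect_equal(unname(sm["MAF>=0.5%"]), 40L)
  # monotone for arbitrary random input
  set.seed(10)
  rnd <- do.call(rbind, lapply(1:60, function(i)
    make_bc(pos = i, ref = "A", A = sample(0:50, 2), C = sample(0:50, 2),
            G = sample(0:50, 2), T = sample(0:50, 2))))
  sm <- summarize_sample(call_sample(rnd))
  expect_true(sm["MAF>=10%"] <= sm["MAF>=5%"])
  expect_true(sm["MAF>=5%"] <= sm["MAF>=1%"])
  expect_true(sm["MAF>=1%"] <= sm["MAF>=0.5%"])
  # all-reference sample: every tier zero
  allref <- do.call(rbind, lapply(1:5, function(i)
    make_bc(pos = i, ref = "A", A = c(50, 50))))
  expect_true(all(summarize_sample(call_sample(allref))[1:5] == 0))
})

test_that("called MAF converges to the simulated fraction at high coverage", {
  set.seed(77)
  f <- 0.02
  reps <- vapply(1:200, function(k) {
    bc <- simulate_counts_at_site(f, coverage = 1e5, e = 0, ref = "A", alt = "G")
    call_site(bc)$maf
  }, numeric(1))
  # binomial se of the mean over 200 replicates at coverage 1e5
  se <- 100 * sqrt(f * (1 - f) / 1e5) / sqrt(200)
  expect_lt(abs(mean(reps) - 100 * f), 4 * se)
})

test_that("VCF and TSV writers emit heteroplasmic sites", {
  counts <- rbind(
    make_bc(pos = 3, ref = "A", A = c(4900, 4900), G = c(100, 100)),
    make_bc(pos = 5, ref = "C", C = c(500, 500)))
  calls <- call_sample(counts)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, tf)
  lines <- readLines(tf)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  expect_equal(length(body), 1L)
  expect_match(body, "^MT\t3\t\\.\tA\tG\t.*AF=0\\.02")
})
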