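test_that("substitution classifier agrees with the exhaustive 12-pair oracle", {
  purines <- c("A", "G")
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  oracle <- ifelse((pairs$ref %in% purines) == (pairs$alt %in% purines),
                   "transition", "transversion")
  expect_equal(classify_substitution(pairs$ref, pairs$alt), oracle)
  expect_equal(sum(oracle == "transition"), 4L)
  expect_equal(sum(oracle == "transversion"), 8L)
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A/C/G/T")
})

test_that("coding variants are classified S/NS by translating both codons", {
  gen <- toy_genome()
  ann <- toy_annotation(gen)
  # g1 codon 2 is GCT (Ala, positions 34..36); third-base C->T stays Ala
  expect_equal(substr(gen$sequence, 34, 36), "GCT")
  a <- annotate_variant(36, "T", "C", ann)   # GCT -> GCC, both Ala
  expect_equal(a$mutation_type, "S")
  expect_true(is.na(a$aa_change))
  # first-base G->C: Ala -> Pro, non-synonymous with label A2P
  a <- annotate_variant(34, "G", "C", ann)
  expect_equal(a$mutation_type, "NS")
  expect_equal(a$aa_change, "A2P")
  expect_equal(a$name, "mt.G34C")
  # D-loop variant: non-coding, no aa change
  d <- annotate_variant(5, ref_base(5, gen),
                        setdiff(c("A", "C", "G", "T"), ref_base(5, gen))[1], ann)
  expect_equal(d$mutation_type, "NC")
  expect_equal(d$region, "D-loop")
  expect_true(is.na(d$aa_change))
  # reference mismatch guards coordinate bugs
  wrong <- setdiff(c("A", "C", "G", "T"), ref_base(34, gen))[1]
  expect_error(annotate_variant(34, wrong, "T", ann), "mismatch")
})

test_that("minus-strand and stop-codon effects are annotated in coding orientation", {
  gen <- toy_genome()
  ann <- toy_annotation(gen)
  # g2 (81..95, -): genome position 95 is the coding start 'A' of ATG
  # genome base at 95 is complement(A) = T; mutate to C => coding G..  ATG->GTG
  a <- annotate_variant(95, "T", "C", ann)
  expect_equal(a$effects$codon_ref, "ATG")
  expect_equal(a$effects$codon_alt, "GTG")
  # terminal stop of g2 is TAG at coding positions 13..15 (genome 83..81)
  # abolishing the stop is NS with X as the reference symbol
  a <- annotate_variant(83, ref_base(83, gen), "G", ann)
  expect_equal(substr(a$aa_change, 1, 1), "X")
  expect_equal(a$mutation_type, "NS")
})

test_that("S/NS decisions match brute-force translation of whole mutated proteins", {
  skip_if_not_installed("seqinr")
  gen <- toy_genome()
  ann <- toy_annotation(gen)
  g1 <- ann$features[ann$features$name == "g1", ]
  set.seed(21)
  chars <- strsplit(gen$sequence, "")[[1]]
  for (k in 1:40) {
    # codons 2.. only: at codon 1 the annotator reads alternative initiation
    # codons as Met, which plain table translation does not
    pos <- sample(34:57, 1)
    ref <- chars[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- annotate_variant(pos, ref, alt, ann)
    mutated <- chars; mutated[pos] <- alt
    prot_ref <- seqinr::translate(chars[31:60], numcode = 2)
    prot_alt <- seqinr::translate(mutated[31:60], numcode = 2)
    oracle <- if (identical(prot_ref, prot_alt)) "S" else "NS"
    expect_equal(a$mutation_type, oracle, label = paste("pos", pos, ref, alt))
  }
})

test_that("packaged reference reproduces the landmark coding annotations", {
  ref <- synthetic_ref_cache()
  a <- annotate_variant(8682, "G", "A", ref$annotation)
  expect_equal(a$feature, "COX2")
  expect_equal(a$mutation_type, "NS")
  expect_equal(a$substitution, "transition")
  # codon 118 GAC (Asp) -> AAC (Asn); an Asp->His change would need G->C,
  # which no G>A substitution can produce under the mitochondrial code
  expect_equal(a$aa_change, "D118N")
  expect_equal(annotate_variant(5694, "A", "T", ref$annotation)$aa_change, "T152S")
  expect_equal(annotate_variant(5718, "T", "G", ref$annotation)$aa_change, "S160A")
})

test_that("annotation tables conserve marginal counts", {
  sites <- data.frame(
    mutation_type = c("NC", "S", "NS"),
    region = c("D-loop", "CDS", "CDS"),
    feature = c("D-loop", "COX1", "ND5"),
    substitution = c("transition", "transition", "transversion"),
    polymorphic = c(FALSE, TRUE, FALSE))
  tab <- tabulate_annotations(sites)
  grand <- tab[tab$mutation_type == "All", ]
  expect_equal(grand$n, 3)
  expect_equal(grand$transition, 2)
  expect_equal(grand$transversion, 1)
  expect_equal(grand$polymorphic, 1)
  body <- tab[tab$region != "Total", ]
  expect_equal(sum(body$n), 3)
  expect_equal(nrow(tabulate_annotations(sites[0, ])), 0L)

  # random tables conserve counts for every grouping
  set.seed(31)
  n <- 120
  rnd <- data.frame(
    mutation_type = sample(c("NC", "S", "NS"), n, TRUE),
    region = "x", feature = sample(c("g1", "g2", "g3"), n, TRUE),
    substitution = sample(c("transition", "transversion"), n, TRUE))
  rnd$region <- ifelse(rnd$mutation_type == "NC",
                       sample(c("D-loop", "rRNA"), n, TRUE), "CDS")
  tab <- tabulate_annotations(rnd)
  expect_equal(tab$n[tab$mutation_type == "All"], n)
  expect_equal(sum(tab$n[tab$region != "Total"]), n)
  for (tp in c("NC", "S", "NS")) {
    expect_equal(tab$n[tab$mutation_type == tp & tab$region == "Total"],
                 sum(rnd$mutation_type == tp))
  }
})
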