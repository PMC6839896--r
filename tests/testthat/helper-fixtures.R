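# Shared fixtures and independent oracles used across the test files.

# deterministic toy circular genome with a known layout:
#   D-loop 1..20, CDS g1 31..60 (+), CDS g2 81..95 (-), rest intergenic
toy_genome <- function(seed = 7) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  # plus-strand CDS g1: ATG + 8 non-stop codons + TAA
  g1 <- paste0("ATG", "GCTGACGGATTTCACAAACTAGGC", "TAA")
  stopifnot(nchar(g1) == 30)
  chars[31:60] <- strsplit(g1, "")[[1]]
  # minus-strand CDS g2 (15 bp = 5 codons): ATG GCT CAC CTA TAG, one terminal stop
  g2 <- paste0("ATG", "GCTCACCTA", "TAG")
  stopifnot(nchar(g2) == 15)
  rc <- strsplit(as.character(Biostrings::reverseComplement(Biostrings::DNAString(g2))), "")[[1]]
  chars[81:95] <- rc
  circular_genome("toy", 100, paste(chars, collapse = ""))
}

toy_features <- function() {
  data.frame(name = c("D-loop", "g1", "g2"),
             ftype = c("D-loop", "CDS", "CDS"),
             start = c(1, 31, 81), end = c(20, 60, 95),
             strand = c(NA, "+", "-"), codon_start = c(NA, 1, 1),
             stringsAsFactors = FALSE)
}

toy_annotation <- function(genome = toy_genome()) load_annotation(toy_features(), genome)

# one-row base-count record from per-base strand counts
make_bc <- function(pos = 1L, ref = "A",
                    A = c(0, 0), C = c(0, 0), G = c(0, 0), T = c(0, 0),
                    del = 0L, sample = "s1", chrom = "mt") {
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos), ref = ref,
             A_fwd = A[1], A_rev = A[2], C_fwd = C[1], C_rev = C[2],
             G_fwd = G[1], G_rev = G[2], T_fwd = T[1], T_rev = T[2],
             del = del, skipped = 0L, discarded = 0L,
             depth_used = sum(A, C, G, T), stringsAsFactors = FALSE)
}

# --- independent pileup oracle -------------------------------------------
# Counts a read-bases string by explicit token classification, written
# independently of the package parser (regex-free cursor over a char vector
# with a separate state table).
oracle_parse_bases <- function(bases, ref) {
  out <- list(fwd = c(A = 0, C = 0, G = 0, T = 0),
              rev = c(A = 0, C = 0, G = 0, T = 0),
              del = 0, skipped = 0, discarded = 0)
  v <- strsplit(bases, "")[[1]]
  i <- 1
  while (i <= length(v)) {
    c0 <- v[i]
    if (c0 == "^") { i <- i + 2; next }
    if (c0 == "$") { i <- i + 1; next }
    if (c0 %in% c("+", "-")) {
      num <- ""
      j <- i + 1
      while (grepl("[0-9]", v[j])) { num <- paste0(num, v[j]); j <- j + 1 }
      i <- j + as.numeric(num); next
    }
    if (c0 == "*") out$del <- out$del + 1
    else if (c0 %in% c(">", "<")) out$skipped <- out$skipped + 1
    else if (c0 == ".") {
      if (ref %in% names(out$fwd)) out$fwd[ref] <- out$fwd[ref] + 1
      else out$discarded <- out$discarded + 1
    } else if (c0 == ",") {
      if (ref %in% names(out$rev)) out$rev[ref] <- out$rev[ref] + 1
      else out$discarded <- out$discarded + 1
    } else if (c0 %in% c("A", "C", "G", "T")) out$fwd[c0] <- out$fwd[c0] + 1
    else if (c0 %in% c("a", "c", "g", "t")) {
      b <- toupper(c0); out$rev[b] <- out$rev[b] + 1
    } else if (c0 %in% c("N", "n")) out$discarded <- out$discarded + 1
    else stop("oracle: unexpected char ", c0)
    i <- i + 1
  }
  out
}

# random grammar-valid pileup read-bases string; returns the string and its
# declared depth (reads contributing to the depth column: matches, mismatches,
# dels and refskips)
random_pileup_line <- function(ref = sample(c("A", "C", "G", "T"), 1),
                               n_tokens = sample(0:40, 1), pos = 1L) {
  toks <- character(0)
  depth <- 0
  for (k in seq_len(n_tokens)) {
    kind <- sample(c("ref_f", "ref_r", "alt_f", "alt_r", "del", "skip", "N",
                     "start", "end", "ins", "dele"), 1,
                   prob = c(30, 30, 8, 8, 3, 2, 2, 4, 4, 3, 3))
    toks <- c(toks, switch(kind,
      ref_f = ".", ref_r = ",",
      alt_f = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
      alt_r = tolower(sample(setdiff(c("A", "C", "G", "T"), ref), 1)),
      del = "*", skip = sample(c(">", "<"), 1),
      N = sample(c("N", "n"), 1),
      start = paste0("^", rawToChar(as.raw(sample(33:126, 1))), "."),
      end = ".$",
      ins = paste0(".+", l <- sample(1:12, 1),
                   paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                         collapse = "")),
      dele = paste0(".-", l <- sample(1:12, 1),
                    paste(sample(c("a", "c", "g", "t"), l, replace = TRUE),
                          collapse = ""))))
    depth <- depth + 1  # every token carries exactly one read
  }
  bases <- paste(toks, collapse = "")
  quals <- paste(rep("~", depth), collapse = "")
  list(line = paste("mt", pos, ref, depth, bases, quals, sep = "\t"),
       ref = ref, bases = bases, depth = depth)
}

# --- from-scratch hypergeometric enumeration (no dhyper) ------------------
oracle_fisher_2x2 <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1]); N <- sum(t)
  prob <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  ks <- max(0, c1 - r2):min(r1, c1)
  p_obs <- prob(t[1, 1])
  sum(vapply(ks, prob, numeric(1))[vapply(ks, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

synthetic_ref_cache <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- synthetic_reference()
    ref
  }
})
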