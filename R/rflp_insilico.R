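#' Primer pair
#'
#' @param name primer set name.
#' @param forward,reverse primer sequences, 5' to 3', over A/C/G/T,
#'   length >= 10.
#' @param expected_length optional expected product length in bp.
#' @return List of class \code{primer_pair}.
#' @export
primer_pair <- function(name, forward, reverse, expected_length = NULL) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse))
    stop("primer alphabet restricted to A/C/G/T")
  if (nchar(forward) < 10 || nchar(reverse) < 10)
    stop("primers must be at least 10 bases")
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_length = expected_length), class = "primer_pair")
}

#' Restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition pattern (length >= 4),
#'   e.g. \code{"GANTC"}.
#' @param cut_offset bases after the pattern start at which the top strand is
#'   cut (\code{1} for G^ANTC).
#' @return List of class \code{restriction_enzyme}.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4) stop("recognition pattern must be >= 4 bases")
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the pattern")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' HinfI (G^ANTC)
#'
#' Recognition GANTC with the top-strand cut one base after the pattern
#' start; GANTC is its own reverse complement, so both strands share one cut
#' set.
#' @return A \code{\link{restriction_enzyme}}.
#' @export
hinfI <- function() restriction_enzyme("HinfI", "GANTC", 1L)

.circ_matches <- function(pattern, genome_seq, max_mismatch = 0) {
  L <- nchar(genome_seq)
  # append pattern-length-1 bases so origin-spanning sites are found once
  doubled <- paste0(genome_seq, substr(genome_seq, 1, nchar(pattern) - 1))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(doubled),
                                max.mismatch = max_mismatch, fixed = FALSE)
  sort(unique(Biostrings::start(m)))
}

#' In-silico PCR on a circular genome
#'
#' Locates the forward primer on the top strand and the reverse complement of
#' the reverse primer downstream of it (circularly); the product runs from
#' the forward primer's 5' end through the reverse primer's 5' end inclusive,
#' so both primers are part of the product. Back-to-back primers therefore
#' produce a near-genome-length amplicon. The smaller of the two circular
#' products is returned for each forward site; ambiguous primer sets
#' (several distinct products) are an error.
#'
#' @param genome a \code{circular_genome} with sequence.
#' @param primers a \code{\link{primer_pair}}.
#' @param max_mismatches mismatches tolerated per primer (default 0).
#' @return List of class \code{amplicon}: \code{sequence}, \code{start}
#'   (genome position of the forward 5' end), \code{length},
#'   \code{spans_origin}.
#' @export
in_silico_pcr <- function(genome, primers, max_mismatches = 0) {
  stopifnot(inherits(genome, "circular_genome"), inherits(primers, "primer_pair"))
  if (is.null(genome$sequence)) stop("genome sequence required for in-silico PCR")
  L <- genome$length
  fwd_starts <- .circ_matches(primers$forward, genome$sequence, max_mismatches)
  rev_rc <- reverse_complement(primers$reverse)
  rev_starts <- .circ_matches(rev_rc, genome$sequence, max_mismatches)
  if (!length(fwd_starts)) stop("forward primer has no binding site")
  if (!length(rev_starts)) stop("reverse primer has no binding site")
  rev_ends <- ((rev_starts + nchar(rev_rc) - 2L) %% L) + 1L

  products <- NULL
  for (f in fwd_starts) for (e in rev_ends) {
    len <- ((e - f) %% L) + 1L
    if (len >= nchar(primers$forward) + nchar(primers$reverse))
      products <- rbind(products, c(f, len))
  }
  if (is.null(products)) stop("no amplifiable product (primers overlap?)")
  # per forward site, a polymerase runs to the nearest downstream reverse site
  keep <- do.call(rbind, lapply(split(as.data.frame(products), products[, 1]),
                                function(d) d[which.min(d[, 2]), ]))
  if (nrow(keep) > 1L)
    stop("ambiguous PCR: ", nrow(keep), " distinct products")
  f <- keep[1, 1]; len <- keep[1, 2]
  doubled <- paste0(genome$sequence, genome$sequence)
  structure(list(name = primers$name,
                 sequence = substr(doubled, f, f + len - 1L),
                 start = as.integer(f), length = as.integer(len),
                 spans_origin = (f + len - 1L) > L),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat("<amplicon>", x$name, "-", x$length, "bp from position", x$start,
      if (x$spans_origin) "(spans origin)" else "", "\n")
  invisible(x)
}

#' Apply a single-base substitution to an amplicon
#'
#' @param a an \code{amplicon}.
#' @param pos genome position of the substitution (circular-aware; must fall
#'   inside the amplicon).
#' @param alt substituted base.
#' @param genome_length length of the source genome (needed to map positions
#'   across the origin for origin-spanning amplicons).
#' @return The amplicon with one base replaced; length unchanged.
#' @export
apply_variant <- function(a, pos, alt, genome_length) {
  stopifnot(inherits(a, "amplicon"))
  alt <- toupper(alt)
  if (!alt %in% c("A", "C", "G", "T")) stop("alt must be A/C/G/T")
  offset <- ((as.integer(pos) - a$start) %% genome_length) + 1L
  if (offset > a$length)
    stop("position ", pos, " is outside the amplicon")
  substr(a$sequence, offset, offset) <- alt
  a
}

#' Digest a linear amplicon with a restriction enzyme
#'
#' Finds all matches of the enzyme's IUPAC recognition pattern on both
#' strands of the (linear) product; each match contributes a cut at
#' \code{cut_offset} bases after the top-strand-equivalent pattern start.
#' Fragment lengths always sum to the amplicon length; a product without a
#' site yields a single full-length fragment.
#'
#' @param a an \code{amplicon} (or any object with \code{sequence}).
#' @param e a \code{\link{restriction_enzyme}}.
#' @return List of class \code{digest_result}: \code{fragments} (bp,
#'   descending), \code{cuts} (top-strand positions after which the product
#'   is cut), \code{length}.
#' @examples
#' amp <- structure(list(name = "toy", sequence = "AAGATTCAA", start = 1,
#'   length = 9, spans_origin = FALSE), class = "amplicon")
#' digest(amp, hinfI())   # fragments 6 and 3
#' @export
digest <- function(a, e) {
  stopifnot(inherits(e, "restriction_enzyme"))
  s <- a$sequence
  n <- nchar(s)
  plen <- nchar(e$recognition)
  subject <- Biostrings::DNAString(s)
  top <- Biostrings::start(Biostrings::matchPattern(e$recognition, subject, fixed = FALSE))
  bottom_m <- Biostrings::matchPattern(reverse_complement(e$recognition), subject,
                                       fixed = FALSE)
  # one cut per site interval, cut_offset from its 5'-most top coordinate;
  # for self-complementary patterns (HinfI) both scans give the same set
  bottom_cuts <- Biostrings::start(bottom_m) + e$cut_offset - 1L
  cuts <- sort(unique(c(top + e$cut_offset - 1L, bottom_cuts)))
  cuts <- cuts[cuts >= 1L & cuts < n]
  fragments <- diff(c(0L, cuts, n))
  structure(list(fragments = sort(as.integer(fragments), decreasing = TRUE),
                 cuts = as.integer(cuts), length = n),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result>", x$length, "bp ->",
      paste(x$fragments, collapse = " + "), "bp\n")
  invisible(x)
}

#' Band-intensity allele ratio
#'
#' Converts per-allele band grey values into allele percentages:
#' each allele's intensity over the total, times 100.
#'
#' @param grey_values named non-negative numeric vector of band intensities
#'   per allele.
#' @return Named numeric vector of allele percentages summing to 100.
#' @examples
#' band_allele_ratio(c(A = 52.71, G = 47.29))
#' @export
band_allele_ratio <- function(grey_values) {
  if (any(grey_values < 0)) stop("negative band intensity")
  tot <- sum(grey_values)
  if (tot == 0) stop("all band intensities are zero")
  100 * grey_values / tot
}

#' Per-allele RFLP banding report
#'
#' Digests an amplicon under each allele at a variant position and reports
#' the predicted fragment sizes, flagging fragments below the gel detection
#' floor as unresolved (they still count toward length conservation).
#'
#' @param genome a \code{circular_genome} with sequence.
#' @param primers a \code{\link{primer_pair}}.
#' @param pos variant genome position.
#' @param alleles bases to genotype (default: reference base and each
#'   supplied alternative).
#' @param enzyme a \code{\link{restriction_enzyme}} (default HinfI).
#' @param detection_floor_bp fragments shorter than this are flagged
#'   "not resolved" (default 50).
#' @return data.frame with one row per allele: \code{allele},
#'   \code{fragments} (text, descending), \code{resolved_fragments},
#'   \code{n_cuts}.
#' @export
rflp_genotype_report <- function(genome, primers, pos, alleles,
                                 enzyme = hinfI(), detection_floor_bp = 50) {
  amp <- in_silico_pcr(genome, primers)
  do.call(rbind, lapply(alleles, function(b) {
    av <- apply_variant(amp, pos, b, genome$length)
    d <- digest(av, enzyme)
    resolved <- d$fragments[d$fragments >= detection_floor_bp]
    data.frame(allele = b,
               product_bp = amp$length,
               fragments = paste(d$fragments, collapse = "+"),
               resolved_fragments = paste(resolved, collapse = "+"),
               n_cuts = length(d$cuts), stringsAsFactors = FALSE)
  }))
}

#' Read a primer table
#'
#' TSV with columns \code{name}, \code{forward}, \code{reverse} and
#' optionally \code{expected_length}.
#' @param path TSV path.
#' @return Named list of \code{\link{primer_pair}} objects.
#' @export
read_primer_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$name[i], df$forward[i], df$reverse[i],
                if ("expected_length" %in% names(df)) df$expected_length[i]))
  setNames(out, df$name)
}
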