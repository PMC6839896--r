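#' Assemble per-sample calls into a cohort matrix
#'
#' Stacks per-site calls from several samples into site-by-sample matrices of
#' minor allele frequency, predominant (major) allele and call status, tied
#' to per-sample metadata (individual, tissue, maternal line, generation,
#' age). Sites missing from a sample's call table are marked undetectable.
#'
#' @param calls a call data.frame covering several samples
#'   (\code{rbind} of \code{\link{call_sample}} outputs).
#' @param metadata data.frame with columns \code{sample}, \code{individual},
#'   \code{tissue}, \code{maternal_line}, \code{generation} (and optionally
#'   \code{age}); one row per sample in \code{calls}.
#' @return An object of class \code{cohort_matrix}: list with \code{sites}
#'   (ordered positions), \code{samples} (metadata in matrix column order),
#'   and \code{maf}, \code{major}, \code{status} matrices.
#' @export
cohort_matrix <- function(calls, metadata) {
  need <- c("sample", "individual", "tissue", "maternal_line", "generation")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(unique(calls$sample), metadata$sample)
  if (length(extra))
    stop("samples missing from metadata: ", paste(extra, collapse = ", "))
  metadata <- metadata[metadata$sample %in% calls$sample, , drop = FALSE]
  sites <- sort(unique(calls$pos))
  ids <- metadata$sample
  dim2 <- list(sites, ids)
  maf <- matrix(NA_real_, length(sites), length(ids), dimnames = dim2)
  major <- matrix(NA_character_, length(sites), length(ids), dimnames = dim2)
  status <- matrix("undetectable", length(sites), length(ids), dimnames = dim2)
  for (s in ids) {
    cs <- calls[calls$sample == s, ]
    i <- match(cs$pos, sites)
    maf[i, s] <- cs$maf
    major[i, s] <- cs$major
    status[i, s] <- cs$status
  }
  structure(list(sites = sites, samples = metadata,
                 maf = maf, major = major, status = status),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix>", length(x$sites), "sites x", nrow(x$samples), "samples\n")
  invisible(x)
}

#' Classify sites as polymorphic across a cohort
#'
#' A site is polymorphic when at least two distinct predominant alleles are
#' observed among samples in which the site is detectable; undetectable
#' cells are excluded, not imputed.
#'
#' @param cm a \code{\link{cohort_matrix}} (>= 2 samples).
#' @return data.frame with \code{pos}, \code{is_polymorphic},
#'   \code{predominant_alleles} (comma-separated set) and
#'   \code{n_samples_detectable}.
#' @export
classify_polymorphic <- function(cm) {
  stopifnot(inherits(cm, "cohort_matrix"))
  if (nrow(cm$samples) < 2L) stop("polymorphism requires >= 2 samples")
  res <- lapply(seq_along(cm$sites), function(i) {
    det <- cm$status[i, ] != "undetectable"
    alleles <- sort(unique(cm$major[i, det]))
    data.frame(pos = cm$sites[i],
               is_polymorphic = length(alleles) >= 2L,
               predominant_alleles = paste(alleles, collapse = ","),
               n_samples_detectable = sum(det))
  })
  do.call(rbind, res)
}

#' Tissue specificity of heteroplasmy within one individual
#'
#' Counts, for each site, the number of tissues of one individual in which it
#' is heteroplasmic. Sites heteroplasmic in exactly one tissue are
#' tissue-specific (TSS); the TSS count is also broken down by the tissue
#' carrying the call.
#'
#' @param cm a \code{\link{cohort_matrix}}.
#' @param individual individual id to restrict to (must have >= 2 tissues).
#' @return List with \code{site_counts} (data.frame \code{pos},
#'   \code{n_tissues_het}), \code{tss_sites} (positions heteroplasmic in one
#'   tissue), \code{tss_per_tissue} (named counts) and \code{histogram}
#'   (table of sites by number of heteroplasmic tissues, het sites only).
#' @export
tissue_specificity <- function(cm, individual) {
  stopifnot(inherits(cm, "cohort_matrix"))
  sel <- cm$samples$individual == individual
  if (sum(sel) < 2L) stop("individual ", individual, " has < 2 tissues in the cohort")
  st <- cm$status[, sel, drop = FALSE]
  tissues <- cm$samples$tissue[sel]
  n_het <- rowSums(st == "heteroplasmic")
  tss_idx <- which(n_het == 1L)
  tss_tissue <- vapply(tss_idx, function(i) tissues[st[i, ] == "heteroplasmic"],
                       character(1))
  list(site_counts = data.frame(pos = cm$sites, n_tissues_het = n_het),
       tss_sites = cm$sites[tss_idx],
       tss_per_tissue = table(factor(tss_tissue, levels = unique(tissues))),
       histogram = table(n_het[n_het > 0]))
}

#' Pairwise predominant-allele concordance between samples
#'
#' For each sample pair, the fraction of sites (within \code{sites}) at which
#' both samples are detectable and share the same predominant allele. Pairs
#' with no comparable site get \code{NA}. Same-maternal-line pairs are
#' expected near 1 at polymorphic sites under maternal inheritance.
#'
#' @param cm a \code{\link{cohort_matrix}}.
#' @param sites positions to compare (e.g. polymorphic sites); default all.
#' @return List with \code{concordance} (symmetric matrix, unit diagonal),
#'   \code{n_shared} and \code{n_compared} count matrices.
#' @export
maternal_concordance <- function(cm, sites = cm$sites) {
  stopifnot(inherits(cm, "cohort_matrix"))
  idx <- match(sites, cm$sites)
  if (anyNA(idx)) stop("some requested sites are absent from the cohort")
  if (!length(idx)) stop("empty site set")
  ids <- cm$samples$sample
  k <- length(ids)
  conc <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  shared <- compared <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ok <- cm$status[idx, a] != "undetectable" & cm$status[idx, b] != "undetectable"
    compared[a, b] <- sum(ok)
    shared[a, b] <- sum(ok & cm$major[idx, a] == cm$major[idx, b])
    if (compared[a, b] > 0) conc[a, b] <- shared[a, b] / compared[a, b]
  }
  list(concordance = conc, n_shared = shared, n_compared = compared)
}

#' Genotype frequencies per stratum and pooled
#'
#' Converts genotype counts per stratum (e.g. breed) into within-stratum and
#' pooled frequencies, the layout used for PCR-RFLP genotyping surveys.
#'
#' @param counts data.frame with columns \code{site}, \code{genotype},
#'   \code{stratum}, \code{count}.
#' @return List with \code{per_stratum} (adds \code{frequency} within
#'   site-by-stratum) and \code{pooled} (per site-by-genotype over all
#'   strata).
#' @export
genotype_frequencies <- function(counts) {
  need <- c("site", "genotype", "stratum", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols))
    stop("genotype counts lack columns: ", paste(missing_cols, collapse = ", "))
  if (any(counts$count < 0)) stop("negative genotype counts")
  per <- counts
  per$frequency <- NA_real_
  for (k in split(seq_len(nrow(per)), paste(per$site, per$stratum))) {
    tot <- sum(per$count[k])
    if (tot == 0) stop("zero total genotype count in a stratum")
    per$frequency[k] <- per$count[k] / tot
  }
  pooled <- aggregate(count ~ site + genotype, counts, sum)
  pooled$frequency <- NA_real_
  for (k in split(seq_len(nrow(pooled)), pooled$site))
    pooled$frequency[k] <- pooled$count[k] / sum(pooled$count[k])
  list(per_stratum = per, pooled = pooled)
}

#' Heteroplasmy occurrence and mother-offspring outcomes at one site
#'
#' From a pedigree allele-ratio table (pyrosequencing-style percent of the
#' predominant allele per individual), counts heteroplasmic individuals per
#' generation (minor-allele ratio of at least \code{het_floor} percent) and
#' tabulates, for each heteroplasmic mother, her offspring's ratios and
#' whether each offspring reverted to homoplasmy. The default floor of
#' 0.05\% is the pyrosequencing convention; NGS calls use the 0.5\% MAF
#' threshold of \code{\link{caller_config}}.
#'
#' @param pedigree data.frame with columns \code{individual}, \code{mother}
#'   (id or \code{NA}), \code{generation} (\code{"F0"}/\code{"F1"}),
#'   \code{site}, \code{allele_ratio_percent} (0..100, predominant-allele
#'   scale).
#' @param site site label to analyse.
#' @param het_floor heteroplasmy floor in percent on the minor allele
#'   (default 0.05).
#' @return List with \code{occurrence} (per-generation data.frame \code{n},
#'   \code{heteroplasmic}), \code{offspring_outcomes} (one row per offspring
#'   of a heteroplasmic mother: mother ratio, offspring ratio,
#'   \code{offspring_homoplasmic}) and \code{het_floor}.
#' @export
transmission_summary <- function(pedigree, site, het_floor = 0.05) {
  ped <- pedigree[pedigree$site == site, , drop = FALSE]
  if (!nrow(ped)) stop("no pedigree records for site ", site)
  if (any(ped$allele_ratio_percent < 0 | ped$allele_ratio_percent > 100))
    stop("allele ratios must lie in [0, 100]")
  minor <- pmin(ped$allele_ratio_percent, 100 - ped$allele_ratio_percent)
  ped$heteroplasmic <- minor >= het_floor
  occ <- do.call(rbind, lapply(split(ped, ped$generation), function(g)
    data.frame(generation = g$generation[1], n = nrow(g),
               heteroplasmic = sum(g$heteroplasmic))))
  rownames(occ) <- NULL

  mothers <- ped[ped$generation == "F0" & ped$heteroplasmic, ]
  kids <- ped[ped$generation == "F1" & !is.na(ped$mother) &
                ped$mother %in% mothers$individual, ]
  outcomes <- if (nrow(kids)) {
    data.frame(mother = kids$mother,
               mother_ratio = mothers$allele_ratio_percent[match(kids$mother, mothers$individual)],
               offspring = kids$individual,
               offspring_ratio = kids$allele_ratio_percent,
               offspring_homoplasmic = !kids$heteroplasmic)
  } else {
    data.frame(mother = character(0), mother_ratio = numeric(0),
               offspring = character(0), offspring_ratio = numeric(0),
               offspring_homoplasmic = logical(0))
  }
  list(occurrence = occ, offspring_outcomes = outcomes, het_floor = het_floor)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: with margins
#' fixed, sum the hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table.
#'
#' @param t 2x2 non-negative integer matrix.
#' @return p-value in [0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(54, 149, 2, 29), 2))
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  stopifnot(all(dim(t) == 2L), all(t >= 0))
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(t[, 2]) == 0)
    stop("degenerate margins in 2x2 table")
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(t[1, 1], r1, r2, c1)
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic on 1 degree of freedom, without continuity correction by
#' default. Errors when an expected cell is zero (use
#' \code{\link{fisher_exact_2x2}} for sparse tables).
#'
#' @param t 2x2 non-negative matrix.
#' @param correct apply the Yates continuity correction.
#' @return List with \code{statistic}, \code{df} and \code{p_value}.
#' @export
chi_square_2x2 <- function(t, correct = FALSE) {
  t <- as.matrix(t)
  stopifnot(all(dim(t) == 2L), all(t >= 0))
  n <- sum(t)
  expected <- outer(rowSums(t), colSums(t)) / n
  if (any(expected == 0))
    stop("zero expected cell; use fisher_exact_2x2 instead")
  d <- abs(t - expected)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / expected)
  list(statistic = stat, df = 1L, p_value = pchisq(stat, 1L, lower.tail = FALSE))
}
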