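#' Caller configuration
#'
#' Thresholds for heteroplasmy calling. The primary detection threshold is a
#' minor allele frequency (MAF) of at least 0.5\%; sites with
#' 0.1\% <= MAF < 0.5\% are reported as potentially heteroplasmic. The
#' minimum minor-read count and optional strand-bias cap are additional
#' guards against sequencing artefacts; setting \code{min_minor_count = 0}
#' and \code{strand_bias_max = NULL} recovers pure threshold behaviour.
#'
#' @param het_threshold heteroplasmy MAF threshold in percent (default 0.5).
#' @param potential_floor lower MAF bound in percent for "potential" calls
#'   (default 0.1).
#' @param min_depth minimum used depth (A+C+G+T reads); below it a site is
#'   undetectable (default 10).
#' @param min_minor_count minimum minor-allele read count for a heteroplasmic
#'   call (default 2).
#' @param strand_bias_max optional cap on the minor allele's strand imbalance
#'   \code{max(fwd, rev) / max(1, min(fwd, rev))}; \code{NULL} disables it.
#' @return A list of class \code{caller_config}.
#' @export
caller_config <- function(het_threshold = 0.5, potential_floor = 0.1,
                          min_depth = 10, min_minor_count = 2,
                          strand_bias_max = NULL) {
  if (!(potential_floor > 0 && potential_floor < het_threshold && het_threshold <= 50))
    stop("need 0 < potential_floor < het_threshold <= 50")
  structure(list(het_threshold = het_threshold, potential_floor = potential_floor,
                 min_depth = as.integer(min_depth),
                 min_minor_count = as.integer(min_minor_count),
                 strand_bias_max = strand_bias_max),
            class = "caller_config")
}

.base_totals <- function(bc) {
  cbind(A = bc$A_fwd + bc$A_rev, C = bc$C_fwd + bc$C_rev,
        G = bc$G_fwd + bc$G_rev, T = bc$T_fwd + bc$T_rev)
}

#' Call heteroplasmy status at sites from base counts
#'
#' For each site the alternative allele frequency of every base is its
#' forward+reverse read count divided by the total A+C+G+T coverage
#' (both strands), times 100. The major allele is the most frequent base
#' (ties broken toward the reference base, then alphabetically); the MAF is
#' the frequency of the second most frequent base. Status is
#' \code{undetectable} when used depth is below \code{min_depth};
#' \code{heteroplasmic} when MAF >= \code{het_threshold} (and the minor count
#' and strand-bias guards pass); \code{potential} when
#' \code{potential_floor} <= MAF < \code{het_threshold}; otherwise
#' \code{homoplasmic}.
#'
#' @param bc a base-count data.frame (one or more rows); see
#'   \code{\link{parse_pileup_line}}.
#' @param cfg a \code{\link{caller_config}}.
#' @return A data.frame with one row per input row: \code{sample},
#'   \code{pos}, \code{ref}, \code{aaf_A..aaf_T} (percent), \code{major},
#'   \code{minor}, \code{minor_count}, \code{maf} (percent),
#'   \code{depth_used} and \code{status}.
#' @examples
#' bc <- data.frame(sample = "s", chrom = "mt", pos = 1, ref = "A",
#'   A_fwd = 4990, A_rev = 4990, C_fwd = 0, C_rev = 0,
#'   G_fwd = 10, G_rev = 10, T_fwd = 0, T_rev = 0, del = 0)
#' call_site(bc)   # MAF 0.2% -> potential
#' @export
call_site <- function(bc, cfg = caller_config()) {
  stopifnot(inherits(cfg, "caller_config"))
  n <- nrow(bc)
  tot <- .base_totals(bc)
  depth <- rowSums(tot)
  aaf <- 100 * tot / ifelse(depth > 0, depth, 1)
  aaf[depth == 0, ] <- 0

  major <- minor <- character(n)
  maf <- numeric(n)
  minor_count <- integer(n)
  bases <- colnames(tot)
  for (i in seq_len(n)) {
    f <- aaf[i, ]
    # tie-break toward the reference base, then alphabetical
    if (bc$ref[i] %in% bases && f[bc$ref[i]] == max(f)) {
      ord <- c(bc$ref[i], setdiff(bases[order(-f, bases)], bc$ref[i]))
    } else {
      ord <- bases[order(-f, bases)]
    }
    major[i] <- ord[1]
    minor[i] <- ord[2]
    maf[i] <- f[ord[2]]
    minor_count[i] <- tot[i, ord[2]]
  }
  minor[maf == 0] <- NA_character_

  status <- rep("homoplasmic", n)
  is_het <- maf >= cfg$het_threshold & minor_count >= cfg$min_minor_count
  if (!is.null(cfg$strand_bias_max)) {
    fwd <- as.matrix(bc[paste0(bases, "_fwd")]); rev <- as.matrix(bc[paste0(bases, "_rev")])
    for (i in which(is_het)) {
      mf <- fwd[i, paste0(minor[i], "_fwd")]; mr <- rev[i, paste0(minor[i], "_rev")]
      if (max(mf, mr) / max(1, min(mf, mr)) > cfg$strand_bias_max) is_het[i] <- FALSE
    }
  }
  status[maf >= cfg$potential_floor & !is_het] <- "potential"
  status[is_het] <- "heteroplasmic"
  status[depth < cfg$min_depth] <- "undetectable"

  out <- data.frame(sample = bc$sample, pos = bc$pos, ref = bc$ref,
                    stringsAsFactors = FALSE)
  out$aaf_A <- aaf[, "A"]; out$aaf_C <- aaf[, "C"]
  out$aaf_G <- aaf[, "G"]; out$aaf_T <- aaf[, "T"]
  out$major <- major; out$minor <- minor; out$minor_count <- minor_count
  out$maf <- maf; out$depth_used <- as.integer(depth); out$status <- status
  out
}

#' Call every site of one sample
#'
#' @param counts base-count data.frame for a single sample with unique
#'   positions.
#' @param cfg a \code{\link{caller_config}}.
#' @return Per-site call data.frame (input order preserved); see
#'   \code{\link{call_site}}.
#' @export
call_sample <- function(counts, cfg = caller_config()) {
  if (nrow(counts) == 0L) return(call_site(counts[0, , drop = FALSE], cfg))
  if (length(unique(counts$sample)) > 1L)
    stop("call_sample expects a single sample; got ",
         paste(unique(counts$sample), collapse = ", "))
  if (anyDuplicated(counts$pos)) stop("duplicate positions in sample counts")
  call_site(counts, cfg)
}

#' Summarise one sample's calls into threshold tiers
#'
#' Reproduces the per-sample summary layout of whole-mtDNA heteroplasmy
#' surveys: counts of sites with MAF at or above 0.5/1/5/10 percent, sites
#' whose predominant allele differs from the reference (AAF >= 50\%), and
#' undetectable sites (UN). Tissue-specific site (TSS) counts are a
#' cohort-level quantity filled in by \code{\link{tissue_specificity}}.
#'
#' @param calls per-site call data.frame from \code{\link{call_sample}}.
#' @param tiers MAF tier thresholds in percent.
#' @return Named integer vector with elements \code{MAF>=0.5\%} etc.,
#'   \code{AAF>=50\%} and \code{UN}.
#' @export
summarize_sample <- function(calls, tiers = c(0.5, 1, 5, 10)) {
  det <- calls$status != "undetectable"
  tier_counts <- vapply(tiers, function(t) sum(det & calls$maf >= t), integer(1))
  names(tier_counts) <- sprintf("MAF>=%g%%", tiers)
  c(tier_counts,
    "AAF>=50%" = sum(det & calls$major != calls$ref),
    UN = sum(!det))
}

#' Write per-site calls as TSV
#' @param calls call data.frame.
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write heteroplasmic calls as a minimal VCF
#'
#' Emits heteroplasmic sites only, with the minor allele as ALT and its
#' frequency (fraction, not percent) as \code{AF} in INFO.
#'
#' @param calls call data.frame.
#' @param path output file.
#' @param chrom chromosome name to print.
#' @export
write_calls_vcf <- function(calls, path, chrom = "MT") {
  het <- calls[calls$status == "heteroplasmic", , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Minor allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(het))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f",
                       chrom, het$pos, het$ref, het$minor, het$maf / 100), con)
  invisible(path)
}
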