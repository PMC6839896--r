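#' Simulation configuration for synthetic heteroplasmy cohorts
#'
#' Defines the generating conditions for synthetic base-count cohorts: a
#' multi-individual, multi-tissue design with maternal haplotype structure,
#' D-loop hotspot enrichment, transition bias, binomial sequencing noise and
#' a single-generation germline bottleneck. Defaults emulate the study
#' conditions of a whole-mtDNA chicken heteroplasmy survey: an 18-sample
#' design (one individual with ten tissues, seven further individuals with
#' one muscle sample each, two mixed-tissue samples) over three maternal
#' lines; ~34-fold per-base hotspot weight on the D-loop (so roughly 73\% of
#' variant sites fall in the 1,227-bp D-loop); transition probability 0.84;
#' heteroplasmic fractions log-uniform on [0.001, 0.40]; mean coverage
#' 7,800x; per-base error 0.001; bottleneck size 32.
#'
#' @param seed integer seed; all randomness in \code{\link{simulate_cohort}}
#'   flows from it.
#' @param annotation a \code{genome_annotation} providing genome length and
#'   the D-loop interval; default the packaged synthetic reference.
#' @param design data.frame (sample, individual, tissue, maternal_line,
#'   generation, age) describing the cohort; default the 18-sample layout.
#' @param n_polymorphic_sites number of haplotype sites distinguishing
#'   maternal lines (default 56).
#' @param line_alt_counts per-line number of haplotype sites carrying the
#'   alternative allele (first line is the reference haplotype; defaults
#'   c(0, 42, 44) so lines differ pairwise at 42..56 sites).
#' @param n_inherited_het_sites inherited heteroplasmic sites per individual,
#'   shared across its tissues (default 4).
#' @param n_somatic_sites somatic heteroplasmic sites per tissue sample
#'   (default 10).
#' @param dloop_weight per-base sampling weight of D-loop positions relative
#'   to the rest of the genome (default 34).
#' @param kappa probability a simulated substitution is a transition
#'   (default 0.84).
#' @param frac_range log-uniform range of true minor-allele fractions
#'   (default c(0.001, 0.40)).
#' @param coverage_mean,coverage_size negative-binomial coverage model
#'   (mean 7800, size 8).
#' @param error_rate per-base sequencing error rate (default 1e-3).
#' @param bottleneck_size germline bottleneck size N_b (default 32).
#' @param pyro_noise_sd sd (percentage points) of pyrosequencing measurement
#'   noise on reported allele ratios, after triplicate averaging
#'   (default 0.02).
#' @param tissue_jitter_sd lognormal sd of inherited-site fractions around
#'   the individual mean across tissues (default 0.3).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       annotation = NULL,
                       design = default_cohort_design(),
                       n_polymorphic_sites = 56L,
                       line_alt_counts = c(0L, 42L, 44L),
                       n_inherited_het_sites = 4L,
                       n_somatic_sites = 10L,
                       dloop_weight = 34,
                       kappa = 0.84,
                       frac_range = c(0.001, 0.40),
                       coverage_mean = 7800,
                       coverage_size = 8,
                       error_rate = 1e-3,
                       bottleneck_size = 32L,
                       pyro_noise_sd = 0.02,
                       tissue_jitter_sd = 0.3) {
  stopifnot(kappa >= 0, kappa <= 1, error_rate >= 0, error_rate <= 1,
            bottleneck_size >= 1, all(frac_range > 0), frac_range[1] <= frac_range[2])
  structure(as.list(environment()), class = "sim_config")
}

#' Default 18-sample cohort design
#'
#' One individual (line 2) sampled in ten tissues, five line-1 individuals
#' sampled in skeletal muscle, one line-3 individual in muscle, and two
#' line-1 mixed-tissue homogenates.
#'
#' @return data.frame with columns sample, individual, tissue,
#'   maternal_line, generation, age.
#' @export
default_cohort_design <- function() {
  tissues10 <- c("cerebrum", "pectoral", "visceral_fat", "heart", "kidney",
                 "lung", "gizzard", "proventriculus", "testis", "crureus")
  rbind(
    data.frame(sample = paste0("IND1_", tissues10), individual = "IND1",
               tissue = tissues10, maternal_line = "L2", generation = "F1",
               age = 60),
    data.frame(sample = paste0("IND", 2:6, "_crureus"),
               individual = paste0("IND", 2:6), tissue = "crureus",
               maternal_line = "L1", generation = "F1", age = c(1, 30, 60, 60, 60)),
    data.frame(sample = "IND7_crureus", individual = "IND7", tissue = "crureus",
               maternal_line = "L3", generation = "F1", age = 60),
    data.frame(sample = paste0("IND", 8:9, "_homogenate"),
               individual = paste0("IND", 8:9), tissue = "homogenate",
               maternal_line = "L1", generation = "F1", age = c(1, 60))
  )
}

.other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

.draw_alt <- function(ref, kappa) {
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  if (runif(1) < kappa) unname(transition_of[ref])
  else sample(setdiff(.other_bases(ref), transition_of[ref]), 1)
}

#' Simulate strand-aware base counts at one site
#'
#' Reads are multinomial over the four bases: a fraction \code{f} of
#' template molecules carries \code{alt}, sequencing errors move each read
#' to one of the other three bases uniformly at rate \code{e}, and each read
#' lands on the forward strand with probability 1/2.
#'
#' @param sample,chrom,pos,ref record identity; \code{ref} is the reference
#'   base.
#' @param alt minor (alternative) allele.
#' @param f true minor fraction in [0, 1].
#' @param coverage total read count.
#' @param e per-base error rate.
#' @return One-row base-count data.frame (see
#'   \code{\link{parse_pileup_line}}).
#' @export
simulate_counts_at_site <- function(f, coverage, e = 0, ref = "A", alt = "G",
                                    sample = "sim", chrom = "mt", pos = 1L) {
  stopifnot(f >= 0, f <= 1, coverage >= 0)
  bases <- c("A", "C", "G", "T")
  true_frac <- setNames(numeric(4), bases)
  true_frac[ref] <- 1 - f
  true_frac[alt] <- true_frac[alt] + f
  # error redistributes each base's reads uniformly to the other three
  p <- vapply(bases, function(b)
    true_frac[b] * (1 - e) + sum(true_frac[.other_bases(b)]) * e / 3, numeric(1))
  n <- if (coverage > 0) as.vector(rmultinom(1, coverage, p)) else rep(0L, 4)
  fwd <- vapply(n, function(k) rbinom(1, k, 0.5), integer(1))
  out <- data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
                    ref = ref, stringsAsFactors = FALSE)
  out$A_fwd <- fwd[1]; out$A_rev <- n[1] - fwd[1]
  out$C_fwd <- fwd[2]; out$C_rev <- n[2] - fwd[2]
  out$G_fwd <- fwd[3]; out$G_rev <- n[3] - fwd[3]
  out$T_fwd <- fwd[4]; out$T_rev <- n[4] - fwd[4]
  out$del <- 0L; out$skipped <- 0L; out$discarded <- 0L
  out$depth_used <- as.integer(sum(n))
  out
}

.sample_positions <- function(n, cfg, ann, exclude = integer(0)) {
  L <- ann$genome$length
  w <- rep(1, L)
  w[ann$pos_class == "D-loop"] <- cfg$dloop_weight
  w[exclude] <- 0
  sample.int(L, n, prob = w)
}

#' Simulate a base-count cohort with truth tables
#'
#' Generates per-sample base counts under the configured design: maternal
#' lines carry fixed alternative alleles at haplotype sites (truth
#' polymorphic), each individual carries inherited heteroplasmic sites whose
#' fractions are correlated across its tissues (lognormal jitter around an
#' individual mean), and each tissue sample receives its own somatic sites
#' (truth tissue-specific). Variant positions are drawn with D-loop hotspot
#' weighting and substitutions with transition probability \code{kappa}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List with \code{counts} (base-count data.frame over all samples;
#'   positions assayed are the union of haplotype and variant sites),
#'   \code{truth} (per site-by-sample: true fraction, origin, region class,
#'   substitution class), \code{metadata} (the design), \code{sites}
#'   (per-site truth: pos, ref, alt, origin), and \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ann <- cfg$annotation
  if (is.null(ann)) ann <- synthetic_reference()$annotation
  genome <- ann$genome
  design <- cfg$design
  lines <- unique(design$maternal_line)
  stopifnot(length(cfg$line_alt_counts) >= length(lines))

  refchars <- strsplit(genome$sequence, "")[[1]]
  rfrac <- function(n) exp(runif(n, log(cfg$frac_range[1]), log(cfg$frac_range[2])))
  rcov <- function(n) rnbinom(n, size = cfg$coverage_size, mu = cfg$coverage_mean)

  # haplotype (polymorphic) sites: uniform positions, line-specific alleles
  hap_pos <- sort(sample.int(genome$length, cfg$n_polymorphic_sites))
  hap_ref <- refchars[hap_pos]
  hap_alt <- vapply(hap_ref, .draw_alt, character(1), kappa = cfg$kappa)
  hap_allele <- matrix(rep(hap_ref, length(lines)), ncol = length(lines),
                       dimnames = list(NULL, lines))
  for (j in seq_along(lines)) {
    k <- min(cfg$line_alt_counts[j], cfg$n_polymorphic_sites)
    if (k > 0) {
      idx <- sample.int(cfg$n_polymorphic_sites, k)
      hap_allele[idx, j] <- hap_alt[idx]
    }
  }

  used <- hap_pos
  sites <- data.frame(pos = hap_pos, ref = hap_ref, alt = hap_alt,
                      origin = "haplotype", stringsAsFactors = FALSE)
  counts <- list(); truth <- list()

  # inherited heteroplasmic sites per individual
  inherited <- list()
  for (ind in unique(design$individual)) {
    p <- .sample_positions(cfg$n_inherited_het_sites, cfg, ann, exclude = used)
    used <- c(used, p)
    r <- refchars[p]
    a <- vapply(r, .draw_alt, character(1), kappa = cfg$kappa)
    inherited[[ind]] <- data.frame(pos = p, ref = r, alt = a,
                                   mean_frac = rfrac(length(p)),
                                   stringsAsFactors = FALSE)
    sites <- rbind(sites, data.frame(pos = p, ref = r, alt = a,
                                     origin = "inherited"))
  }

  for (si in seq_len(nrow(design))) {
    smp <- design$sample[si]; ind <- design$individual[si]
    line <- design$maternal_line[si]
    # somatic sites private to this tissue sample
    p <- .sample_positions(cfg$n_somatic_sites, cfg, ann, exclude = used)
    used <- c(used, p)
    som <- data.frame(pos = p, ref = refchars[p],
                      alt = vapply(refchars[p], .draw_alt, character(1),
                                   kappa = cfg$kappa),
                      frac = rfrac(length(p)), stringsAsFactors = FALSE)
    sites <- rbind(sites, data.frame(pos = som$pos, ref = som$ref,
                                     alt = som$alt, origin = "somatic"))

    inh <- inherited[[ind]]
    inh_frac <- pmin(0.45, inh$mean_frac *
                       rlnorm(nrow(inh), 0, cfg$tissue_jitter_sd))

    tab <- rbind(
      data.frame(pos = hap_pos, ref = hap_ref, site_allele = hap_allele[, line],
                 frac = 0, origin = "haplotype", stringsAsFactors = FALSE),
      data.frame(pos = inh$pos, ref = inh$ref, site_allele = inh$alt,
                 frac = inh_frac, origin = "inherited"),
      data.frame(pos = som$pos, ref = som$ref, site_allele = som$alt,
                 frac = som$frac, origin = "somatic")
    )
    cov <- rcov(nrow(tab))
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      if (tab$origin[i] == "haplotype") {
        # fixed line allele: the "alt" IS the consensus when it differs from ref
        fixed <- tab$site_allele[i]
        bc <- simulate_counts_at_site(f = if (fixed == tab$ref[i]) 0 else 1,
                                      coverage = cov[i], e = cfg$error_rate,
                                      ref = tab$ref[i],
                                      alt = if (fixed == tab$ref[i]) .other_bases(tab$ref[i])[1] else fixed,
                                      sample = smp, chrom = genome$id,
                                      pos = tab$pos[i])
      } else {
        bc <- simulate_counts_at_site(f = tab$frac[i], coverage = cov[i],
                                      e = cfg$error_rate, ref = tab$ref[i],
                                      alt = tab$site_allele[i], sample = smp,
                                      chrom = genome$id, pos = tab$pos[i])
      }
      bc
    })
    cnt <- do.call(rbind, rows)
    cnt <- cnt[order(cnt$pos), ]
    counts[[smp]] <- cnt
    truth[[smp]] <- data.frame(sample = smp, pos = tab$pos,
                               true_frac = tab$frac, origin = tab$origin,
                               line_allele = tab$site_allele,
                               stringsAsFactors = FALSE)
  }

  sites <- sites[!duplicated(sites$pos), ]
  reg <- region_of(sites$pos, ann)
  sites$region <- reg$class
  sites$substitution <- classify_substitution(sites$ref, sites$alt)

  list(counts = do.call(rbind, counts), truth = do.call(rbind, truth),
       metadata = design, sites = sites[order(sites$pos), ], config = cfg)
}

#' Simulate single-generation bottleneck transmission
#'
#' Offspring heteroplasmic fractions after one germline bottleneck of
#' \code{n_b} segregating mtDNA units: each offspring's fraction is
#' \code{k / n_b} with \code{k ~ Binomial(n_b, p)}. The offspring variance
#' is \code{p (1 - p) / n_b}.
#'
#' @param p mother's heteroplasmic fraction in [0, 1].
#' @param n_b bottleneck size (>= 1).
#' @param n_offspring number of offspring to draw.
#' @return Numeric vector of offspring fractions in [0, 1].
#' @examples
#' set.seed(1); simulate_transmission(0.3, 32, 5)
#' @export
simulate_transmission <- function(p, n_b, n_offspring) {
  stopifnot(p >= 0, p <= 1, n_b >= 1)
  rbinom(n_offspring, as.integer(n_b), p) / as.integer(n_b)
}

#' Simulate a pyrosequencing-style pedigree table through a bottleneck
#'
#' Draws mother fractions, transmits each through a single-generation
#' bottleneck, adds Gaussian measurement noise, and returns a pedigree
#' allele-ratio table suitable for \code{\link{transmission_summary}}.
#'
#' @param n_mothers number of F0 mothers.
#' @param n_offspring_per_mother offspring per mother.
#' @param mother_frac_range log-uniform range of mother minor fractions.
#' @param cfg a \code{\link{sim_config}} (bottleneck size, pyro noise, seed).
#' @param site site label for the output table.
#' @return Pedigree data.frame (individual, mother, generation, site,
#'   allele_ratio_percent) on the predominant-allele percent scale.
#' @export
simulate_pedigree <- function(n_mothers = 26, n_offspring_per_mother = 2,
                              mother_frac_range = c(0.0005, 0.5),
                              cfg = sim_config(), site = "site1") {
  set.seed(cfg$seed + 1L)
  noisy <- function(x) pmin(100, pmax(0, x + rnorm(length(x), 0, cfg$pyro_noise_sd)))
  p <- exp(runif(n_mothers, log(mother_frac_range[1]), log(mother_frac_range[2])))
  rows <- list()
  for (m in seq_len(n_mothers)) {
    mid <- sprintf("F0_%03d", m)
    rows[[length(rows) + 1L]] <-
      data.frame(individual = mid, mother = NA_character_, generation = "F0",
                 site = site, allele_ratio_percent = noisy(100 * (1 - p[m])),
                 stringsAsFactors = FALSE)
    off <- simulate_transmission(p[m], cfg$bottleneck_size, n_offspring_per_mother)
    for (k in seq_along(off)) {
      rows[[length(rows) + 1L]] <-
        data.frame(individual = sprintf("F1_%03d_%d", m, k), mother = mid,
                   generation = "F1", site = site,
                   allele_ratio_percent = noisy(100 * (1 - off[k])),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
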