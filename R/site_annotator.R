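#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) exchanges are
#' transitions; all others are transversions.
#'
#' @param ref,alt reference and alternative bases (vectorised).
#' @return Character vector of \code{"transition"} / \code{"transversion"}.
#' @examples
#' classify_substitution("G", "A")
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("bases must be A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(ref) == purine(alt), "transition", "transversion")
}

.aa_symbol <- function(aa) if (aa == "*") "X" else aa

#' Annotate a variant with region, substitution class and coding effect
#'
#' Resolves the region class of the position, classifies the substitution,
#' and for coding positions mutates the codon, translates reference and
#' mutant codons under the vertebrate mitochondrial code, and labels the
#' amino-acid change as e.g. \code{"D118N"} (1-based from the CDS start
#' codon; stop codons are written \code{X}). Positions covered by several
#' overlapping CDSs are annotated against each; the reported mutation type
#' and label come from the first CDS in genome order, with all effects
#' retained in \code{effects}.
#'
#' @param pos 1-based genome position.
#' @param ref reference base; must match the genome sequence at \code{pos}.
#' @param alt alternative base.
#' @param ann a \code{genome_annotation} whose genome carries a sequence.
#' @return A list with \code{name} (e.g. \code{"mt.G8682A"}), \code{pos},
#'   \code{ref}, \code{alt}, \code{region} (single class), \code{feature},
#'   \code{substitution}, \code{mutation_type} (\code{NC}/\code{S}/\code{NS}),
#'   \code{aa_change} (label for non-synonymous changes, otherwise \code{NA})
#'   and \code{effects} (per-CDS data.frame, \code{NULL} outside CDS).
#' @export
annotate_variant <- function(pos, ref, alt, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  genome <- ann$genome
  if (is.null(genome$sequence)) stop("genome sequence required to annotate variants")
  ref <- toupper(ref); alt <- toupper(alt)
  genome_ref <- ref_base(pos, genome)
  if (genome_ref != ref)
    stop("reference mismatch at ", pos, ": variant says ", ref,
         ", genome has ", genome_ref)
  substitution <- classify_substitution(ref, alt)
  reg <- region_of(pos, ann)

  cds_names <- cds_at(pos, ann)
  effects <- NULL
  mutation_type <- "NC"
  aa_change <- NA_character_
  if (length(cds_names)) {
    effects <- do.call(rbind, lapply(cds_names, function(nm) {
      cds <- ann$cds_features[ann$cds_features$name == nm, ]
      ctx <- codon_context(pos, cds, genome)
      coding_ref <- if (identical(cds$strand, "-")) unname(COMPLEMENT[ref]) else ref
      coding_alt <- if (identical(cds$strand, "-")) unname(COMPLEMENT[alt]) else alt
      stopifnot(substr(ctx$codon, ctx$within, ctx$within) == coding_ref)
      mut <- ctx$codon
      substr(mut, ctx$within, ctx$within) <- coding_alt
      aa_ref <- ctx$aa
      aa_alt <- translate_codon(mut, as_start = ctx$aa_index == 1L)
      data.frame(gene = nm, codon_ref = ctx$codon, codon_alt = mut,
                 aa_index = ctx$aa_index,
                 aa_ref = aa_ref, aa_alt = aa_alt,
                 type = if (aa_ref == aa_alt) "S" else "NS",
                 label = if (aa_ref == aa_alt) NA_character_ else
                   paste0(.aa_symbol(aa_ref), ctx$aa_index, .aa_symbol(aa_alt)),
                 stringsAsFactors = FALSE)
    }))
    mutation_type <- effects$type[1]
    aa_change <- effects$label[1]
  }

  list(name = paste0("mt.", ref, pos, alt), pos = as.integer(pos),
       ref = ref, alt = alt,
       region = reg$class, feature = reg$feature,
       substitution = substitution, mutation_type = mutation_type,
       aa_change = aa_change, effects = effects)
}

#' Annotate many variants into a site table
#'
#' @param sites data.frame with columns \code{pos}, \code{ref}, \code{alt}.
#' @param ann a \code{genome_annotation}.
#' @return data.frame with one row per variant (name, region, feature,
#'   substitution, mutation_type, aa_change) merged onto the input columns.
#' @export
annotate_sites <- function(sites, ann) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    a <- annotate_variant(sites$pos[i], sites$ref[i], sites$alt[i], ann)
    data.frame(name = a$name, pos = a$pos, ref = a$ref, alt = a$alt,
               region = a$region, feature = a$feature,
               substitution = a$substitution, mutation_type = a$mutation_type,
               aa_change = a$aa_change, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  extra <- setdiff(names(sites), names(out))
  if (length(extra) && !is.null(out)) out <- cbind(out, sites[extra])
  if (is.null(out)) out <- data.frame()
  out
}

#' Tabulate annotated sites by mutation type, region and substitution
#'
#' Builds the region-by-substitution contingency layout used to report
#' heteroplasmic and polymorphic site distributions: one row per
#' (mutation type, region/gene), with per-group totals and a grand total,
#' counting transitions, transversions and any logical grouping columns
#' supplied (e.g. \code{polymorphic}, \code{heteroplasmic}). Marginal totals
#' always equal the number of input sites.
#'
#' @param sites annotated site data.frame from \code{\link{annotate_sites}};
#'   for coding sites the row's region label is the gene name (feature), for
#'   non-coding sites the region class.
#' @param flags optional character vector naming logical columns of
#'   \code{sites} to count per row (e.g. \code{c("polymorphic")}).
#' @return data.frame with columns \code{mutation_type}, \code{region},
#'   \code{n}, one count column per flag (and its complement for
#'   \code{polymorphic}), \code{transition}, \code{transversion}. Total rows
#'   carry \code{region = "Total"}.
#' @export
tabulate_annotations <- function(sites, flags = intersect(c("polymorphic", "heteroplasmic"),
                                                          names(sites))) {
  if (nrow(sites) == 0L)
    return(data.frame(mutation_type = character(0), region = character(0),
                      n = integer(0), transition = integer(0),
                      transversion = integer(0)))
  lab <- ifelse(sites$mutation_type == "NC", sites$region, sites$feature)
  key <- data.frame(mutation_type = sites$mutation_type, region = lab,
                    stringsAsFactors = FALSE)
  one <- function(rows) {
    out <- data.frame(n = length(rows))
    for (f in flags) out[[f]] <- sum(sites[[f]][rows])
    out$transition <- sum(sites$substitution[rows] == "transition")
    out$transversion <- sum(sites$substitution[rows] == "transversion")
    out
  }
  groups <- split(seq_len(nrow(sites)), paste(key$mutation_type, key$region, sep = "\r"))
  body <- do.call(rbind, lapply(names(groups), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cbind(data.frame(mutation_type = parts[1], region = parts[2],
                     stringsAsFactors = FALSE), one(groups[[k]]))
  }))
  type_order <- c("NC", "NS", "S")
  body <- body[order(match(body$mutation_type, type_order), body$region), ]
  totals <- do.call(rbind, lapply(intersect(type_order, body$mutation_type), function(tp) {
    cbind(data.frame(mutation_type = tp, region = "Total", stringsAsFactors = FALSE),
          one(which(sites$mutation_type == tp)))
  }))
  grand <- cbind(data.frame(mutation_type = "All", region = "Total",
                            stringsAsFactors = FALSE), one(seq_len(nrow(sites))))
  out <- rbind(body, totals, grand)
  rownames(out) <- NULL
  out
}

#' Transition:transversion ratio
#' @param ts,tv transition and transversion counts.
#' @return ts/tv as a plain number (e.g. 149 and 29 give about 5.14).
#' @export
ts_tv_ratio <- function(ts, tv) {
  if (tv == 0) stop("no transversions: ratio undefined")
  ts / tv
}

#' Totals of a region-level site count table
#'
#' Sums a per-region count table (columns \code{n}, \code{transition},
#' \code{transversion} and any other numeric count columns) and appends the
#' transition:transversion ratio.
#'
#' @param counts data.frame of per-region counts.
#' @return Named numeric vector of column totals plus \code{ts_tv_ratio}.
#' @export
region_count_totals <- function(counts) {
  num <- vapply(counts, is.numeric, logical(1))
  tot <- colSums(counts[num])
  c(tot, ts_tv_ratio = unname(tot["transition"] / tot["transversion"]))
}
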