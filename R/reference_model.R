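#' Circular genome object
#'
#' Represents a circular DNA molecule (typically a mitochondrial genome) by
#' id, length and, optionally, its full sequence. Coordinates throughout the
#' package are 1-based inclusive, matching variant names such as
#' \code{mt.G8682A}.
#'
#' @param id genome identifier.
#' @param length genome length in bp (> 0).
#' @param sequence optional DNA string over A/C/G/T/N of exactly
#'   \code{length} characters.
#' @return An object of class \code{circular_genome}.
#' @export
circular_genome <- function(id, length, sequence = NULL) {
  length <- as.integer(length)
  stopifnot(is.character(id), length(id) == 1L, length > 0L)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence), ") != declared length (", length, ")")
    if (grepl("[^ACGTN]", sequence))
      stop("sequence contains characters outside A/C/G/T/N")
  }
  structure(list(id = id, length = length, sequence = sequence),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome>", x$id, "-", x$length, "bp,",
      if (is.null(x$sequence)) "no sequence" else "with sequence", "\n")
  invisible(x)
}

#' Read a circular genome from a FASTA file
#'
#' Reads the first record of a FASTA file into a \code{\link{circular_genome}}.
#'
#' @param path FASTA file path.
#' @param id genome id; defaults to the first word of the FASTA header.
#' @return A \code{circular_genome} with sequence.
#' @export
read_genome_fasta <- function(path, id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  if (is.null(id)) id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  circular_genome(id, Biostrings::width(ss)[1], as.character(ss[[1]]))
}

#' Genome positions covered by a (possibly origin-spanning) feature
#'
#' On a circular genome a feature with \code{end < start} wraps through the
#' origin; its positions run \code{start..L, 1..end}.
#'
#' @param start,end 1-based inclusive endpoints.
#' @param genome_length total genome length.
#' @return Integer vector of covered positions in feature order.
#' @export
feature_positions <- function(start, end, genome_length) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 1L, end >= 1L, start <= genome_length, end <= genome_length)
  if (end >= start) start:end else c(start:genome_length, 1:end)
}

REGION_CLASSES <- c("D-loop", "tRNA", "rRNA", "CDS", "intergenic")
# precedence used when features overlap (lower rank wins)
.region_rank <- c("D-loop" = 1L, "tRNA" = 2L, "rRNA" = 3L, "CDS" = 4L,
                  "intergenic" = 5L)

#' Load a genome feature annotation
#'
#' Reads a tab-separated feature table (columns \code{name}, \code{ftype},
#' \code{start}, \code{end}, \code{strand}, \code{codon_start}) describing the
#' genes of a circular genome, validates it, auto-fills unannotated gaps as
#' intergenic, and builds a per-position region index. Features with
#' \code{end < start} span the origin. Where features overlap, each position
#' is assigned one class by the precedence D-loop > tRNA > rRNA > CDS >
#' intergenic; among overlapping CDSs the one earliest in genome order wins
#' for the single-class index, but all covering CDSs are retained for effect
#' annotation.
#'
#' @param x path to a TSV file, or a data.frame with the columns above.
#' @param genome a \code{\link{circular_genome}}.
#' @return An object of class \code{genome_annotation} with elements
#'   \code{genome}, \code{features} (including auto-filled intergenic rows),
#'   \code{pos_class} and \code{pos_feature} (length-L indexes).
#' @examples
#' gen <- circular_genome("toy", 100)
#' ann <- load_annotation(data.frame(name = "g1", ftype = "CDS", start = 11,
#'   end = 40, strand = "+", codon_start = 1), gen)
#' region_length(ann)
#' @export
load_annotation <- function(x, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  feat <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else as.data.frame(x)
  required <- c("name", "ftype", "start", "end", "strand", "codon_start")
  missing_cols <- setdiff(setdiff(required, c("codon_start", "strand")), names(feat))
  if (length(missing_cols))
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(feat$codon_start)) feat$codon_start <- NA_integer_
  if (is.null(feat$strand)) feat$strand <- NA_character_
  feat$start <- as.integer(feat$start); feat$end <- as.integer(feat$end)
  L <- genome$length

  bad <- feat$start < 1L | feat$start > L | feat$end < 1L | feat$end > L
  if (any(bad))
    stop("feature coordinates out of range 1..", L, ": ",
         paste(feat$name[bad], collapse = ", "))
  if (!all(feat$ftype %in% setdiff(REGION_CLASSES, "intergenic")))
    stop("unknown ftype: ",
         paste(unique(feat$ftype[!feat$ftype %in% REGION_CLASSES]), collapse = ", "))
  cds <- feat$ftype == "CDS"
  if (any(cds & (is.na(feat$codon_start) | !feat$codon_start %in% 1:3)))
    stop("CDS features require codon_start in 1..3")
  if (any(cds & !feat$strand %in% c("+", "-")))
    stop("CDS features require strand '+' or '-'")

  pos_list <- lapply(seq_len(nrow(feat)),
                     function(i) feature_positions(feat$start[i], feat$end[i], L))
  # identical-name features must not overlap
  for (nm in unique(feat$name[duplicated(feat$name)])) {
    idx <- which(feat$name == nm)
    if (anyDuplicated(unlist(pos_list[idx])))
      stop("overlapping features share the name '", nm, "'")
  }

  cds_idx <- which(cds)[order(feat$start[cds])]
  cds_positions <- pos_list[cds_idx]
  cds_names <- feat$name[cds_idx]
  cds_features <- feat[cds_idx, , drop = FALSE]

  pos_class <- rep(NA_character_, L)
  pos_feature <- rep(NA_character_, L)
  ord <- order(.region_rank[feat$ftype], feat$start)
  for (i in ord) {
    p <- pos_list[[i]]
    free <- is.na(pos_class[p])
    pos_class[p[free]] <- feat$ftype[i]
    pos_feature[p[free]] <- feat$name[i]
  }

  # auto-fill gaps as intergenic features
  gap <- which(is.na(pos_class))
  if (length(gap)) {
    runs <- split(gap, cumsum(c(1L, diff(gap) != 1L)))
    ig <- do.call(rbind, lapply(seq_along(runs), function(k) {
      r <- runs[[k]]
      data.frame(name = sprintf("intergenic_%02d", k), ftype = "intergenic",
                 start = min(r), end = max(r), strand = NA_character_,
                 codon_start = NA_integer_, stringsAsFactors = FALSE)
    }))
    for (k in seq_along(runs)) {
      pos_class[runs[[k]]] <- "intergenic"
      pos_feature[runs[[k]]] <- ig$name[k]
    }
    feat <- rbind(feat[required], ig[required])
  } else {
    feat <- feat[required]
  }

  structure(list(genome = genome, features = feat,
                 pos_class = pos_class, pos_feature = pos_feature,
                 cds_positions = cds_positions, cds_names = cds_names,
                 cds_features = cds_features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>", x$genome$id, "-", nrow(x$features), "features,",
      x$genome$length, "bp\n")
  print(region_length(x))
  invisible(x)
}

#' Region class at genome positions
#'
#' @param pos integer vector of 1-based positions.
#' @param ann a \code{genome_annotation}.
#' @return data.frame with \code{pos}, \code{class} (D-loop/tRNA/rRNA/CDS/
#'   intergenic) and \code{feature} (winning feature name).
#' @export
region_of <- function(pos, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > ann$genome$length))
    stop("position out of range 1..", ann$genome$length)
  data.frame(pos = pos, class = ann$pos_class[pos],
             feature = ann$pos_feature[pos], stringsAsFactors = FALSE)
}

#' All CDS features covering a position
#'
#' Vertebrate mtDNA contains overlapping reading frames (e.g. ATP8/ATP6);
#' unlike \code{\link{region_of}}, which resolves to a single class, this
#' returns every CDS whose interval covers \code{pos}, in genome order.
#'
#' @param pos a single 1-based position.
#' @param ann a \code{genome_annotation}.
#' @return Character vector of CDS names (possibly empty).
#' @export
cds_at <- function(pos, ann) {
  stopifnot(inherits(ann, "genome_annotation"), length(pos) == 1L)
  hit <- vapply(ann$cds_positions, function(p) pos %in% p, logical(1))
  ann$cds_names[hit]
}

#' Total bases per region class
#'
#' Lengths are computed under the overlap precedence documented in
#' \code{\link{load_annotation}}, so they always partition the genome:
#' their sum equals the genome length.
#'
#' @param ann a \code{genome_annotation}.
#' @param class optional single class (or feature name) to return a scalar for.
#' @return Named integer vector of class lengths, or a scalar when
#'   \code{class} is given.
#' @export
region_length <- function(ann, class = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (is.null(class)) {
    tab <- table(factor(ann$pos_class, levels = REGION_CLASSES))
    return(setNames(as.integer(tab), names(tab)))
  }
  if (class %in% REGION_CLASSES) return(sum(ann$pos_class == class))
  sum(ann$pos_feature == class, na.rm = TRUE)
}

#' Codon context of a position inside a CDS
#'
#' Locates the codon containing \code{pos} in the coding orientation of the
#' CDS (reverse-complemented for minus-strand genes), honouring the feature's
#' \code{codon_start} offset, and translates it under the vertebrate
#' mitochondrial code (initiation codons at codon 1 are translated as Met).
#'
#' @param pos 1-based genome position inside the CDS.
#' @param cds one row of an annotation \code{features} table (or an
#'   equivalent list with \code{start}, \code{end}, \code{strand},
#'   \code{codon_start}).
#' @param genome a \code{circular_genome} with sequence.
#' @return List with \code{codon} (coding-strand codon), \code{within}
#'   (position of \code{pos} inside the codon, 1..3), \code{aa}, and
#'   \code{aa_index} (1-based amino-acid number from the CDS start codon).
#' @export
codon_context <- function(pos, cds, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  if (is.null(genome$sequence)) stop("genome sequence required for codon context")
  cds <- as.list(cds)
  allpos <- feature_positions(cds$start, cds$end, genome$length)
  if (identical(cds$strand, "-")) allpos <- rev(allpos)
  offset <- if (is.null(cds$codon_start) || is.na(cds$codon_start)) 1L else as.integer(cds$codon_start)
  coding <- allpos[offset:length(allpos)]
  idx <- match(as.integer(pos), coding)
  if (is.na(idx)) {
    if (pos %in% allpos) stop("position ", pos, " precedes the codon_start offset")
    stop("position ", pos, " is not inside CDS ", cds$name)
  }
  aa_index <- (idx - 1L) %/% 3L + 1L
  within <- (idx - 1L) %% 3L + 1L
  cpos <- coding[(aa_index - 1L) * 3L + 1:3]
  if (anyNA(cpos)) stop("incomplete terminal codon at CDS end")
  b <- strsplit(genome$sequence, "")[[1]][cpos]
  if (identical(cds$strand, "-")) b <- unname(COMPLEMENT[b])
  codon <- paste(b, collapse = "")
  list(codon = codon, within = within,
       aa = translate_codon(codon, as_start = aa_index == 1L),
       aa_index = aa_index, codon_positions = cpos)
}

#' Reference base at genome positions
#' @param pos integer positions.
#' @param genome a \code{circular_genome} with sequence.
#' @return Character vector of bases.
#' @export
ref_base <- function(pos, genome) {
  stopifnot(inherits(genome, "circular_genome"), !is.null(genome$sequence))
  substring(genome$sequence, pos, pos)
}

#' Packaged synthetic chicken mitochondrial reference
#'
#' Loads the synthetic stand-in chicken mtDNA reference shipped with the
#' package: a 16,775-bp circular genome with the vertebrate mitochondrial
#' gene order, a 1,227-bp D-loop at positions 1..1227, and engineered
#' landmark sites used by the worked examples (HinfI sites at the mt.G8682A
#' and mt.G16121A loci, ND2 codons 152/160 at positions 5694/5718). The
#' sequence between landmarks is random and does not reproduce the real
#' chicken reference; see the package vignette.
#'
#' @return List with \code{genome} (a \code{circular_genome}) and
#'   \code{annotation} (a \code{genome_annotation}).
#' @export
synthetic_reference <- function() {
  fa <- system.file("extdata", "synthetic_chicken_mt.fasta", package = "mitohet",
                    mustWork = TRUE)
  tsv <- system.file("extdata", "synthetic_chicken_mt_features.tsv",
                     package = "mitohet", mustWork = TRUE)
  genome <- read_genome_fasta(fa)
  list(genome = genome, annotation = load_annotation(tsv, genome))
}
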