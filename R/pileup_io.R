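BASECOUNT_COUNT_COLS <- c("A_fwd", "A_rev", "C_fwd", "C_rev",
                          "G_fwd", "G_rev", "T_fwd", "T_rev")

.empty_basecount <- function() {
  df <- data.frame(sample = character(0), chrom = character(0),
                   pos = integer(0), ref = character(0),
                   stringsAsFactors = FALSE)
  for (cc in BASECOUNT_COUNT_COLS) df[[cc]] <- integer(0)
  df$del <- integer(0); df$skipped <- integer(0); df$discarded <- integer(0)
  df$depth_used <- integer(0)
  df
}

#' Parse one line of samtools pileup text into strand-aware base counts
#'
#' Implements the samtools read-bases grammar: \code{.}/\code{,} count the
#' reference base on the forward/reverse strand; upper/lower-case letters
#' count alternative bases per strand; \code{^} consumes the following
#' mapping-quality character; \code{$} marks a read end; \code{+n}/\code{-n}
#' indel strings are consumed without affecting substitution counts (indels
#' are excluded from the substitution analysis); \code{*} is counted as a
#' deletion; \code{>}/\code{<} reference skips and \code{N}/\code{n} are
#' counted into \code{skipped}/\code{discarded} buckets that do not enter
#' \code{depth_used}.
#'
#' @param line a pileup line with at least 5 tab-separated columns
#'   (chrom, pos, ref, depth, read bases).
#' @param sample sample id attached to the record.
#' @param lineno line number used in parse-error messages.
#' @return A one-row data.frame with columns \code{sample}, \code{chrom},
#'   \code{pos}, \code{ref}, the eight strand-specific counts, \code{del},
#'   \code{skipped}, \code{discarded} and \code{depth_used}
#'   (= sum of the A/C/G/T counts).
#' @examples
#' parse_pileup_line("mt\t100\tA\t8\t....,,,,\t~~~~~~~~")
#' @export
parse_pileup_line <- function(line, sample = "sample", lineno = 1L) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 5L)
    stop("pileup line ", lineno, ": expected >= 5 columns, got ", length(fields))
  chrom <- fields[1]
  pos <- suppressWarnings(as.integer(fields[2]))
  if (is.na(pos)) stop("pileup line ", lineno, ": bad position '", fields[2], "'")
  ref <- toupper(fields[3])
  bases <- fields[5]

  counts <- setNames(integer(8), BASECOUNT_COUNT_COLS)
  del <- 0L; skipped <- 0L; discarded <- 0L
  chars <- strsplit(bases, "")[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n) stop("pileup line ", lineno, ": truncated '^' start marker")
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L)
        stop("pileup line ", lineno, ": indel marker '", ch, "' without length")
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n)
        stop("pileup line ", lineno, ": indel sequence shorter than declared length")
      i <- j + len
    } else if (ch == "*") {
      del <- del + 1L; i <- i + 1L
    } else if (ch == ">" || ch == "<") {
      skipped <- skipped + 1L; i <- i + 1L
    } else if (ch == "." || ch == ",") {
      if (ref %in% c("A", "C", "G", "T")) {
        key <- paste0(ref, if (ch == ".") "_fwd" else "_rev")
        counts[key] <- counts[key] + 1L
      } else discarded <- discarded + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% c("A", "C", "G", "T")) {
      key <- paste0(toupper(ch), if (ch %in% c("A", "C", "G", "T")) "_fwd" else "_rev")
      counts[key] <- counts[key] + 1L
      i <- i + 1L
    } else if (toupper(ch) == "N") {
      discarded <- discarded + 1L; i <- i + 1L
    } else {
      stop("pileup line ", lineno, ": unexpected character '", ch, "' in read bases")
    }
  }

  out <- data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
                    stringsAsFactors = FALSE)
  for (cc in BASECOUNT_COUNT_COLS) out[[cc]] <- counts[[cc]]
  out$del <- del; out$skipped <- skipped; out$discarded <- discarded
  out$depth_used <- sum(counts)
  out
}

#' Parse a pileup file (or text) into a base-count table
#'
#' @param path path to a samtools pileup text file, or a character vector of
#'   lines via \code{text =}.
#' @param sample sample id for all records (sample identity is file-level
#'   metadata; pileup text carries none).
#' @param text optional character vector of pileup lines instead of a file.
#' @return A base-count data.frame (one row per position); see
#'   \code{\link{parse_pileup_line}}.
#' @export
parse_pileup <- function(path = NULL, sample = "sample", text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.empty_basecount())
  do.call(rbind, lapply(seq_along(lines), function(i)
    parse_pileup_line(lines[i], sample = sample, lineno = i)))
}

#' Read / write a per-site strand-aware base-count table
#'
#' The exchange format is a TSV with header \code{sample, chrom, pos, ref,
#' A_fwd, A_rev, C_fwd, C_rev, G_fwd, G_rev, T_fwd, T_rev, del} (the
#' pileup2base-style layout). \code{depth_used} is recomputed on read as the
#' sum of the eight substitution counts, so write-then-read is the identity
#' on the stored columns.
#'
#' @param path TSV file path.
#' @return \code{read_basecount_table} returns a base-count data.frame.
#' @export
read_basecount_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample = "character", chrom = "character"))
  need <- c("sample", "chrom", "pos", "ref", BASECOUNT_COUNT_COLS, "del")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("base-count table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(.empty_basecount())
  cnt <- as.matrix(df[BASECOUNT_COUNT_COLS])
  if (any(cnt < 0) || any(df$del < 0)) stop("negative counts in base-count table")
  if (anyDuplicated(df[c("sample", "pos")]))
    stop("duplicate (sample, pos) rows in base-count table")
  df$skipped <- if (is.null(df$skipped)) 0L else df$skipped
  df$discarded <- if (is.null(df$discarded)) 0L else df$discarded
  df$depth_used <- as.integer(rowSums(cnt))
  df[c(need, "skipped", "discarded", "depth_used")]
}

#' @rdname read_basecount_table
#' @param counts a base-count data.frame.
#' @export
write_basecount_table <- function(counts, path) {
  keep <- c("sample", "chrom", "pos", "ref", BASECOUNT_COUNT_COLS, "del")
  write.table(counts[keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
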