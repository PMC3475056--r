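#' Load aligned reads from BED6 / tagAlign
#'
#' Both formats are 6-column tab-separated text: chrom, start, end, name,
#' score, strand. The name and score columns are ignored. Coordinates are
#' 0-based half-open, as in BED. Duplicate reads are kept.
#'
#' @param path Path to the reads file.
#' @param format `"bed"` or `"tagalign"` (parsed identically; kept for
#'   provenance in messages).
#' @param layout Optional [genome_layout()]; when supplied, chromosome names
#'   are validated against it and reads must lie within chromosome bounds.
#'
#' @return A data.frame of class `aligned_reads` with columns `chrom`
#'   (character), `start`, `end` (0-based half-open integers) and `strand`
#'   (`"+"` or `"-"`).
#' @export
load_reads <- function(path, format = c("bed", "tagalign"), layout = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("reads file not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(.aligned_reads(data.frame(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     stringsAsFactors = FALSE)))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 6L) {
    stop(sprintf("%s file %s has %d column(s); 6 expected (chrom, start, end, name, score, strand)",
                 format, path, ncol(dt)))
  }
  reads <- data.frame(chrom = as.character(dt[[1L]]),
                      start = suppressWarnings(as.numeric(dt[[2L]])),
                      end = suppressWarnings(as.numeric(dt[[3L]])),
                      strand = as.character(dt[[6L]]),
                      stringsAsFactors = FALSE)
  bad <- which(!is.finite(reads$start) | !is.finite(reads$end) |
                 reads$start < 0 | reads$start >= reads$end |
                 !(reads$strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("malformed %s record at line %d of %s (need 0 <= start < end and strand +/-)",
                 format, bad[1L], path))
  }
  if (!is.null(layout)) {
    len <- .chrom_lengths(layout, reads$chrom)
    over <- which(reads$end > len)
    if (length(over)) {
      stop(sprintf("read at line %d of %s extends past the end of %s",
                   over[1L], path, reads$chrom[over[1L]]))
    }
  }
  .aligned_reads(reads)
}

.aligned_reads <- function(df) {
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Shift reads to fragment-midpoint tags
#'
#' Each read is shifted towards its 3' end by `l/2` (integer floor), where
#' `l` is the average sequenced fragment length, so that tags from both
#' strands stack at the fragment midpoint. For a `+` strand read the tag
#' position is `start + floor(l/2)`; for a `-` strand read it is
#' `(end - 1) - floor(l/2)` (the 3' terminal base is `end - 1` in 0-based
#' half-open coordinates). Tags shifted past a chromosome end are clamped to
#' the terminal base so that no reads are lost.
#'
#' @param reads An `aligned_reads` data.frame (see [load_reads()]) or any
#'   data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @param l Average fragment length in bp (default 200).
#' @param layout Optional [genome_layout()] used to clamp tags into
#'   `[0, chromosome length)`; without it tags are only clamped at 0.
#'
#' @return A data.frame of class `shifted_tags` with columns `chrom`, `pos`
#'   (0-based tag coordinate) and `strand`.
#' @export
shift_reads <- function(reads, l = 200, layout = NULL) {
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
    stop("fragment length 'l' must be a positive number")
  }
  half <- floor(l / 2)
  plus <- reads$strand == "+"
  pos <- ifelse(plus, reads$start + half, (reads$end - 1) - half)
  pos <- pmax(pos, 0)
  if (!is.null(layout)) {
    len <- .chrom_lengths(layout, reads$chrom)
    pos <- pmin(pos, len - 1)
  }
  out <- data.frame(chrom = as.character(reads$chrom), pos = pos,
                    strand = as.character(reads$strand),
                    stringsAsFactors = FALSE)
  class(out) <- c("shifted_tags", "data.frame")
  out
}

.as_tags <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "pos", "strand") %in% names(x)))
  x
}

#' Write tags as tagAlign
#'
#' Tags are written as single-base records (start = pos, end = pos + 1) with
#' placeholder name `N` and score 1000, the usual tagAlign convention.
#'
#' @param tags A `shifted_tags` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tagalign <- function(tags, path) {
  tags <- .as_tags(tags)
  out <- data.frame(tags$chrom, as.integer(tags$pos), as.integer(tags$pos) + 1L,
                    "N", 1000L, tags$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
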