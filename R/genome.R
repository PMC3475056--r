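#' Genome layout
#'
#' A genome layout records the chromosome names and lengths of the reference
#' assembly that reads were aligned to. All coordinates in the package are
#' 0-based, half-open.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in base pairs
#'   (positive, same length as `chrom`).
#'
#' @return An object of class `genome_layout`: a data.frame with columns
#'   `chrom` and `length`, with attribute `G` holding the total genome
#'   length (the sum of all chromosome lengths).
#'
#' @examples
#' gl <- genome_layout(c("chrI", "chrII"), c(230218L, 813184L))
#' genome_size(gl)
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("genome layout needs at least one chromosome")
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(out, "G") <- sum(length)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Total genome length of a layout
#'
#' @param layout A [genome_layout()].
#' @return Total genome length in base pairs.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  attr(layout, "G")
}

#' Read a chrom.sizes file
#'
#' Reads the standard two-column tab-separated chromosome-sizes format
#' (name, length) as produced by e.g. `samtools faidx` post-processing or
#' UCSC `fetchChromSizes`.
#'
#' @param path Path to a chrom.sizes file.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2L) stop("chrom.sizes must have two columns (name, length): ", path)
  genome_layout(dt[[1L]], dt[[2L]])
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), G = %s bp\n",
              nrow(x), format(attr(x, "G"), big.mark = ",")))
  print(as.data.frame(x), ...)
  invisible(x)
}

# chromosome lengths looked up for a vector of names; errors on unknowns
.chrom_lengths <- function(layout, chrom) {
  idx <- match(chrom, layout$chrom)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("chromosome(s) not in genome layout: ", paste(bad, collapse = ", "))
  }
  layout$length[idx]
}
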