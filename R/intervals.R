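# Genomic intervals use the BED convention throughout: 0-based start,
# exclusive end, half-open [start, end).

#' Validate a set of genomic intervals
#'
#' @param x data.frame with at least `chrom`, `start`, `end` columns.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      stop(what, ": non-finite coordinates")
    }
    if (any(x$start < 0)) stop(what, ": negative start coordinate")
    if (any(x$start >= x$end)) {
      stop(what, ": start must be < end (half-open intervals)")
    }
  }
  invisible(x)
}

#' Reciprocal overlap fractions of two intervals
#'
#' Computes, for two half-open intervals, the fraction of each interval
#' covered by the other. Intervals on different chromosomes overlap by zero.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return numeric vector `c(frac_a, frac_b)`: fraction of `a` covered by
#'   `b`, and of `b` covered by `a`, each in `[0, 1]`.
#' @examples
#' overlap_fraction(list(chrom = "chr1", start = 100, end = 200),
#'                  list(chrom = "chr1", start = 150, end = 250))
#' @export
overlap_fraction <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  for (iv in list(a, b)) {
    if (!is.finite(iv$start) || !is.finite(iv$end) || iv$start >= iv$end ||
        iv$start < 0) {
      stop("malformed interval: require 0 <= start < end")
    }
  }
  if (!identical(as.character(a$chrom), as.character(b$chrom))) {
    return(c(0, 0))
  }
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  c(ov / (a$end - a$start), ov / (b$end - b$start))
}

#' Window centered at a binding-site summit
#'
#' Returns the half-open interval `[summit - width/2, summit + width/2)`,
#' clipped at the chromosome start (and end, when the chromosome length is
#' known). Clipping emits a warning; a summit at or beyond the chromosome
#' end is an error.
#'
#' @param summit absolute 0-based summit position.
#' @param width window width in bp; even and positive.
#' @param chrom_len optional chromosome length for right clipping.
#' @return list with `start`, `end`, and logical `clipped`.
#' @export
window_around <- function(summit, width = 100, chrom_len = NULL) {
  stopifnot(length(summit) == 1, is.finite(summit), summit >= 0)
  if (width <= 0 || width %% 2 != 0) stop("width must be even and positive")
  if (!is.null(chrom_len) && summit >= chrom_len) {
    stop("summit ", summit, " beyond chromosome end (", chrom_len, ")")
  }
  start <- summit - width / 2
  end <- summit + width / 2
  clipped <- FALSE
  if (start < 0) {
    start <- 0
    clipped <- TRUE
  }
  if (!is.null(chrom_len) && end > chrom_len) {
    end <- chrom_len
    clipped <- TRUE
  }
  if (clipped) warning("window around summit ", summit, " clipped")
  list(start = start, end = end, clipped = clipped)
}

# Vectorised, warning-free variant used internally for bulk extraction;
# returns a data.frame of clipped windows plus a `clipped` flag.
windows_around <- function(summits, width, chrom, chrom_sizes = NULL) {
  start <- summits - width / 2
  end <- summits + width / 2
  clipped <- start < 0
  start[start < 0] <- 0
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[as.character(chrom)])
    over <- !is.na(len) & end > len
    clipped <- clipped | over
    end[over] <- len[over]
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             clipped = clipped, stringsAsFactors = FALSE)
}

# data.frame of BED intervals -> GRanges (1-based closed coordinates)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
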