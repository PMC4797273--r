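# Alternative signal input: precomputed coverage (bedGraph) instead of read
# intervals. In coverage mode the windowed statistic is the base-pair-
# weighted mean coverage over the window — RPKM does not apply because
# there is no read count — and the log2(x + pseudocount) transform is
# shared with the RPKM mode.

#' Construct a coverage track
#'
#' @param feature_name label for the chromatin feature.
#' @param intervals data.frame with `chrom`, `start`, `end`, `value`
#'   (bedGraph semantics: constant coverage over each half-open interval;
#'   uncovered positions count as 0).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(feature_name, intervals) {
  validate_intervals(intervals, paste0("coverage (", feature_name, ")"))
  if (!"value" %in% names(intervals)) stop("coverage needs a value column")
  structure(list(feature_name = feature_name,
                 intervals = intervals[c("chrom", "start", "end", "value")]),
            class = "coverage_track")
}

#' Read a bedGraph coverage file
#' @param path file path (4 columns: chrom, start, end, value).
#' @param feature_name feature label.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, feature_name) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(x) < 4) stop("bedGraph needs 4 columns: ", path)
  coverage_track(feature_name,
                 data.frame(chrom = as.character(x[[1]]),
                            start = as.integer(x[[2]]),
                            end = as.integer(x[[3]]),
                            value = as.numeric(x[[4]]),
                            stringsAsFactors = FALSE))
}

#' Base-pair-weighted mean coverage over a window
#'
#' @param track a [coverage_track()].
#' @param window list with `chrom`, `start`, `end`.
#' @return mean coverage (uncovered bases contribute 0).
#' @export
mean_coverage <- function(track, window) {
  stopifnot(inherits(track, "coverage_track"))
  w <- as.list(window)
  iv <- track$intervals
  sel <- iv$chrom == as.character(w$chrom) & iv$start < w$end &
    iv$end > w$start
  if (!any(sel)) return(0)
  iv <- iv[sel, ]
  ov <- pmin(iv$end, w$end) - pmax(iv$start, w$start)
  sum(ov * iv$value) / (w$end - w$start)
}

mean_coverage_bulk <- function(track, windows) {
  iv <- track$intervals
  if (!nrow(iv)) return(numeric(nrow(windows)))
  hits <- GenomicRanges::findOverlaps(as_granges(windows), as_granges(iv))
  out <- numeric(nrow(windows))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(iv$end[si], windows$end[qi]) -
      pmax(iv$start[si], windows$start[qi])
    contrib <- tapply(ov * iv$value[si], qi, sum)
    out[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  out / (windows$end - windows$start)
}
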