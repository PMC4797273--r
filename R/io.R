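# Readers and writers for the standard plain-text formats the pipeline
# consumes: narrowPeak/BED peaks, tagAlign reads, FASTA genomes, CpG
# methylation tables, chromatin-state segmentations.

#' Read peaks from narrowPeak or plain BED
#'
#' narrowPeak is BED6+4; column 10 is the summit offset from `start`
#' (`-1` meaning unknown, in which case the interval midpoint is used).
#' Plain BED (< 10 columns) also falls back to the midpoint. Summits are
#' converted to absolute 0-based positions.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `summit` columns.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(x) < 3) stop("peak file needs at least 3 BED columns: ", path)
  out <- data.frame(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    name = if (ncol(x) >= 4) as.character(x[[4]]) else NA_character_,
    score = if (ncol(x) >= 7) as.numeric(x[[7]])
            else if (ncol(x) >= 5) as.numeric(x[[5]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (all(is.na(out$name)) || any(out$name == ".")) {
    out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  }
  if (ncol(x) >= 10) {
    off <- as.integer(x[[10]])
    mid <- out$start + (out$end - out$start) %/% 2L
    out$summit <- ifelse(off >= 0L, out$start + off, mid)
  } else {
    out$summit <- out$start + (out$end - out$start) %/% 2L
  }
  validate_peaks(out, path)
  out
}

#' Write peaks in narrowPeak format
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `summit`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  np <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name, score = 0L, strand = ".",
    signalValue = if (is.null(peaks$score)) 0 else round(peaks$score, 4),
    pValue = -1, qValue = -1,
    peak = peaks$summit - peaks$start
  )
  data.table::fwrite(np, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a read track
#'
#' A read track is a set of aligned-read intervals for one chromatin
#' feature plus the library size (total mapped reads) used as the RPKM
#' denominator; the stored reads may be a subset of the library.
#'
#' @param feature_name label, e.g. `"DNase"` or `"H3K27ac"`.
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`).
#' @param library_size total mapped reads; defaults to `nrow(reads)`.
#' @return object of class `read_track`.
#' @export
read_track <- function(feature_name, reads, library_size = nrow(reads)) {
  validate_intervals(reads, paste0("reads (", feature_name, ")"))
  if (library_size < nrow(reads)) {
    stop("library_size smaller than the number of stored reads")
  }
  if (library_size <= 0) stop("library_size must be positive")
  structure(
    list(feature_name = feature_name,
         reads = reads[c("chrom", "start", "end")],
         library_size = as.numeric(library_size)),
    class = "read_track"
  )
}

#' Read a tagAlign (BED-like) file of aligned reads
#' @param path file path.
#' @param feature_name feature label for the track.
#' @param library_size total mapped reads; defaults to the number of lines.
#' @return a [read_track()] object.
#' @export
read_tagalign <- function(path, feature_name, library_size = NULL) {
  if (!file.exists(path)) stop("tagAlign file not found: ", path)
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  reads <- data.frame(chrom = as.character(x[[1]]),
                      start = as.integer(x[[2]]),
                      end = as.integer(x[[3]]),
                      stringsAsFactors = FALSE)
  read_track(feature_name, reads,
             library_size = if (is.null(library_size)) nrow(reads)
                            else library_size)
}

#' Write a read track as tagAlign (BED6)
#' @param track a [read_track()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tagalign <- function(track, path) {
  r <- track$reads
  out <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                    name = "N", score = 1000L, strand = "+")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CpG methylation table
#'
#' Expects a TSV with header columns `chrom`, `pos` (0-based CpG position)
#' and `beta` (methylation fraction in `[0, 1]`).
#'
#' @param path file path.
#' @return data.frame with `chrom`, `pos`, `beta`.
#' @export
read_cpg_table <- function(path) {
  if (!file.exists(path)) stop("CpG table not found: ", path)
  x <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("chrom", "pos", "beta")
  if (!all(need %in% names(x))) {
    stop("CpG table must have columns chrom, pos, beta: ", path)
  }
  if (any(x$beta < 0 | x$beta > 1)) stop("beta values outside [0, 1]")
  if (anyDuplicated(x[c("chrom", "pos")])) {
    stop("duplicated CpG positions in ", path)
  }
  x[need]
}

#' Write a CpG methylation table
#' @param cpgs data.frame with `chrom`, `pos`, `beta`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(cpgs, path) {
  data.table::fwrite(cpgs[c("chrom", "pos", "beta")], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation from BED
#'
#' BED4: `chrom`, `start`, `end`, state label in the name column. Intervals
#' must not overlap within a chromosome.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `state`.
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop("segmentation file not found: ", path)
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(x) < 4) stop("segmentation BED needs 4 columns: ", path)
  seg <- data.frame(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    state = as.character(x[[4]]),
                    stringsAsFactors = FALSE)
  validate_segmentation(seg)
  seg
}

validate_segmentation <- function(seg) {
  validate_intervals(seg, "segmentation")
  if (!"state" %in% names(seg)) stop("segmentation needs a state column")
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segmentation intervals on ", ch)
    }
  }
  invisible(seg)
}

#' Write a segmentation as BED4
#' @param seg segmentation data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  data.table::fwrite(seg[c("chrom", "start", "end", "state")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
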