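# Chromatin-feature quantification at binding events: windowed read counts
# in RPKM, GC content, CpG methylation, chromatin state, and 6-kb binned
# signal profiles around summits.

#' Count reads overlapping a window
#'
#' Under the default `"overlap"` rule a read counts when it overlaps the
#' window by at least 1 bp; under the `"five_prime"` alternative it counts
#' only when its leftmost (5') base lies inside the window.
#'
#' @param track a [read_track()].
#' @param window list or one-row data.frame with `chrom`, `start`, `end`.
#' @param rule read-to-window assignment rule.
#' @return integer count.
#' @export
count_reads <- function(track, window, rule = c("overlap", "five_prime")) {
  stopifnot(inherits(track, "read_track"))
  rule <- match.arg(rule)
  w <- as.list(window)
  r <- track$reads
  if (!nrow(r)) return(0L)
  same <- r$chrom == as.character(w$chrom)
  if (rule == "overlap") {
    sum(same & r$start < w$end & r$end > w$start)
  } else {
    sum(same & r$start >= w$start & r$start < w$end)
  }
}

# Bulk variant: counts per window via interval trees.
count_reads_bulk <- function(track, windows,
                             rule = c("overlap", "five_prime")) {
  rule <- match.arg(rule)
  r <- track$reads
  if (!nrow(r)) return(integer(nrow(windows)))
  if (rule == "five_prime") {
    r <- data.frame(chrom = r$chrom, start = r$start, end = r$start + 1L)
  }
  GenomicRanges::countOverlaps(as_granges(windows), as_granges(r))
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (window_bp / 1000) / (library_size / 1e6)` — the windowed tag
#' density unit used for all signal features.
#'
#' @param count read count (vectorised).
#' @param window_bp window width in bp.
#' @param library_size total mapped reads in the library.
#' @return numeric RPKM.
#' @export
rpkm <- function(count, window_bp, library_size) {
  if (any(window_bp <= 0)) stop("window_bp must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (window_bp / 1000) / (library_size / 1e6)
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; `N` bases are excluded
#' from the denominator and an all-N sequence yields `NA`.
#'
#' @param sequence character string (or `Biostrings::DNAString`) over
#'   `ACGTN`, either case.
#' @return fraction in `[0, 1]`, or `NA` for an all-N sequence.
#' @export
gc_content <- function(sequence) {
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("illegal character in sequence (expected A/C/G/T/N)")
  }
  acgt <- sum(chars != "N")
  if (acgt == 0) return(NA_real_)
  sum(chars %in% c("G", "C")) / acgt
}

# Bulk GC over windows of a DNAStringSet genome; windows must be within
# chromosome bounds (pre-clipped).
gc_content_bulk <- function(genome, windows) {
  out <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    if (!ch %in% names(genome)) next
    v <- Biostrings::Views(genome[[ch]],
                           start = windows$start[idx] + 1L,
                           end = windows$end[idx])
    freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    gc <- freq[, "G"] + freq[, "C"]
    acgt <- gc + freq[, "A"] + freq[, "T"]
    out[idx] <- ifelse(acgt > 0, gc / acgt, NA_real_)
  }
  out
}

#' Mean CpG methylation in a window
#'
#' Arithmetic mean of beta values over CpG sites falling inside the
#' half-open window; `NA` when no CpG maps there (most binding sites carry
#' no covered CpG and are excluded from methylation-based models).
#'
#' @param cpgs CpG table (`chrom`, `pos`, `beta`), see [read_cpg_table()].
#' @param window list with `chrom`, `start`, `end`.
#' @return mean beta, or `NA` when the window contains no CpG.
#' @export
methylation_level <- function(cpgs, window) {
  w <- as.list(window)
  hit <- cpgs$chrom == as.character(w$chrom) &
    cpgs$pos >= w$start & cpgs$pos < w$end
  if (!any(hit)) return(NA_real_)
  mean(cpgs$beta[hit])
}

methylation_bulk <- function(cpgs, windows) {
  if (!nrow(cpgs)) return(rep(NA_real_, nrow(windows)))
  cg <- GenomicRanges::GRanges(cpgs$chrom,
                               IRanges::IRanges(cpgs$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(as_granges(windows), cg)
  out <- rep(NA_real_, nrow(windows))
  if (length(hits)) {
    b <- tapply(cpgs$beta[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), mean)
    out[as.integer(names(b))] <- as.numeric(b)
  }
  out
}

#' Chromatin state at a position
#'
#' Returns the state label of the segmentation interval containing the
#' position under the half-open convention (a position at an interval
#' boundary belongs to the interval that starts there); `NA` in gaps.
#'
#' @param seg segmentation data.frame (`chrom`, `start`, `end`, `state`).
#' @param chrom chromosome name.
#' @param pos 0-based position (typically a peak summit).
#' @return state label, or `NA` if the position falls in a gap.
#' @export
state_at <- function(seg, chrom, pos) {
  validate_segmentation(seg)
  hit <- seg$chrom == as.character(chrom) & seg$start <= pos & pos < seg$end
  if (!any(hit)) return(NA_character_)
  seg$state[which(hit)[1]]
}

#' One-hot encoding of a state label
#' @param state state label (or `NA`).
#' @param levels the full state alphabet.
#' @return named 0/1 vector over `levels` (all `NA` when `state` is `NA`).
#' @export
state_one_hot <- function(state, levels) {
  out <- stats::setNames(rep(0, length(levels)), paste0("state_", levels))
  if (is.na(state)) return(out + NA)
  if (!state %in% levels) stop("state '", state, "' not in alphabet")
  out[paste0("state_", state)] <- 1
  out
}

states_bulk <- function(seg, chrom, pos) {
  validate_segmentation(seg)
  sg <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1L, seg$end))
  qg <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(qg, sg, select = "first")
  ifelse(is.na(hits), NA_character_, seg$state[hits])
}

#' Build the sites-by-features matrix for one contrast side
#'
#' One row per binding event of the chosen source TF; the binary label is 1
#' for co-occupied events and 0 for solo events. Signal columns are
#' `log2(RPKM + pseudocount)` of each read track in the window centered at
#' the event summit; GC content over the same window is added when a genome
#' is supplied, mean CpG methylation when a CpG table is supplied, and a
#' one-hot chromatin-state encoding when a segmentation is supplied. When
#' methylation is included, rows without any CpG in the window are dropped
#' (they carry no methylation measurement), mirroring the restriction of
#' methylation models to CpG-bearing sites.
#'
#' @param events event table from [classify_events()].
#' @param tracks list of [read_track()] objects.
#' @param genome optional `Biostrings::DNAStringSet` for GC content.
#' @param cpgs optional CpG table for methylation.
#' @param seg optional segmentation for chromatin state.
#' @param side which TF's events form the contrast: `"A"` (co-occupied vs
#'   A-only) or `"B"`.
#' @param window_bp width of the summit-centered window (default 100).
#' @param pseudocount added inside the log2 transform (default 1).
#' @param chrom_sizes optional named vector for window clipping.
#' @param state_levels state alphabet for one-hot encoding; defaults to the
#'   sorted unique states present in `seg`.
#' @param count_rule read-to-window assignment rule, see [count_reads()].
#' @return data.frame of class `feature_matrix`: `site_id`, `label`, then
#'   one column per feature; feature names in `attr(, "feature_names")`.
#' @export
extract_features <- function(events, tracks, genome = NULL, cpgs = NULL,
                             seg = NULL, side = c("A", "B"),
                             window_bp = 100, pseudocount = 1.0,
                             chrom_sizes = NULL, state_levels = NULL,
                             count_rule = c("overlap", "five_prime")) {
  side <- match.arg(side)
  count_rule <- match.arg(count_rule)
  ev <- events[events$source_tf == side, , drop = FALSE]
  if (!nrow(ev)) stop("no events for source TF ", side)
  if (is.null(chrom_sizes) && !is.null(genome)) {
    chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))
  }
  win <- windows_around(ev$summit, window_bp, ev$chrom, chrom_sizes)
  if (any(win$clipped)) {
    message(sum(win$clipped), " window(s) clipped at chromosome edges")
  }

  out <- data.frame(site_id = ev$name,
                    label = as.integer(ev$category == "co_occupied"),
                    stringsAsFactors = FALSE)
  feat_names <- character()

  for (tr in tracks) {
    if (inherits(tr, "coverage_track")) {
      # coverage mode: windowed mean coverage, no RPKM (no read counts)
      out[[tr$feature_name]] <-
        log2(mean_coverage_bulk(tr, win) + pseudocount)
    } else {
      stopifnot(inherits(tr, "read_track"))
      counts <- count_reads_bulk(tr, win, rule = count_rule)
      out[[tr$feature_name]] <-
        log2(rpkm(counts, window_bp, tr$library_size) + pseudocount)
    }
    feat_names <- c(feat_names, tr$feature_name)
  }
  if (!is.null(genome)) {
    out$gc <- gc_content_bulk(genome, win)
    feat_names <- c(feat_names, "gc")
  }
  if (!is.null(cpgs)) {
    out$methylation <- methylation_bulk(cpgs, win)
    feat_names <- c(feat_names, "methylation")
    drop <- is.na(out$methylation)
    if (any(drop)) {
      message("dropping ", sum(drop), " site(s) without CpG coverage")
      out <- out[!drop, , drop = FALSE]
    }
  }
  if (!is.null(seg)) {
    if (is.null(state_levels)) state_levels <- sort(unique(seg$state))
    st <- states_bulk(seg, ev$chrom, ev$summit)
    if (nrow(out) < nrow(ev)) st <- st[match(out$site_id, ev$name)]
    oh <- t(vapply(st, state_one_hot, numeric(length(state_levels)),
                   levels = state_levels))
    rownames(oh) <- NULL
    out <- cbind(out, as.data.frame(oh))
    feat_names <- c(feat_names, colnames(oh))
  }
  rownames(out) <- NULL
  attr(out, "feature_names") <- feat_names
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Feature columns of a feature matrix, as a numeric matrix
#' @param fm a `feature_matrix`.
#' @param features optional subset of feature names.
#' @return numeric matrix (rows = sites).
#' @export
feature_values <- function(fm, features = NULL) {
  fn <- attr(fm, "feature_names")
  if (is.null(features)) features <- fn
  miss <- setdiff(features, fn)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  as.matrix(as.data.frame(fm)[features])
}

#' Subset the features of a feature matrix
#'
#' Named sets mirror the usual modelling contrasts: `"all"` (every feature),
#' `"dnase"`, `"hms"` (the histone-mark channels), `"gc"`, `"dnase+gc"`,
#' `"hms+gc"`, or any single feature name.
#'
#' @param fm a `feature_matrix`.
#' @param set set name or character vector of feature names.
#' @param dnase_name name of the accessibility channel (default "DNase").
#' @return a `feature_matrix` restricted to the chosen columns.
#' @export
select_feature_set <- function(fm, set = "all", dnase_name = "DNase") {
  fn <- attr(fm, "feature_names")
  hms <- setdiff(fn[!startsWith(fn, "state_")],
                 c(dnase_name, "gc", "methylation"))
  keep <- if (length(set) > 1) set
  else switch(set,
              all = fn,
              dnase = dnase_name,
              hms = hms,
              gc = "gc",
              `dnase+gc` = c(dnase_name, "gc"),
              `hms+gc` = c(hms, "gc"),
              set)
  miss <- setdiff(keep, fn)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  out <- fm[c("site_id", "label", keep)]
  attr(out, "feature_names") <- keep
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Write a feature matrix as TSV
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  data.table::fwrite(as.data.frame(fm), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV file.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  attr(out, "feature_names") <- setdiff(names(out), c("site_id", "label"))
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Binned signal profile around binding-site summits
#'
#' For each event group (source TF x category) and each bin across a span
#' centered at the summit, the mean RPKM of a read track over that group's
#' sites. Bins clipped at chromosome edges are excluded from the affected
#' site's contribution. The default 6-kb span at 100-bp resolution gives 60
#' bins with centers from -2950 to +2950 bp.
#'
#' @param events event table.
#' @param track a [read_track()].
#' @param span total profile span in bp (default 6000).
#' @param bin_bp bin width in bp (default 100); must divide `span`.
#' @param chrom_sizes optional named chromosome lengths for edge clipping.
#' @return data.frame with `feature`, `source_tf`, `category`, `offset`
#'   (bin center relative to summit), `mean_rpkm`, `n` (sites contributing).
#' @export
aggregate_profile <- function(events, track, span = 6000, bin_bp = 100,
                              chrom_sizes = NULL) {
  if (span %% bin_bp != 0) stop("span must be divisible by bin_bp")
  n_bins <- span %/% bin_bp
  offsets <- seq(-span / 2, span / 2 - bin_bp, by = bin_bp) + bin_bp / 2

  n_ev <- nrow(events)
  bin_start <- rep(events$summit, each = n_bins) +
    rep(offsets - bin_bp / 2, times = n_ev)
  bins <- data.frame(
    chrom = rep(as.character(events$chrom), each = n_bins),
    start = bin_start,
    end = bin_start + bin_bp,
    stringsAsFactors = FALSE
  )
  ok <- bins$start >= 0
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[bins$chrom])
    ok <- ok & (is.na(len) | bins$end <= len)
  }
  counts <- rep(NA_real_, nrow(bins))
  if (any(ok)) {
    counts[ok] <- count_reads_bulk(track, bins[ok, , drop = FALSE])
  }
  val <- rpkm(counts, bin_bp, track$library_size)

  grp <- paste(rep(events$source_tf, each = n_bins),
               rep(events$category, each = n_bins), sep = "|")
  off <- rep(offsets, times = n_ev)
  mean_mat <- tapply(val, list(grp, off), function(v) mean(v, na.rm = TRUE))
  n_mat <- tapply(val, list(grp, off), function(v) sum(!is.na(v)))
  parts <- strsplit(rownames(mean_mat), "|", fixed = TRUE)
  out <- data.frame(
    feature = track$feature_name,
    source_tf = rep(vapply(parts, `[`, "", 1), times = ncol(mean_mat)),
    category = rep(vapply(parts, `[`, "", 2), times = ncol(mean_mat)),
    offset = rep(as.numeric(colnames(mean_mat)), each = nrow(mean_mat)),
    mean_rpkm = as.vector(mean_mat),
    n = as.vector(n_mat),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$source_tf, out$category, out$offset), ]
  rownames(out) <- NULL
  out
}
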