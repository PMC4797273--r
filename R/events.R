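# Binding-event classification: two TFs' peak sets are partitioned into
# TF1-only, co-occupied and TF2-only events by reciprocal interval overlap.

validate_peaks <- function(peaks, what = "peaks") {
  validate_intervals(peaks, what)
  need <- c("name", "summit")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(peaks)) {
    if (anyDuplicated(peaks$name)) {
      stop(what, ": duplicated peak identifiers")
    }
    bad <- peaks$summit < peaks$start | peaks$summit >= peaks$end
    if (any(bad)) stop(what, ": summit outside [start, end) for ",
                       sum(bad), " peak(s)")
  }
  invisible(peaks)
}

# For one side (query peaks vs candidate partner peaks), return for each
# query peak the best qualifying partner index (NA if none). A partner
# qualifies when both reciprocal overlap fractions reach min_frac; the best
# partner maximises min(frac_q, frac_p), ties broken by leftmost partner
# start, then end, then input order.
best_partners <- function(query, partners, min_frac) {
  out <- rep(NA_integer_, nrow(query))
  if (!nrow(query) || !nrow(partners)) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(partners))
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], partners$end[pi]) -
    pmax(query$start[qi], partners$start[pi])
  fq <- ov / (query$end[qi] - query$start[qi])
  fp <- ov / (partners$end[pi] - partners$start[pi])
  keep <- fq >= min_frac & fp >= min_frac
  if (!any(keep)) return(out)
  qi <- qi[keep]; pi <- pi[keep]
  crit <- pmin(fq[keep], fp[keep])
  ord <- order(qi, -crit, partners$start[pi], partners$end[pi], pi)
  first <- !duplicated(qi[ord])
  out[qi[ord][first]] <- pi[ord][first]
  out
}

#' Classify two TFs' peaks into solo and co-occupied binding events
#'
#' A peak of TF A is called co-occupied when some peak of TF B covers at
#' least `min_frac` of it while it covers at least `min_frac` of that B peak
#' (reciprocal overlap), and vice versa; the default 30% threshold is the
#' standard criterion for ChIP-seq co-localization. Each co-occupied peak
#' records its single best partner: the one maximising the smaller of the
#' two overlap fractions, ties broken by leftmost partner start. A
#' co-occupied region contributes two records, one per source TF, because
#' the two TFs' summits are generally not at the same position and the two
#' sides are analysed separately.
#'
#' @param peaks_a,peaks_b data.frames with columns `chrom`, `start`, `end`,
#'   `name`, `summit` (and optionally `score`); BED half-open coordinates.
#' @param min_frac reciprocal overlap threshold in `(0, 1]`.
#' @return data.frame (the event table) with one row per input peak:
#'   `chrom`, `start`, `end`, `summit`, `name`, `score`, `source_tf`
#'   (`"A"`/`"B"`), `category` (`"A_only"`, `"co_occupied"`, `"B_only"`),
#'   `partner_name` (NA for solo events).
#' @export
classify_events <- function(peaks_a, peaks_b, min_frac = 0.30) {
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1) {
    stop("min_frac must be in (0, 1]")
  }
  validate_peaks(peaks_a, "peaks_a")
  validate_peaks(peaks_b, "peaks_b")

  pa <- best_partners(peaks_a, peaks_b, min_frac)
  pb <- best_partners(peaks_b, peaks_a, min_frac)

  one_side <- function(peaks, partner_idx, partners, tf, only_label) {
    co <- !is.na(partner_idx)
    data.frame(
      chrom = if (nrow(peaks)) as.character(peaks$chrom) else character(),
      start = peaks$start,
      end = peaks$end,
      summit = peaks$summit,
      name = if (nrow(peaks)) as.character(peaks$name) else character(),
      score = if ("score" %in% names(peaks)) peaks$score
              else rep(NA_real_, nrow(peaks)),
      source_tf = rep(tf, nrow(peaks)),
      category = ifelse(co, "co_occupied", only_label),
      partner_name = ifelse(co, as.character(partners$name)[partner_idx],
                            NA_character_),
      stringsAsFactors = FALSE
    )
  }

  out <- rbind(
    one_side(peaks_a, pa, peaks_b, "A", "A_only"),
    one_side(peaks_b, pb, peaks_a, "B", "B_only")
  )
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write an event table as TSV
#' @param events event table from [classify_events()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#' @param path TSV file.
#' @return event table data.frame.
#' @export
read_event_table <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  out$partner_name <- as.character(out$partner_name) # all-NA reads as logical
  class(out) <- c("event_table", "data.frame")
  out
}
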