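# Independent oracles and small generators shared across tests. These are
# deliberately naive (quadratic loops, direct arithmetic) and share no code
# with the implementation paths they check.

# All-pairs brute-force event classifier: for every peak of one TF, scan
# every peak of the other TF, compute both overlap fractions directly, and
# apply the same best-partner rule (max of the smaller fraction, ties by
# leftmost partner start, then end, then index).
brute_force_classify <- function(peaks_a, peaks_b, min_frac = 0.30) {
  # all pairs considered for every query peak (vectorised over partners)
  pick_partner <- function(q, partners) {
    if (!nrow(partners)) return(NA_integer_)
    ov <- pmax(0, pmin(q$end, partners$end) - pmax(q$start, partners$start))
    ov[partners$chrom != q$chrom] <- 0
    fq <- ov / (q$end - q$start)
    fp <- ov / (partners$end - partners$start)
    qual <- which(fq >= min_frac & fp >= min_frac)
    if (!length(qual)) return(NA_integer_)
    crit <- pmin(fq, fp)[qual]
    qual[order(-crit, partners$start[qual], partners$end[qual], qual)][1]
  }
  side <- function(query, partners, tf, only) {
    j <- vapply(seq_len(nrow(query)), function(i)
      pick_partner(list(chrom = query$chrom[i], start = query$start[i],
                        end = query$end[i]), partners), 0L)
    data.frame(name = query$name, source_tf = rep(tf, nrow(query)),
               category = ifelse(is.na(j), only, "co_occupied"),
               partner_name = ifelse(is.na(j), NA_character_,
                                     partners$name[ifelse(is.na(j), 1, j)]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(side(peaks_a, peaks_b, "A", "A_only"),
               side(peaks_b, peaks_a, "B", "B_only"))
  rownames(out) <- NULL
  out
}

# random peak sets on a toy genome; caller controls the RNG state
random_peaks <- function(n, prefix, chroms = c(chrA = 1e5, chrB = 8e4),
                         width_range = c(50, 500)) {
  ch <- sample(names(chroms), n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start <- vapply(seq_len(n),
                  function(i) sample.int(chroms[[ch[i]]] - w[i], 1), 0L)
  data.frame(chrom = ch, start = start, end = start + w,
             name = sprintf("%s%04d", prefix, seq_len(n)),
             score = 1, summit = start + w %/% 2,
             stringsAsFactors = FALSE)
}

# brute-force AUC: mean over all positive x negative score pairs of
# 1(pos > neg) + 1(pos == neg)/2
brute_force_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# assemble a feature_matrix from a plain numeric matrix + labels
make_fm <- function(x, labels, site_ids = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  out <- data.frame(site_id = site_ids %||%
                      sprintf("s%04d", seq_len(nrow(x))),
                    label = as.integer(labels))
  out <- cbind(out, as.data.frame(x))
  attr(out, "feature_names") <- colnames(x)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic config used repeatedly: 3 tracks, no sequence extras
quick_config <- function(n = 60, effects = c(1.5, 0, -0.5), seed = 1,
                         ...) {
  feats <- data.frame(name = paste0("f", seq_along(effects)),
                      baseline_mu = 20, log2_effect = effects,
                      dispersion = 10, stringsAsFactors = FALSE)
  synthetic_config(chrom_sizes = c(chr1 = max(2e5, n * 3 * 1400 + 2e4)),
                   n_a_only = n, n_b_only = n, n_co = n, features = feats,
                   include_sequence = FALSE, include_cpg = FALSE,
                   include_segmentation = FALSE, seed = seed, ...)
}
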