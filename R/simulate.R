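# Synthetic-data generator: complete pipeline inputs (peak sets with a
# controlled co-occupancy structure, per-feature read tracks with stated
# log2 effect sizes and negative-binomial noise, GC-biased sequence, sparse
# CpG methylation, a chromatin-state segmentation) plus the exact truth
# labels, so every stage is testable and calibratable without downloads.

#' Default chromatin-feature panel
#'
#' Twelve channels: DNase accessibility plus eleven histone marks (the
#' usual activation/repression panel including the H2A.Z variant). Defaults
#' emulate the enrichment direction seen at co-occupied sites: +1.5 log2 on
#' the six "active" channels, 0 on five, -0.5 on the repressive H3K27me3.
#'
#' @param log2_active,log2_neutral,log2_repressive effect sizes by group.
#' @param baseline_mu mean reads per 100-bp window at solo sites.
#' @param dispersion negative-binomial size parameter (`Inf` = Poisson).
#' @return data.frame with `name`, `baseline_mu`, `log2_effect`,
#'   `dispersion`.
#' @export
default_feature_panel <- function(log2_active = 1.5, log2_neutral = 0,
                                  log2_repressive = -0.5, baseline_mu = 20,
                                  dispersion = 10) {
  active <- c("DNase", "H3K27ac", "H3K4me2", "H3K4me3", "H3K9ac", "H2A.Z")
  neutral <- c("H3K4me1", "H3K79me2", "H3K36me3", "H4K20me1", "H3K9me3")
  repressive <- "H3K27me3"
  data.frame(
    name = c(active, neutral, repressive),
    baseline_mu = baseline_mu,
    log2_effect = c(rep(log2_active, length(active)),
                    rep(log2_neutral, length(neutral)),
                    log2_repressive),
    dispersion = dispersion,
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic cell
#'
#' The defaults are the study conditions used throughout the package's
#' calibration: 500 events per class, 300-bp peaks, 12 feature channels
#' with +1.5 log2 enrichment on the active marks, negative-binomial
#' dispersion 10, 36-bp reads, GC-enriched co-occupied sequence and
#' hypomethylated co-occupied CpGs.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param n_a_only,n_b_only,n_co event counts per category.
#' @param peak_width_bp peak width (both TFs).
#' @param summit_jitter_bp sd of the co-partner summit offset; offsets are
#'   clamped so the 30% reciprocal-overlap criterion always holds, keeping
#'   truth labels exact.
#' @param features feature panel, see [default_feature_panel()].
#' @param library_size RPKM denominator per track.
#' @param background_per_kb uniform background reads per kb of genome.
#' @param read_length read length in bp (36, typical of the era's tracks).
#' @param window_bp window width to which `baseline_mu` refers.
#' @param gc_background,gc_solo,gc_co G+C base probabilities.
#' @param cpg_per_kb expected CpG density.
#' @param beta_background,beta_solo,beta_co mean methylation beta by
#'   context.
#' @param n_states segmentation alphabet size (default 15).
#' @param p_active_co,p_active_solo probability that a bin holding a
#'   co-occupied (resp. solo) summit is assigned one of the low-index
#'   "active" states.
#' @param include_sequence,include_cpg,include_segmentation toggles for the
#'   non-track outputs.
#' @param seed default seed for [simulate_cell()].
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_sizes = c(chr1 = 2e6, chr2 = 1e6),
                             n_a_only = 500, n_b_only = 500, n_co = 500,
                             peak_width_bp = 300, summit_jitter_bp = 40,
                             features = default_feature_panel(),
                             library_size = 1e6, background_per_kb = 0.5,
                             read_length = 36, window_bp = 100,
                             gc_background = 0.40, gc_solo = 0.45,
                             gc_co = 0.55, cpg_per_kb = 2,
                             beta_background = 0.8, beta_solo = 0.6,
                             beta_co = 0.3, n_states = 15,
                             p_active_co = 0.8, p_active_solo = 0.3,
                             include_sequence = TRUE, include_cpg = TRUE,
                             include_segmentation = TRUE, seed = 1L) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0),
            n_a_only >= 0, n_b_only >= 0, n_co >= 0,
            peak_width_bp > 0, summit_jitter_bp >= 0,
            is.data.frame(features),
            all(c("name", "baseline_mu", "log2_effect", "dispersion")
                %in% names(features)),
            all(features$dispersion > 0), all(features$baseline_mu > 0),
            library_size > 0, read_length > 0, window_bp > 0,
            window_bp %% 2 == 0,
            gc_background > 0, gc_background < 1,
            gc_solo > 0, gc_solo < 1, gc_co > 0, gc_co < 1,
            n_states >= 2)
  n_tot <- n_a_only + n_b_only + n_co
  if (n_tot * peak_width_bp > 0.5 * sum(chrom_sizes)) {
    stop("total peak footprint exceeds 50% of the genome; ",
         "use a larger genome or fewer peaks")
  }
  structure(
    list(chrom_sizes = chrom_sizes, n_a_only = n_a_only,
         n_b_only = n_b_only, n_co = n_co, peak_width_bp = peak_width_bp,
         summit_jitter_bp = summit_jitter_bp, features = features,
         library_size = library_size, background_per_kb = background_per_kb,
         read_length = read_length, window_bp = window_bp,
         gc_background = gc_background, gc_solo = gc_solo, gc_co = gc_co,
         cpg_per_kb = cpg_per_kb, beta_background = beta_background,
         beta_solo = beta_solo, beta_co = beta_co, n_states = n_states,
         p_active_co = p_active_co, p_active_solo = p_active_solo,
         include_sequence = include_sequence, include_cpg = include_cpg,
         include_segmentation = include_segmentation,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Overdispersed count draw: negative binomial with size = dispersion;
# Poisson is the dispersion -> Inf limit.
draw_counts <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else stats::rnbinom(n, size = dispersion, mu = mu)
}

rbeta_mean <- function(n, mean, concentration = 10) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

#' Simulate one synthetic cell
#'
#' Solo peaks of both TFs are placed on disjoint slots so they share no
#' qualifying overlap; co-occupied pairs share a slot with a
#' normally-jittered, clamped summit offset guaranteeing at least 30%
#' reciprocal overlap, so the generated truth labels are exact rather than
#' probabilistic. Per-site read counts follow a negative-binomial law whose
#' expected count in the 100-bp summit window equals `baseline_mu` at solo
#' sites and `baseline_mu * 2^log2_effect` at co-occupied sites: reads are
#' scattered uniformly over a wider signal region centered on the site (so
#' the two windows of a co pair sample the same local enrichment, as they
#' would under a broad histone-mark domain) with the region total scaled by
#' the exact window capture probability; binomial thinning preserves the
#' negative-binomial dispersion. Uniform background reads, class-dependent
#' G+C composition inside event windows, Poisson-placed CpGs with
#' Beta-distributed betas, and a binned chromatin-state segmentation
#' enriched for active states at co-occupied summits complete the cell.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed`.
#' @return list of class `synthetic_cell`: `peaks_a`, `peaks_b`, `tracks`,
#'   `genome`, `cpgs`, `segmentation`, `truth` (event table), `config`,
#'   `seed`.
#' @export
simulate_cell <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  cs <- config$chrom_sizes
  pw <- config$peak_width_bp
  rl <- config$read_length
  wbp <- config$window_bp
  max_shift <- floor(0.6 * pw)

  # --- placement: one slot per event, slots spaced so only intended
  # overlaps occur even after jitter
  jitter_room <- 60
  pitch <- 2 * pw + 2 * max_shift + jitter_room + 40
  margin <- 3200 + pw # room for 6-kb profiles without edge clipping
  slot_tab <- do.call(rbind, lapply(names(cs), function(ch) {
    usable <- cs[[ch]] - 2 * margin
    k <- max(0, floor(usable / pitch))
    if (k == 0) return(NULL)
    data.frame(chrom = ch,
               base = margin + (seq_len(k) - 1) * pitch,
               stringsAsFactors = FALSE)
  }))
  n_tot <- config$n_a_only + config$n_b_only + config$n_co
  if (is.null(slot_tab) || nrow(slot_tab) < n_tot) {
    stop("cannot place ", n_tot, " events on this genome; ",
         "use a larger genome or fewer/narrower peaks")
  }
  slots <- slot_tab[sort(sample.int(nrow(slot_tab), n_tot)), ]
  slots$start <- slots$base +
    sample.int(jitter_room, n_tot, replace = TRUE) - 1L
  cat_lab <- sample(rep(c("A_only", "B_only", "co"),
                        c(config$n_a_only, config$n_b_only, config$n_co)))

  mk_peaks <- function(starts, chroms, prefix) {
    n <- length(starts)
    if (!n) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = numeric(), summit = integer(),
                        stringsAsFactors = FALSE))
    }
    data.frame(chrom = chroms, start = as.integer(starts),
               end = as.integer(starts + pw),
               name = sprintf("%s_%04d", prefix, seq_len(n)),
               score = round(stats::rgamma(n, shape = 4, rate = 0.4), 3),
               summit = as.integer(starts + pw %/% 2),
               stringsAsFactors = FALSE)
  }

  is_co <- cat_lab == "co"
  is_a <- cat_lab == "A_only"
  is_b <- cat_lab == "B_only"

  # co pairs: B partner shifted by a clamped normal offset
  d <- as.integer(pmax(-max_shift, pmin(max_shift,
    round(stats::rnorm(sum(is_co), 0, config$summit_jitter_bp)))))

  peaks_a <- mk_peaks(c(slots$start[is_a], slots$start[is_co]),
                      c(slots$chrom[is_a], slots$chrom[is_co]), "A")
  a_cat <- rep(c("A_only", "co_occupied"), c(sum(is_a), sum(is_co)))
  peaks_b <- mk_peaks(c(slots$start[is_b], slots$start[is_co] + d),
                      c(slots$chrom[is_b], slots$chrom[is_co]), "B")
  b_cat <- rep(c("B_only", "co_occupied"), c(sum(is_b), sum(is_co)))
  a_partner <- c(rep(NA_character_, sum(is_a)),
                 peaks_b$name[sum(is_b) + seq_len(sum(is_co))])
  b_partner <- c(rep(NA_character_, sum(is_b)),
                 peaks_a$name[sum(is_a) + seq_len(sum(is_co))])

  # sort each peak set by genomic position, carrying labels along
  ord_a <- order(peaks_a$chrom, peaks_a$start)
  ord_b <- order(peaks_b$chrom, peaks_b$start)
  peaks_a <- peaks_a[ord_a, ]; rownames(peaks_a) <- NULL
  peaks_b <- peaks_b[ord_b, ]; rownames(peaks_b) <- NULL
  a_cat <- a_cat[ord_a]; a_partner <- a_partner[ord_a]
  b_cat <- b_cat[ord_b]; b_partner <- b_partner[ord_b]

  truth <- rbind(
    data.frame(chrom = peaks_a$chrom, start = peaks_a$start,
               end = peaks_a$end, summit = peaks_a$summit,
               name = peaks_a$name, score = peaks_a$score,
               source_tf = rep("A", nrow(peaks_a)), category = a_cat,
               partner_name = a_partner, stringsAsFactors = FALSE),
    data.frame(chrom = peaks_b$chrom, start = peaks_b$start,
               end = peaks_b$end, summit = peaks_b$summit,
               name = peaks_b$name, score = peaks_b$score,
               source_tf = rep("B", nrow(peaks_b)), category = b_cat,
               partner_name = b_partner, stringsAsFactors = FALSE)
  )
  rownames(truth) <- NULL
  class(truth) <- c("event_table", "data.frame")

  # --- signal sites: one per solo peak, one per co pair, centred on the
  # summit (solo) or the summit midpoint (pair)
  co_a_sum <- slots$start[is_co] + pw %/% 2
  co_b_sum <- slots$start[is_co] + d + pw %/% 2
  site <- data.frame(
    chrom = c(slots$chrom[is_a], slots$chrom[is_b], slots$chrom[is_co]),
    center = c(slots$start[is_a] + pw %/% 2, slots$start[is_b] + pw %/% 2,
               as.integer(floor((co_a_sum + co_b_sum) / 2))),
    co = rep(c(FALSE, TRUE), c(sum(is_a) + sum(is_b), sum(is_co))),
    stringsAsFactors = FALSE
  )

  region_len <- max(600, 2 * (ceiling(max_shift / 2) + wbp / 2 + rl + 20))
  capture <- (wbp + rl - 1) / (region_len - rl + 1)

  tracks <- list()
  for (i in seq_len(nrow(config$features))) {
    f <- config$features[i, ]
    mu_site <- ifelse(site$co, f$baseline_mu * 2^f$log2_effect,
                      f$baseline_mu)
    n_site <- draw_counts(nrow(site), mu_site / capture, f$dispersion)
    g0 <- rep(site$center - region_len %/% 2, n_site)
    starts <- g0 + (sample.int(region_len - rl + 1,
                               sum(n_site), replace = TRUE) - 1L)
    chroms <- rep(site$chrom, n_site)
    n_bg <- round(config$background_per_kb * sum(cs) / 1000)
    if (n_bg > 0) {
      bg_ch <- sample(names(cs), n_bg, replace = TRUE,
                      prob = cs / sum(cs))
      bg_start <- floor(stats::runif(n_bg, 0, cs[bg_ch] - rl))
      chroms <- c(chroms, bg_ch)
      starts <- c(starts, as.integer(bg_start))
    }
    reads <- data.frame(chrom = chroms, start = starts,
                        end = starts + rl, stringsAsFactors = FALSE)
    reads <- reads[order(reads$chrom, reads$start), ]
    rownames(reads) <- NULL
    lib <- max(config$library_size, nrow(reads))
    tracks[[f$name]] <- read_track(f$name, reads, library_size = lib)
  }

  # event windows used for sequence / methylation class structure
  solo_win <- data.frame(
    chrom = c(slots$chrom[is_a], slots$chrom[is_b]),
    start = c(slots$start[is_a], slots$start[is_b]) + pw %/% 2 - wbp / 2,
    end = c(slots$start[is_a], slots$start[is_b]) + pw %/% 2 + wbp / 2
  )
  co_win <- data.frame(
    chrom = slots$chrom[is_co],
    start = pmin(co_a_sum, co_b_sum) - wbp / 2,
    end = pmax(co_a_sum, co_b_sum) + wbp / 2
  )

  genome <- NULL
  if (config$include_sequence) {
    bases <- c("A", "C", "G", "T")
    pr <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- lapply(names(cs), function(ch) {
      v <- sample(bases, cs[[ch]], replace = TRUE,
                  prob = pr(config$gc_background))
      for (w in list(list(df = solo_win, gc = config$gc_solo),
                     list(df = co_win, gc = config$gc_co))) {
        df <- w$df[w$df$chrom == ch, , drop = FALSE]
        for (j in seq_len(nrow(df))) {
          idx <- (df$start[j] + 1):df$end[j]
          v[idx] <- sample(bases, length(idx), replace = TRUE,
                           prob = pr(w$gc))
        }
      }
      paste(v, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(cs)
  }

  cpgs <- NULL
  if (config$include_cpg) {
    cpg_list <- lapply(names(cs), function(ch) {
      n <- stats::rpois(1, cs[[ch]] / 1000 * config$cpg_per_kb)
      if (!n) return(NULL)
      data.frame(chrom = ch, pos = sort(sample.int(cs[[ch]], n)) - 1L,
                 stringsAsFactors = FALSE)
    })
    cpgs <- do.call(rbind, cpg_list)
    if (!is.null(cpgs) && nrow(cpgs)) {
      in_win <- function(win) {
        hit <- rep(FALSE, nrow(cpgs))
        for (ch in unique(win$chrom)) {
          w <- win[win$chrom == ch, , drop = FALSE]
          sel <- which(cpgs$chrom == ch)
          if (!length(sel) || !nrow(w)) next
          iv <- IRanges::IRanges(w$start + 1L, w$end)
          qq <- IRanges::IRanges(cpgs$pos[sel] + 1L, width = 1L)
          hit[sel] <- IRanges::overlapsAny(qq, iv)
        }
        hit
      }
      in_co <- in_win(co_win)
      in_solo <- in_win(solo_win) & !in_co
      m <- ifelse(in_co, config$beta_co,
                  ifelse(in_solo, config$beta_solo,
                         config$beta_background))
      cpgs$beta <- round(rbeta_mean(nrow(cpgs), m), 4)
    }
  }

  seg <- NULL
  if (config$include_segmentation) {
    bin <- 200L
    seg_list <- lapply(names(cs), function(ch) {
      starts <- seq(0L, cs[[ch]] - 1L, by = bin)
      data.frame(chrom = ch, start = starts,
                 end = pmin(starts + bin, cs[[ch]]),
                 stringsAsFactors = FALSE)
    })
    seg <- do.call(rbind, seg_list)
    st <- sample.int(config$n_states, nrow(seg), replace = TRUE)
    n_active <- max(1L, min(4L, config$n_states - 1L))
    bins_per_chrom <- vapply(cs, function(x) length(seq(0L, x - 1L, by = bin)),
                             0)
    row_offset <- stats::setNames(cumsum(c(0, bins_per_chrom))[
      seq_along(cs)], names(cs))
    assign_active <- function(chrom, pos, p_active) {
      if (!length(pos)) return(st)
      rows <- row_offset[chrom] + pos %/% bin + 1L
      pick <- stats::runif(length(pos)) < p_active
      if (any(pick)) {
        st[rows[pick]] <- sample.int(n_active, sum(pick), replace = TRUE)
      }
      st
    }
    st <- assign_active(slots$chrom[is_co],
                        as.integer(floor((co_a_sum + co_b_sum) / 2)),
                        config$p_active_co)
    st <- assign_active(c(slots$chrom[is_a], slots$chrom[is_b]),
                        c(slots$start[is_a], slots$start[is_b]) + pw %/% 2,
                        config$p_active_solo)
    seg$state <- as.character(st)
    rownames(seg) <- NULL
  }

  structure(
    list(peaks_a = peaks_a, peaks_b = peaks_b, tracks = tracks,
         genome = genome, cpgs = cpgs, segmentation = seg, truth = truth,
         config = config, seed = as.integer(seed)),
    class = "synthetic_cell"
  )
}

#' Write a synthetic cell to disk in standard formats
#'
#' Emits two narrowPeak files, one tagAlign per feature, the genome FASTA,
#' the CpG TSV, the segmentation BED, the truth event table and a JSON
#' manifest carrying the configuration, library sizes and per-file MD5
#' checksums.
#'
#' @param cell a [simulate_cell()] result.
#' @param out_dir output directory (created if absent).
#' @return manifest list, invisibly; written as `manifest.json`.
#' @export
write_cell <- function(cell, out_dir) {
  stopifnot(inherits(cell, "synthetic_cell"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  files <- list(peaks_a = "peaks_A.narrowPeak",
                peaks_b = "peaks_B.narrowPeak",
                truth = "truth_events.tsv")
  write_narrowpeak(cell$peaks_a, p(files$peaks_a))
  write_narrowpeak(cell$peaks_b, p(files$peaks_b))
  write_event_table(cell$truth, p(files$truth))

  lib_sizes <- list()
  for (tr in cell$tracks) {
    rel <- file.path("tracks", paste0(tr$feature_name, ".tagAlign"))
    write_tagalign(tr, p(rel))
    files[[paste0("track_", tr$feature_name)]] <- rel
    lib_sizes[[tr$feature_name]] <- tr$library_size
  }
  if (!is.null(cell$genome)) {
    files$genome <- "genome.fa"
    Biostrings::writeXStringSet(cell$genome, p(files$genome))
  }
  if (!is.null(cell$cpgs)) {
    files$cpgs <- "cpg_methylation.tsv"
    write_cpg_table(cell$cpgs, p(files$cpgs))
  }
  if (!is.null(cell$segmentation)) {
    files$segmentation <- "segmentation.bed"
    write_segmentation(cell$segmentation, p(files$segmentation))
  }

  cfg <- cell$config
  cfg$features <- as.list(cfg$features)
  manifest <- list(
    format_version = 1L,
    seed = cell$seed,
    config = unclass(cfg),
    library_sizes = lib_sizes,
    files = files,
    md5 = as.list(tools::md5sum(vapply(files, p, "")))
  )
  names(manifest$md5) <- names(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a synthetic cell back from disk
#'
#' Reconstructs peaks, tracks, genome, CpG table, segmentation and truth
#' labels from the files named in `manifest.json`.
#'
#' @param dir directory written by [write_cell()].
#' @return list with the same components as [simulate_cell()] (minus the
#'   config object; the raw config values are in `manifest$config`).
#' @export
read_cell <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  p <- function(rel) file.path(dir, rel)

  tracks <- list()
  track_keys <- grep("^track_", names(mf$files), value = TRUE)
  for (k in track_keys) {
    fname <- sub("^track_", "", k)
    tracks[[fname]] <- read_tagalign(p(mf$files[[k]]), fname,
                                     library_size =
                                       mf$library_sizes[[fname]])
  }
  list(
    peaks_a = read_narrowpeak(p(mf$files$peaks_a)),
    peaks_b = read_narrowpeak(p(mf$files$peaks_b)),
    tracks = tracks,
    genome = if (!is.null(mf$files$genome)) {
      g <- Biostrings::readDNAStringSet(p(mf$files$genome))
      names(g) <- sub(" .*$", "", names(g))
      g
    },
    cpgs = if (!is.null(mf$files$cpgs)) read_cpg_table(p(mf$files$cpgs)),
    segmentation = if (!is.null(mf$files$segmentation)) {
      read_segmentation(p(mf$files$segmentation))
    },
    truth = read_event_table(p(mf$files$truth)),
    manifest = mf
  )
}
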