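# End-to-end orchestration: classify events, extract features, contrast,
# evaluate, optionally transfer to a second cell; all outputs written with
# provenance (config hash, seed, stage counts).

#' Build a pipeline configuration
#'
#' @param peaks_a,peaks_b paths to the two TFs' narrowPeak/BED files.
#' @param tracks named character vector of tagAlign paths (names = feature
#'   labels).
#' @param genome optional FASTA path (enables the GC feature).
#' @param cpgs optional CpG TSV path (enables methylation).
#' @param include_methylation add the methylation column to the modelling
#'   matrix. Off by default even when `cpgs` is given, because methylation
#'   restricts the matrix to the (typically small) CpG-bearing subset of
#'   sites; methylation-based models are usually run as a separate
#'   contrast.
#' @param segmentation optional segmentation BED path (enables state
#'   one-hot features).
#' @param library_sizes optional named vector of library sizes per track
#'   (defaults to the line counts).
#' @param side contrast side: `"A"` (co-occupied vs A-only) or `"B"`.
#' @param feature_set feature-set name, see [select_feature_set()].
#' @param classifier classifier kind, see [classifier_spec()].
#' @param min_frac reciprocal overlap threshold.
#' @param window_bp,pseudocount feature-extraction parameters.
#' @param reps,train_frac,seed evaluation settings.
#' @param out_dir output directory.
#' @param cross_cell_dir optional directory of a second cell written by
#'   [write_cell()]; when given, the trained model is also applied there.
#' @return validated list of class `run_config`; all referenced files must
#'   exist.
#' @export
run_config <- function(peaks_a, peaks_b, tracks, genome = NULL,
                       cpgs = NULL, segmentation = NULL,
                       include_methylation = FALSE,
                       library_sizes = NULL, side = "A",
                       feature_set = "all", classifier = "rbf_margin",
                       min_frac = 0.30, window_bp = 100, pseudocount = 1.0,
                       reps = 10, train_frac = 2 / 3, seed = 1L,
                       out_dir = "cooccupy_run", cross_cell_dir = NULL) {
  paths <- c(peaks_a = peaks_a, peaks_b = peaks_b, tracks,
             if (!is.null(genome)) c(genome = genome),
             if (!is.null(cpgs)) c(cpgs = cpgs),
             if (!is.null(segmentation)) c(segmentation = segmentation))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("validation: input file(s) not found: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    stop("validation: tracks must be a named vector (names = features)")
  }
  structure(
    list(peaks_a = peaks_a, peaks_b = peaks_b, tracks = tracks,
         genome = genome, cpgs = cpgs, segmentation = segmentation,
         include_methylation = include_methylation,
         library_sizes = library_sizes, side = side,
         feature_set = feature_set, classifier = classifier,
         min_frac = min_frac, window_bp = window_bp,
         pseudocount = pseudocount, reps = reps, train_frac = train_frac,
         seed = as.integer(seed), out_dir = out_dir,
         cross_cell_dir = cross_cell_dir),
    class = "run_config"
  )
}

#' Convenience: a run_config pointing at a written synthetic cell
#' @param cell_dir directory written by [write_cell()].
#' @param ... further arguments to [run_config()].
#' @return a `run_config`.
#' @export
run_config_for_cell <- function(cell_dir, ...) {
  mf <- jsonlite::read_json(file.path(cell_dir, "manifest.json"),
                            simplifyVector = TRUE)
  p <- function(rel) file.path(cell_dir, rel)
  track_keys <- grep("^track_", names(mf$files), value = TRUE)
  tracks <- stats::setNames(vapply(mf$files[track_keys], p, ""),
                            sub("^track_", "", track_keys))
  run_config(
    peaks_a = p(mf$files$peaks_a), peaks_b = p(mf$files$peaks_b),
    tracks = tracks,
    genome = if (!is.null(mf$files$genome)) p(mf$files$genome),
    cpgs = if (!is.null(mf$files$cpgs)) p(mf$files$cpgs),
    segmentation = if (!is.null(mf$files$segmentation)) {
      p(mf$files$segmentation)
    },
    library_sizes = unlist(mf$library_sizes),
    ...
  )
}

load_cell_inputs <- function(config) {
  tracks <- lapply(names(config$tracks), function(f) {
    lib <- if (!is.null(config$library_sizes) &&
               f %in% names(config$library_sizes)) {
      config$library_sizes[[f]]
    }
    read_tagalign(config$tracks[[f]], f, library_size = lib)
  })
  names(tracks) <- names(config$tracks)
  genome <- if (!is.null(config$genome)) {
    g <- Biostrings::readDNAStringSet(config$genome)
    names(g) <- sub(" .*$", "", names(g))
    g
  }
  list(
    peaks_a = read_narrowpeak(config$peaks_a),
    peaks_b = read_narrowpeak(config$peaks_b),
    tracks = tracks, genome = genome,
    cpgs = if (!is.null(config$cpgs)) read_cpg_table(config$cpgs),
    seg = if (!is.null(config$segmentation)) {
      read_segmentation(config$segmentation)
    }
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: classify binding events by reciprocal overlap, extract
#' the sites-by-features matrix for the chosen contrast side, contrast each
#' feature between classes, train and evaluate the chosen classifier with
#' repeated splits, and (when a second cell is configured) apply the model
#' trained on the full matrix to the other cell and report |dAUC|. Writes
#' `events.tsv`, `feature_matrix.tsv`, `contrasts.tsv`, `evaluation.tsv`,
#' `roc_points.tsv` and `summary.json` (with the config hash, seed and
#' per-stage counts) under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return result bundle (invisible list): `events`, `features`,
#'   `contrasts`, `evaluation`, `model`, and optionally `transfer` and
#'   `delta_auc`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[cooccupy] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  say("loading inputs")
  inp <- load_cell_inputs(config)
  say("peaks: ", nrow(inp$peaks_a), " (A), ", nrow(inp$peaks_b), " (B)")

  events <- classify_events(inp$peaks_a, inp$peaks_b, config$min_frac)
  write_event_table(events, out("events.tsv"))
  say("events: ", paste(names(table(events$category)),
                        table(events$category), sep = "=", collapse = ", "))

  fm <- extract_features(events, inp$tracks, genome = inp$genome,
                         cpgs = if (config$include_methylation) inp$cpgs,
                         seg = inp$seg,
                         side = config$side, window_bp = config$window_bp,
                         pseudocount = config$pseudocount)
  fm <- select_feature_set(fm, config$feature_set)
  write_feature_matrix(fm, out("feature_matrix.tsv"))
  say("feature matrix: ", nrow(fm), " sites x ",
      length(attr(fm, "feature_names")), " features (",
      sum(fm$label == 1), " positive)")

  contrasts <- contrast_all(fm)
  write_contrasts(contrasts, out("contrasts.tsv"))
  say("contrasts: ", sum(contrasts$p < 0.05), "/", nrow(contrasts),
      " features at p < 0.05")

  spec <- classifier_spec(config$classifier, seed = config$seed)
  ev <- evaluate_classifier(fm, spec, reps = config$reps,
                            seed = config$seed,
                            train_frac = config$train_frac,
                            feature_set = config$feature_set)
  data.table::fwrite(evaluation_table(ev), out("evaluation.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(ev$roc_points, out("roc_points.tsv"), sep = "\t",
                     quote = FALSE)
  say(sprintf("within-cell %s: mean AUC %.3f, mean ACC %.3f over %d reps",
              config$classifier, ev$mean_auc, ev$mean_acc, config$reps))

  model <- fit_classifier(spec, fm)
  bundle <- list(events = events, features = fm, contrasts = contrasts,
                 evaluation = ev, model = model)

  if (!is.null(config$cross_cell_dir)) {
    say("cross-cell transfer to ", config$cross_cell_dir)
    cfg2 <- run_config_for_cell(
      config$cross_cell_dir, side = config$side,
      feature_set = config$feature_set, classifier = config$classifier,
      out_dir = config$out_dir, seed = config$seed
    )
    inp2 <- load_cell_inputs(cfg2)
    ev2 <- classify_events(inp2$peaks_a, inp2$peaks_b, config$min_frac)
    fm2 <- extract_features(ev2, inp2$tracks, genome = inp2$genome,
                            cpgs = if (config$include_methylation) {
                              inp2$cpgs
                            },
                            seg = inp2$seg,
                            side = config$side,
                            window_bp = config$window_bp,
                            pseudocount = config$pseudocount)
    fm2 <- select_feature_set(fm2, config$feature_set)
    transfer <- cross_cell(model, fm2, test_cell = config$cross_cell_dir,
                           feature_set = config$feature_set)
    d_auc <- abs(ev$mean_auc - transfer$mean_auc)
    say(sprintf("cross-cell AUC %.3f (|dAUC| vs within-cell %.3f)",
                transfer$mean_auc, d_auc))
    bundle$transfer <- transfer
    bundle$delta_auc <- d_auc
  }

  cfg_for_hash <- config
  summary <- list(
    package_version = as.character(utils::packageVersion("cooccupy")),
    seed = config$seed,
    config = unclass(cfg_for_hash),
    config_hash = digest_config(cfg_for_hash),
    counts = list(
      peaks_a = nrow(inp$peaks_a), peaks_b = nrow(inp$peaks_b),
      events = as.list(table(events$category)),
      sites = nrow(fm), positives = sum(fm$label == 1)
    ),
    mean_auc = ev$mean_auc, mean_acc = ev$mean_acc,
    delta_auc = bundle$delta_auc
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(bundle)
}

# stable hash of a configuration (md5 of its deparsed form)
digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' One-call demonstration on bundled synthetic data
#'
#' Simulates a cell under the default study conditions (scaled by
#' `n_per_class`), writes it to disk, and runs the full pipeline on the
#' written files.
#'
#' @param out_dir output directory (cell under `cell/`, results under
#'   `run/`).
#' @param seed master seed.
#' @param n_per_class events per category (default 150 for a quick run).
#' @param classifier classifier kind.
#' @param quiet suppress stage messages.
#' @return the [run_pipeline()] bundle, invisibly.
#' @export
run_demo <- function(out_dir = tempfile("cooccupy_demo"), seed = 1L,
                     n_per_class = 150, classifier = "rbf_margin",
                     quiet = FALSE) {
  cfg <- synthetic_config(
    chrom_sizes = c(chr1 = max(6e5, ceiling(n_per_class * 3 * 1400 + 2e4))),
    n_a_only = n_per_class, n_b_only = n_per_class, n_co = n_per_class,
    seed = seed
  )
  cell <- simulate_cell(cfg, seed = seed)
  cell_dir <- file.path(out_dir, "cell")
  write_cell(cell, cell_dir)
  rc <- run_config_for_cell(cell_dir, classifier = classifier, seed = seed,
                            out_dir = file.path(out_dir, "run"))
  run_pipeline(rc, quiet = quiet)
}
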