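# Per-feature statistical contrasts between co-occupied and solo events.

#' Two-sample t contrast between event classes
#'
#' Wraps the classical two-sample t-test. The default is Welch's
#' unequal-variance form (group sizes and variances of co-occupied vs solo
#' events typically differ substantially); the pooled equal-variance
#' Student form is available via `equal_variance = TRUE`. Degenerate inputs
#' with zero variance in both groups are handled by convention: equal means
#' give `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param x,y numeric samples (positive class first); each of length >= 2.
#' @param equal_variance use the pooled-variance Student form.
#' @return list with `t`, `p`, `df`, `mean_x`, `mean_y`, `n_x`, `n_y`,
#'   `direction` (sign of `mean_x - mean_y`).
#' @export
t_contrast <- function(x, y, equal_variance = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need at least 2 finite values")
  }
  mx <- mean(x); my <- mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mx == my) {
      t <- 0; p <- 1; df <- length(x) + length(y) - 2
    } else {
      t <- sign(mx - my) * Inf; p <- 0; df <- length(x) + length(y) - 2
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = equal_variance)
    t <- unname(ht$statistic); p <- ht$p.value
    df <- unname(ht$parameter)
  }
  list(t = t, p = p, df = df, mean_x = mx, mean_y = my,
       n_x = length(x), n_y = length(y),
       direction = sign(mx - my))
}

#' Contrast every feature between the two event classes
#'
#' Runs [t_contrast()] per feature column of a feature matrix, positive
#' class (label 1, co-occupied) versus negative (label 0, solo). Missing
#' cells are excluded pairwise; features with fewer than two finite values
#' in either class are skipped with a warning. Raw p-values are reported
#' (significance is conventionally read off raw thresholds here);
#' a Benjamini-Hochberg adjusted column is added for convenience.
#'
#' @param fm a `feature_matrix` with both labels present.
#' @param equal_variance passed to [t_contrast()].
#' @return data.frame with one row per testable feature: `feature`,
#'   `n_pos`, `n_neg`, `mean_pos`, `mean_neg`, `direction`, `t`, `p`,
#'   `p_adj`.
#' @export
contrast_all <- function(fm, equal_variance = FALSE) {
  if (!all(c(0L, 1L) %in% fm$label)) {
    stop("both classes must be present to contrast co-occupied vs solo")
  }
  fn <- attr(fm, "feature_names")
  rows <- list()
  for (f in fn) {
    v <- fm[[f]]
    x <- v[fm$label == 1L]; y <- v[fm$label == 0L]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning("feature '", f, "' skipped: too few finite values in a class")
      next
    }
    ct <- t_contrast(x, y, equal_variance = equal_variance)
    rows[[f]] <- data.frame(feature = f, n_pos = ct$n_x, n_neg = ct$n_y,
                            mean_pos = ct$mean_x, mean_neg = ct$mean_y,
                            direction = ct$direction, t = ct$t, p = ct$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable features")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write contrast results as TSV
#' @param contrasts data.frame from [contrast_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(contrasts, path) {
  data.table::fwrite(contrasts, path, sep = "\t", quote = FALSE)
  invisible(path)
}
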