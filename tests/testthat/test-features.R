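track_from <- function(starts, ends, name = "t", lib = 1e6,
                       chrom = "chr1") {
  read_track(name, data.frame(chrom = rep(chrom, length(starts)),
                              start = starts, end = ends),
             library_size = lib)
}

test_that("window_around centers, clips and validates", {
  w <- window_around(500, 100)
  expect_equal(c(w$start, w$end), c(450, 550))
  expect_false(w$clipped)

  expect_warning(w <- window_around(10, 100), "clipped")
  expect_equal(c(w$start, w$end), c(0, 60))

  expect_warning(w <- window_around(500, 6000, chrom_len = 1e6), "clipped")
  expect_equal(c(w$start, w$end), c(0, 3500))

  expect_error(window_around(500, 99), "even")
  expect_error(window_around(2000, 100, chrom_len = 1500), "beyond")
})

test_that("count_reads counts >= 1 bp overlaps", {
  tr <- track_from(c(440, 560), c(476, 596))
  expect_equal(count_reads(tr, list(chrom = "chr1", start = 450,
                                    end = 550)), 1)
  # enumerate: read [440,476) overlaps [450,550); [560,596) does not
  expect_equal(count_reads(track_from(integer(), integer()),
                           list(chrom = "chr1", start = 0, end = 100)), 0)
  expect_equal(count_reads(track_from(450, 550),
                           list(chrom = "chr1", start = 450, end = 550)), 1)
  # 1-bp touch counts; abutting does not (half-open)
  expect_equal(count_reads(track_from(549, 600),
                           list(chrom = "chr1", start = 450, end = 550)), 1)
  expect_equal(count_reads(track_from(550, 600),
                           list(chrom = "chr1", start = 450, end = 550)), 0)
  # other chromosome never counts
  expect_equal(count_reads(track_from(450, 550, chrom = "chr2"),
                           list(chrom = "chr1", start = 450, end = 550)), 0)
})

test_that("the 5'-end counting rule only admits reads starting in-window", {
  # read straddles the left window edge: counts under overlap, not 5'
  tr <- track_from(c(430, 460), c(466, 496))
  w <- list(chrom = "chr1", start = 450, end = 550)
  expect_equal(count_reads(tr, w, rule = "overlap"), 2)
  expect_equal(count_reads(tr, w, rule = "five_prime"), 1)

  ev <- structure(
    data.frame(chrom = "chr1", start = 400, end = 600, summit = 500,
               name = "a1", score = 1, source_tf = "A",
               category = "co_occupied", partner_name = "b1",
               stringsAsFactors = FALSE),
    class = c("event_table", "data.frame"))
  f_ov <- extract_features(ev, list(tr), side = "A")
  f_5p <- extract_features(ev, list(tr), side = "A",
                           count_rule = "five_prime")
  expect_equal(f_ov$t, log2(rpkm(2, 100, 1e6) + 1))
  expect_equal(f_5p$t, log2(rpkm(1, 100, 1e6) + 1))
})

test_that("coverage tracks give base-pair-weighted window means", {
  cov <- coverage_track("acc", data.frame(
    chrom = "chr1", start = c(400, 500), end = c(500, 520),
    value = c(2, 10)))
  w <- list(chrom = "chr1", start = 450, end = 550)
  # 50 bp at 2, 20 bp at 10, 30 bp uncovered -> (100 + 200) / 100
  expect_equal(mean_coverage(cov, w), 3)
  expect_equal(mean_coverage(cov, list(chrom = "chr2", start = 0,
                                       end = 100)), 0)

  ev <- structure(
    data.frame(chrom = "chr1", start = 400, end = 600, summit = 500,
               name = "a1", score = 1, source_tf = "A",
               category = "A_only", partner_name = NA_character_,
               stringsAsFactors = FALSE),
    class = c("event_table", "data.frame"))
  fm <- extract_features(ev, list(cov), side = "A")
  expect_equal(fm$acc, log2(3 + 1))

  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t400\t500\t2", "chr1\t500\t520\t10"), f)
  expect_equal(mean_coverage(read_bedgraph(f, "acc"), w), 3)
})

test_that("rpkm implements count / kb / million and scales linearly", {
  expect_equal(rpkm(10, 100, 1e6), 100)
  expect_equal(rpkm(0, 100, 1e6), 0)
  expect_equal(rpkm(1, 1000, 1e6), 1)
  expect_error(rpkm(1, 0, 1e6), "window_bp")
  expect_error(rpkm(1, 100, 0), "library_size")

  set.seed(1)
  counts <- sample(0:500, 50)
  expect_equal(rpkm(2 * counts, 200, 3e6), 2 * rpkm(counts, 200, 3e6))
  expect_equal(rpkm(counts, 200, 2 * 3e6), rpkm(counts, 200, 3e6) / 2)
})

test_that("gc_content counts G+C over ACGT, N excluded, errors on junk", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_equal(gc_content("ACGTNNNN"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content("ACGU"), "illegal")

  # invariant under reverse complement
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  set.seed(2)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE),
               collapse = "")
    rc <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
    expect_equal(gc_content(s), gc_content(rc))
  }
})

test_that("methylation_level averages betas inside the window", {
  cpgs <- data.frame(chrom = "chr1", pos = c(10, 30, 200),
                     beta = c(0.2, 0.8, 0.9))
  expect_equal(methylation_level(cpgs, list(chrom = "chr1", start = 0,
                                            end = 100)), 0.5)
  expect_true(is.na(methylation_level(cpgs, list(chrom = "chr1",
                                                 start = 100, end = 150))))
  expect_equal(methylation_level(data.frame(chrom = "chr1", pos = 50,
                                            beta = 0.37),
                                 list(chrom = "chr1", start = 0,
                                      end = 100)), 0.37)
  # half-open: position at end excluded, at start included
  expect_equal(methylation_level(cpgs, list(chrom = "chr1", start = 30,
                                            end = 200)), 0.8)
})

test_that("state_at uses the half-open convention and flags overlaps", {
  seg <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                    end = c(100, 300, 400),
                    state = c("7", "2", "7"), stringsAsFactors = FALSE)
  expect_equal(state_at(seg, "chr1", 50), "7")
  expect_equal(state_at(seg, "chr1", 100), "2") # boundary -> next interval
  expect_true(is.na(state_at(seg, "chr1", 450))) # gap
  expect_true(is.na(state_at(seg, "chr2", 50)))

  oh <- state_one_hot("2", levels = c("1", "2", "7"))
  expect_equal(sum(oh), 1)
  expect_equal(unname(oh["state_2"]), 1)
  expect_error(state_one_hot("9", levels = c("1", "2")), "alphabet")

  bad <- rbind(seg, data.frame(chrom = "chr1", start = 250, end = 350,
                               state = "1"))
  expect_error(state_at(bad, "chr1", 50), "overlapping")
})

toy_events <- function() {
  # 3 A-only + 2 co-occupied A-side records at known summits
  structure(
    data.frame(
      chrom = "chr1", start = c(100, 300, 500, 700, 900),
      end = c(200, 400, 600, 800, 1000),
      summit = c(150, 350, 550, 750, 950),
      name = paste0("a", 1:5), score = 1,
      source_tf = "A",
      category = c("A_only", "A_only", "A_only", "co_occupied",
                   "co_occupied"),
      partner_name = c(NA, NA, NA, "b1", "b2"),
      stringsAsFactors = FALSE
    ),
    class = c("event_table", "data.frame")
  )
}

test_that("extract_features reproduces hand-computed log2-RPKM cells", {
  ev <- toy_events()
  # track 1: 3 reads in a1's window, 1 read in a4's window
  t1 <- track_from(c(120, 130, 140, 720), c(156, 166, 176, 756),
                   name = "m1", lib = 2e6)
  # track 2: 2 reads in a2's window only
  t2 <- track_from(c(310, 340), c(346, 376), name = "m2", lib = 5e5)
  fm <- extract_features(ev, list(t1, t2), side = "A")

  expect_equal(fm$site_id, paste0("a", 1:5))
  expect_equal(fm$label, c(0L, 0L, 0L, 1L, 1L))
  # hand arithmetic: rpkm = n / 0.1 / (lib/1e6); cell = log2(rpkm + 1)
  expect_equal(fm$m1, log2(c(3, 0, 0, 1, 0) / 0.1 / 2 + 1))
  expect_equal(fm$m2, log2(c(0, 2, 0, 0, 0) / 0.1 / 0.5 + 1))

  # zero counts with pseudocount 1 give exactly 0
  t0 <- track_from(integer(), integer(), name = "z")
  fm0 <- extract_features(ev, list(t0), side = "A")
  expect_equal(fm0$z, rep(0, 5))

  # row order is a pure function of event order
  ev_rev <- ev[5:1, ]
  class(ev_rev) <- class(ev)
  fm_rev <- extract_features(ev_rev, list(t1, t2), side = "A")
  expect_equal(fm_rev$site_id, rev(fm$site_id))
  expect_equal(fm_rev$m1, rev(fm$m1))
})

test_that("methylation columns drop CpG-free rows; states one-hot", {
  ev <- toy_events()
  t1 <- track_from(c(120), c(156), name = "m1")
  cpgs <- data.frame(chrom = "chr1", pos = c(155, 755, 760),
                     beta = c(0.4, 0.2, 0.8))
  expect_message(
    fm <- extract_features(ev, list(t1), cpgs = cpgs, side = "A"),
    "without CpG"
  )
  expect_equal(fm$site_id, c("a1", "a4"))
  expect_equal(fm$methylation, c(0.4, 0.5))

  seg <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                    end = seq(100, 1000, 100),
                    state = as.character(rep(1:2, 5)),
                    stringsAsFactors = FALSE)
  fm2 <- extract_features(ev, list(t1), seg = seg, side = "A")
  oh <- feature_values(fm2, c("state_1", "state_2"))
  expect_equal(rowSums(oh), rep(1, 5))
  # summits 150,350,... all fall in odd 100-bp bins -> state "2"
  expect_equal(unname(oh[, "state_2"]), rep(1, 5))
})

test_that("feature-set selection mirrors the modelling subsets", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("DNase", "H3K4me3", "H3K9ac", "gc")))
  fm <- make_fm(x, rep(0:1, 5))
  expect_equal(attr(select_feature_set(fm, "dnase"), "feature_names"),
               "DNase")
  expect_equal(attr(select_feature_set(fm, "hms"), "feature_names"),
               c("H3K4me3", "H3K9ac"))
  expect_equal(attr(select_feature_set(fm, "hms+gc"), "feature_names"),
               c("H3K4me3", "H3K9ac", "gc"))
  expect_equal(attr(select_feature_set(fm, "H3K9ac"), "feature_names"),
               "H3K9ac")
  expect_error(select_feature_set(fm, "H3K27ac"), "unknown")
})

test_that("aggregate_profile matches a per-site brute-force recomputation", {
  ev <- toy_events()
  set.seed(9)
  n <- 400
  st <- sample.int(1400, n)
  tr <- track_from(st, st + 36, name = "sig", lib = 1e6)

  prof <- aggregate_profile(ev, tr, span = 600, bin_bp = 100)
  expect_equal(sort(unique(prof$offset)),
               seq(-250, 250, by = 100))

  # loop-over-sites oracle using the scalar counting path; bins clipped at
  # the chromosome start carry no measurement and are left out
  for (cat in c("A_only", "co_occupied")) {
    sites <- ev[ev$category == cat, ]
    for (off in unique(prof$offset)) {
      vals <- vapply(seq_len(nrow(sites)), function(i) {
        w <- list(chrom = sites$chrom[i],
                  start = sites$summit[i] + off - 50,
                  end = sites$summit[i] + off + 50)
        if (w$start < 0) return(NA_real_)
        rpkm(count_reads(tr, w), 100, tr$library_size)
      }, 0)
      got <- prof$mean_rpkm[prof$category == cat & prof$offset == off]
      expect_equal(got, mean(vals, na.rm = TRUE))
      expect_equal(prof$n[prof$category == cat & prof$offset == off],
                   sum(!is.na(vals)))
    }
  }

  # single-site category equals that site's binned vector exactly
  one <- ev[4, ]; class(one) <- class(ev)
  p1 <- aggregate_profile(one, tr, span = 600, bin_bp = 100)
  expect_equal(p1$n, rep(1, 6))

  # all reads inside one bin -> profile nonzero only at that bin
  delta <- track_from(c(755, 760), c(770, 775), name = "d")
  pd <- aggregate_profile(one, delta, span = 600, bin_bp = 100)
  expect_gt(pd$mean_rpkm[pd$offset == 50], 0)
  expect_equal(pd$mean_rpkm[pd$offset != 50], rep(0, 5))

  # uniform coverage (a read starting at every bp) -> flat profile
  flat <- track_from(600:900, 600:900 + 1, name = "u")
  pf <- aggregate_profile(one, flat, span = 200, bin_bp = 100)
  expect_equal(length(unique(pf$mean_rpkm)), 1)

  # bins clipped at the chromosome start are excluded from that site:
  # summit 150 leaves the two leftmost 100-bp bins (< 0) without data
  near_edge <- toy_events()[1, ]; class(near_edge) <- class(toy_events())
  pe <- aggregate_profile(near_edge, tr, span = 600, bin_bp = 100)
  expect_equal(pe$n[order(pe$offset)], c(0, 0, 1, 1, 1, 1))
})
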