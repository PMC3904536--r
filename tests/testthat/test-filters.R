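run_filter <- function(blocks, f, ...) iter_collect(f(iter_from_list(blocks), ...))

test_that("subset keeps listed species and honours strict/duplicates", {
  b <- blk(hg = "ACGT", pt = "ACGT", mm = "ACGT")
  out <- run_filter(list(b), flt_subset, species = c("hg", "pt"))
  expect_equal(block_species(out[[1]]), c("hg", "pt"))

  out2 <- run_filter(list(b), flt_subset, species = c("hg", "pt"),
                     keep_others = TRUE)
  expect_equal(block_species(out2[[1]]), c("hg", "pt", "mm"))

  missing_pt <- blk(hg = "ACGT", mm = "ACGT")
  expect_length(run_filter(list(missing_pt), flt_subset,
                           species = c("hg", "pt"), strict = TRUE), 0)
  expect_length(run_filter(list(missing_pt), flt_subset,
                           species = c("hg", "pt")), 1)

  dup <- maf_block(list(maf_sequence("hg", "c", 0L, text = "ACGT"),
                        maf_sequence("hg", "c", 10L, text = "AGGT"),
                        maf_sequence("pt", "c", 0L, text = "ACGT")))
  expect_length(run_filter(list(dup), flt_subset, species = c("hg", "pt"),
                           remove_duplicates = TRUE), 0)
  kept <- run_filter(list(dup), flt_subset, species = c("hg", "pt"),
                     remove_duplicates = TRUE, keep_first = TRUE)
  expect_equal(block_species(kept[[1]]), c("hg", "pt"))
  expect_equal(kept[[1]]$sequences[[1]]$start, 0L)
})

test_that("merge joins contiguous blocks and fills genomic gaps with N", {
  mk2 <- function(start, text, strand = "+", chrom = "chr1")
    maf_block(list(maf_sequence("hg", chrom, start, strand = strand,
                                src_size = 1000, text = text)))
  a <- mk2(0L, paste(rep("A", 10), collapse = ""))
  b <- mk2(10L, paste(rep("C", 5), collapse = ""))
  out <- run_filter(list(a, b), flt_merge, species = "hg", max_dist = 0)
  expect_length(out, 1)
  s <- out[[1]]$sequences[[1]]
  expect_equal(s$start, 0L)
  expect_equal(s$size, 15L)
  expect_equal(s$text, paste0(strrep("A", 10), strrep("C", 5)))

  # gap of 3 within max_dist = 5: bridged with NNN, coordinates re-derived
  cgap <- mk2(13L, paste(rep("G", 5), collapse = ""))
  out2 <- run_filter(list(a, cgap), flt_merge, species = "hg", max_dist = 5)
  expect_length(out2, 1)
  s2 <- out2[[1]]$sequences[[1]]
  expect_equal(s2$size, 10L + 3L + 5L)
  expect_equal(s2$text, paste0(strrep("A", 10), "NNN", strrep("G", 5)))

  # too far, wrong strand, wrong chromosome: no merge
  expect_length(run_filter(list(a, mk2(20L, "TTT")), flt_merge,
                           species = "hg", max_dist = 5), 2)
  minus <- maf_block(list(maf_sequence("hg", "chr1", 10L, strand = "-",
                                       src_size = 1000, text = "CCCCC")))
  expect_length(run_filter(list(a, minus), flt_merge, species = "hg",
                           max_dist = 0), 2)
  expect_length(run_filter(list(a, mk2(10L, "CCCCC", chrom = "chr2")),
                           flt_merge, species = "hg", max_dist = 0), 2)
})

test_that("merge collapses whole syntenic runs and pads one-sided rows", {
  fx <- make_synteny_fixture(10, seed = 4)
  out <- run_filter(fx$blocks, flt_merge, species = c("spA", "spB", "spC"))
  expect_length(out, fx$ledger$n_after_merge)   # all contiguous: 1 block
  expect_equal(block_length(out[[1]]), fx$ledger$total_cols)
  # species absent from one side gets '-' padding, not an error
  b1 <- blk(hg = "AAAA", pt = "AAAA", src_size = 100)
  b2 <- maf_block(list(maf_sequence("hg", "chr1", 4L, src_size = 100,
                                    text = "CCCC")))
  out2 <- run_filter(list(b1, b2), flt_merge, species = "hg")
  expect_length(out2, 1)
  sp <- block_species(out2[[1]])
  pt_row <- out2[[1]]$sequences[[which(sp == "pt")]]
  expect_equal(pt_row$text, "AAAA----")
  expect_equal(pt_row$size, 4L)
})

test_that("concatenate appends blocks up to the target length", {
  b400 <- function() blk(a = strrep("ACGT", 100), b = strrep("ACGT", 100),
                         src_size = 10000)
  out <- run_filter(list(b400(), b400(), b400()), flt_concatenate,
                    min_length = 1000)
  expect_length(out, 1)
  expect_equal(block_length(out[[1]]), 1200L)
  expect_true(isTRUE(attr(out[[1]], "coordinateless")))

  single <- blk(a = strrep("A", 1200), b = strrep("C", 1200), src_size = 2000)
  out1 <- run_filter(list(single), flt_concatenate, min_length = 1000)
  expect_length(out1, 1)
  expect_identical(out1[[1]]$sequences, single$sequences)

  # species-set change flushes the buffer
  other <- blk(a = strrep("A", 400), c = strrep("C", 400), src_size = 1000)
  out2 <- run_filter(list(b400(), other, b400()), flt_concatenate,
                     min_length = 1000)
  expect_length(out2, 3)
})

test_that("remove_full_gap_columns deletes only all-gap ingroup columns", {
  b <- blk(in1 = "A-C", in2 = "A-C", outg = "AAC")
  out <- run_filter(list(b), flt_remove_full_gap_columns,
                    species = c("in1", "in2"))
  expect_equal(block_length(out[[1]]), 2L)
  expect_equal(out[[1]]$sequences[[3]]$text, "AC")
  expect_equal(out[[1]]$sequences[[3]]$size, 2L)  # outgroup lost a residue

  nochange <- blk(in1 = "A-C", in2 = "AGC", outg = "AAC")
  out2 <- run_filter(list(nochange), flt_remove_full_gap_columns,
                     species = c("in1", "in2"))
  expect_identical(out2[[1]], nochange)
})

test_that("no all-gap ingroup column survives the filter (scan oracle)", {
  set.seed(13)
  for (rep in 1:15) {
    b <- random_block(4, 40, gap_rate = 0.35)
    ing <- c("sp1", "sp2")
    out <- run_filter(list(b), flt_remove_full_gap_columns, species = ing)
    cm <- char_matrix(out[[1]])
    rows <- which(block_species(out[[1]]) %in% ing)
    for (k in seq_len(ncol(cm)))
      expect_false(all(cm[rows, k] == "-"))
  }
})

test_that("feature_filter excises featured regions and splits blocks", {
  text <- strrep("A", 100)
  b <- blk(hg = text, pt = text, src_size = 200)
  fs <- feature_set(list(maf_feature("hg", "chr1", 20, 40)))
  out <- run_filter(list(b), flt_feature_filter, features = fs,
                    reference_species = "hg")
  expect_length(out, 2)
  expect_equal(block_length(out[[1]]), 20L)
  expect_equal(out[[1]]$sequences[[1]]$start, 0L)
  expect_equal(block_length(out[[2]]), 60L)
  expect_equal(out[[2]]$sequences[[1]]$start, 40L)

  whole <- feature_set(list(maf_feature("hg", "chr1", 0, 100)))
  expect_length(run_filter(list(b), flt_feature_filter, features = whole,
                           reference_species = "hg"), 0)
  faraway <- feature_set(list(maf_feature("hg", "chr1", 150, 160)))
  expect_identical(run_filter(list(b), flt_feature_filter, features = faraway,
                              reference_species = "hg")[[1]], b)
})

test_that("feature_filter agrees with an interval-subtraction oracle", {
  set.seed(21)
  for (rep in 1:10) {
    L <- 80L
    b <- blk(hg = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""), src_size = 200)
    ivs <- lapply(1:3, function(i) sort(sample(0:L, 2)))
    ivs <- Filter(function(x) x[2] > x[1], ivs)
    if (length(ivs) == 0) next
    fs <- feature_set(lapply(ivs, function(x)
      maf_feature("hg", "chr1", x[1], x[2])))
    out <- run_filter(list(b), flt_feature_filter, features = fs,
                      reference_species = "hg")
    # oracle: subtract intervals from [0, L) on the (gap-free) reference
    covered <- rep(FALSE, L)
    for (x in ivs) covered[(x[1] + 1):x[2]] <- TRUE
    runs <- rle(!covered)
    exp_lens <- runs$lengths[runs$values]
    expect_equal(vapply(out, block_length, integer(1)), exp_lens)
  }
})

test_that("extract_features emits per-feature blocks with ids", {
  text <- strrep("ACGT", 25)
  b <- blk(hg = text, pt = text, src_size = 200)
  feats <- c(lapply(seq(0, 90, by = 10), function(s)
               maf_feature("hg", "chr1", s, s + 5, id = paste0("f", s))),
             list(maf_feature("hg", "chr1", 150, 160, id = "far")))
  fs <- feature_set(feats)
  out <- run_filter(list(b), flt_extract_features, features = fs,
                    reference_species = "hg")
  expect_length(out, 10)        # 10 overlap, 1 does not
  expect_equal(attr(out[[1]], "feature_id"), "f0")
  expect_equal(block_length(out[[1]]), 5L)

  # a feature hanging over the block edge is dropped with complete_only
  edge <- feature_set(list(maf_feature("hg", "chr1", 95, 110, id = "edge")))
  expect_length(run_filter(list(b), flt_extract_features, features = edge,
                           reference_species = "hg", complete_only = TRUE), 0)
  expect_length(run_filter(list(b), flt_extract_features, features = edge,
                           reference_species = "hg"), 1)
})

test_that("minus-strand features are extracted reverse-complemented", {
  b <- blk(hg = "AACCGGTTAA", src_size = 100)
  fs <- feature_set(list(maf_feature("hg", "chr1", 2, 6, strand = "-",
                                     id = "rev")))
  out <- run_filter(list(b), flt_extract_features, features = fs,
                    reference_species = "hg")
  expect_length(out, 1)
  s <- out[[1]]$sequences[[1]]
  # forward slice is CCGG (cols 3..6); reverse complement = CCGG
  expect_equal(s$text, "CCGG")
  expect_equal(s$strand, "-")
  # first emitted column corresponds to the feature's 3' reference end
  asym <- blk(hg = "AACTGGTTAA", src_size = 100)
  out2 <- run_filter(list(asym), flt_extract_features, features = fs,
                     reference_species = "hg")
  expect_equal(out2[[1]]$sequences[[1]]$text, "CCAG")  # revcomp of CTGG
  expect_equal(out2[[1]]$sequences[[1]]$start, 100L - 6L)
})

test_that("feature_filter then extract_features is empty (complementarity)", {
  fx <- make_synteny_fixture(4, block_cols = 120,
                             features = list(c(30, 60), c(200, 260)), seed = 8)
  fs <- feature_set(list(maf_feature("spA", "chr1", 30, 60),
                         maf_feature("spA", "chr1", 200, 260)))
  filtered <- flt_feature_filter(iter_from_list(fx$blocks), fs, "spA")
  residual <- iter_collect(flt_extract_features(filtered, fs, "spA"))
  expect_length(residual, 0)
})

test_that("select_chromosome and threshold filters behave inclusively", {
  b1 <- blk(hg = "ACGT", pt = "ACGT")
  b2 <- blk(hg = "ACGT", chrom = "chr2")
  expect_length(run_filter(list(b1, b2), flt_select_chromosome,
                           reference_species = "hg", chromosome = "chr1"), 1)
  expect_length(run_filter(list(blk(pt = "ACGT")), flt_select_chromosome,
                           reference_species = "hg", chromosome = "chr1"), 0)

  long <- blk(a = strrep("A", 300), src_size = 300)
  short <- blk(a = strrep("A", 299), src_size = 299)
  expect_length(run_filter(list(long, short), flt_min_block_length,
                           min_columns = 300), 1)
  expect_length(run_filter(list(b1, blk(hg = "ACGT")), flt_min_block_size,
                           min_sequences = 2), 1)
})

test_that("window_split partitions blocks per alignment mode", {
  mk <- function(L) blk(a = strrep("A", L), b = strrep("C", L), src_size = L)
  lens <- function(out) vapply(out, block_length, integer(1))

  out <- run_filter(list(mk(3500)), flt_window_split, window_size = 1000)
  expect_equal(lens(out), rep(1000L, 3))
  # left alignment drops the remainder on the right
  expect_equal(out[[1]]$sequences[[1]]$start, 0L)
  expect_equal(out[[3]]$sequences[[1]]$start, 2000L)

  out_r <- run_filter(list(mk(3500)), flt_window_split, window_size = 1000,
                      alignment = "right")
  expect_equal(out_r[[1]]$sequences[[1]]$start, 500L)
  out_c <- run_filter(list(mk(3500)), flt_window_split, window_size = 1000,
                      alignment = "center")
  expect_equal(out_c[[1]]$sequences[[1]]$start, 250L)

  two <- run_filter(list(mk(2000)), flt_window_split, window_size = 1000)
  expect_equal(lens(two), c(1000L, 1000L))
  expect_equal(paste0(two[[1]]$sequences[[1]]$text, two[[2]]$sequences[[1]]$text),
               strrep("A", 2000))

  expect_length(run_filter(list(mk(999)), flt_window_split,
                           window_size = 1000), 0)

  adj <- run_filter(list(mk(2500)), flt_window_split, window_size = 1000,
                    alignment = "adjust")
  expect_equal(sum(lens(adj)), 2500L)
  expect_equal(length(adj), 3L)
  expect_true(max(lens(adj)) - min(lens(adj)) <= 1L)
  expect_identical(run_filter(list(mk(999)), flt_window_split,
                              window_size = 1000, alignment = "adjust")[[1]],
                   mk(999))
})

test_that("gap-free blocks pass any gap predicate unchanged", {
  b <- blk(a = strrep("ACGT", 10), b = strrep("ACGT", 10), src_size = 100)
  for (pred in list(list(p = "gap_count", par = list(max_gap = 0)),
                    list(p = "gap_events", par = list(max_events = 0)))) {
    out <- run_filter(list(b), flt_sliding_window_clean, window_size = 10,
                      step = 1, predicate = pred$p, params = pred$par)
    expect_identical(out[[1]], b)
  }
})

test_that("window cleaning matches the brute-force oracle and is sound", {
  set.seed(31)
  cases <- list(
    list(p = "gap_count", par = list(max_gap = 3), gap = 0.15, mask = 0, q = FALSE),
    list(p = "gap_events", par = list(max_events = 2), gap = 0.12, mask = 0, q = FALSE),
    list(p = "entropy", par = list(entropy_threshold = 1.0, max_columns = 4),
         gap = 0.05, mask = 0, q = FALSE),
    list(p = "mask_count", par = list(max_masked = 4), gap = 0.05, mask = 0.2,
         q = FALSE),
    list(p = "quality_mean", par = list(min_quality = 4.2), gap = 0.05,
         mask = 0, q = TRUE))
  for (case in cases) {
    for (rep in 1:6) {
      win <- sample(6:12, 1); step <- sample(1:win, 1)
      b <- simulate_k80_block("((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);",
                              length = sample(40:90, 1), seed = rep * 100,
                              gap_rate = case$gap, mask_rate = case$mask,
                              quality = case$q)
      out <- run_filter(list(b), flt_sliding_window_clean, window_size = win,
                        step = step, predicate = case$p, params = case$par)
      for (frag in out) {
        expect_length(
          oracle_failing_windows(frag, win, step, case$p, case$par), 0)
      }
      # identity exactly when the oracle finds nothing to remove
      if (length(oracle_failing_windows(b, win, step, case$p, case$par)) == 0) {
        expect_length(out, 1)
        expect_identical(out[[1]], b)
      }
    }
  }
})

test_that("mask action overwrites failing windows with N", {
  b <- blk(a = "ACGTAC---TACGTACGTAC", b = "ACGTACGTATACGTACGTAC",
           src_size = 50)
  out <- run_filter(list(b), flt_sliding_window_clean, window_size = 10,
                    step = 1, predicate = "gap_count",
                    params = list(max_gap = 2), action = "mask")
  expect_length(out, 1)
  s <- out[[1]]$sequences[[2]]
  expect_equal(substr(s$text, 1, 16), strrep("N", 16))
  expect_equal(substr(s$text, 17, 20), "GTAC")
  # gaps stay gaps so sizes and starts are untouched
  expect_equal(out[[1]]$sequences[[1]]$size, b$sequences[[1]]$size)
  expect_true(grepl("---", out[[1]]$sequences[[1]]$text, fixed = TRUE))
})

test_that("quality cleaning without scores passes blocks with a warning", {
  b <- blk(a = "ACGTACGTAC", src_size = 20)
  expect_warning(
    out <- run_filter(list(b), flt_sliding_window_clean, window_size = 5,
                      step = 1, predicate = "quality_mean",
                      params = list(min_quality = 9)),
    "without quality scores")
  expect_identical(out[[1]], b)
})

test_that("filters are lazy: k outputs consume at most k + c inputs", {
  blocks <- lapply(1:200, function(i)
    blk(hg = strrep("ACGT", 5), pt = strrep("ACGT", 5), mm = strrep("ACGT", 5),
        src_size = 100))
  src <- iter_counting(iter_from_list(blocks))
  chain <- flt_min_block_length(
    flt_subset(src, c("hg", "pt")), min_columns = 10)
  got <- iter_collect(chain, n = 7)
  expect_length(got, 7)
  expect_lte(src$count(), 7 + 2)

  # a splitting filter reads fewer inputs than it emits
  src2 <- iter_counting(iter_from_list(blocks))
  ws <- flt_window_split(src2, window_size = 5)
  got2 <- iter_collect(ws, n = 9)
  expect_length(got2, 9)
  expect_lte(src2$count(), 4)
})

test_that("coordinate invariants hold after every filter (fuzz)", {
  set.seed(55)
  check_block <- function(b) {
    for (s in b$sequences) {
      expect_equal(s$size, sum(strsplit(s$text, "")[[1]] != "-"))
      expect_lte(s$start + s$size, s$src_size)
      expect_gte(s$start, 0)
    }
    invisible(TRUE)
  }
  fx <- make_synteny_fixture(6, block_cols = 90, gaps_between = c(0, 4, 0, 0, 2),
                             seed = 77)
  pipelines <- list(
    function(it) flt_merge(it, c("spA", "spB"), max_dist = 10),
    function(it) flt_window_split(it, 25),
    function(it) flt_subset(it, c("spA", "spC")),
    function(it) flt_concatenate(it, 200),
    function(it) flt_sliding_window_clean(it, 10, 5, "entropy",
      list(entropy_threshold = 0.9, max_columns = 3)))
  for (p in pipelines) {
    out <- iter_collect(p(iter_from_list(fx$blocks)))
    expect_gt(length(out), 0)
    for (b in out) check_block(b)
  }
})
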