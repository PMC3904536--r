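# Shared fixture builders. Oracles in the tests work on plain character
# matrices built here, independently of the package's raw-byte internals.

# Build a block from named gapped texts: blk(hg = "AC-GT", pt = "ACCGT")
blk <- function(..., chrom = "chr1", start = 0L, strand = "+",
                src_size = NULL, score = NULL) {
  texts <- list(...)
  seqs <- lapply(names(texts), function(sp) {
    maf_sequence(sp, chrom, start, strand = strand,
                 src_size = src_size, text = texts[[sp]])
  })
  maf_block(seqs, score = score)
}

# A random block with controllable gap/N/mask rates; returns a maf_block
# whose rows are independent random sequences (fine for column classifiers).
random_block <- function(nrow, ncol, gap_rate = 0.1, n_rate = 0.05,
                         mask_rate = 0, species = paste0("sp", seq_len(nrow))) {
  seqs <- lapply(seq_len(nrow), function(i) {
    ch <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
    r <- runif(ncol)
    ch[r < gap_rate] <- "-"
    ch[r >= gap_rate & r < gap_rate + n_rate] <- "N"
    if (mask_rate > 0) {
      lw <- runif(ncol) < mask_rate & ch != "-"
      ch[lw] <- tolower(ch[lw])
    }
    maf_sequence(species[i], "chr1", 0L, strand = "+",
                 src_size = ncol, text = paste(ch, collapse = ""))
  })
  maf_block(seqs)
}

# Character matrix view of a block (rows x columns), upper-cased copy too.
char_matrix <- function(block) {
  do.call(rbind, lapply(block$sequences, function(s)
    strsplit(s$text, "", fixed = TRUE)[[1L]]))
}

# Independent window-predicate oracle: recompute a window verdict from a
# character matrix, the slow way. Used by the cleaning-soundness tests.
oracle_window_fails <- function(cm, scores, from, win, predicate, params) {
  w <- cm[, from:(from + win - 1L), drop = FALSE]
  switch(predicate,
    gap_count = sum(w == "-") > params$max_gap,
    gap_events = {
      ev <- 0L
      for (r in seq_len(nrow(w))) {
        inside <- FALSE
        for (k in seq_len(ncol(w))) {
          if (w[r, k] == "-") {
            if (!inside) ev <- ev + 1L
            inside <- TRUE
          } else inside <- FALSE
        }
      }
      ev > params$max_events
    },
    entropy = {
      nhigh <- 0L
      for (k in seq_len(ncol(w))) {
        col <- toupper(w[, k])
        col <- col[col %in% c("A", "C", "G", "T")]
        if (length(col) == 0L) next
        p <- table(col) / length(col)
        H <- -sum(p * log2(p))
        if (H > params$entropy_threshold) nhigh <- nhigh + 1L
      }
      nhigh > params$max_columns
    },
    mask_count = sum(w %in% letters) > params$max_masked,
    quality_mean = {
      sw <- scores[, from:(from + win - 1L), drop = FALSE]
      v <- sw[sw >= 0]
      if (length(v) == 0L) FALSE else mean(v) < params$min_quality
    })
}

# All failing window start columns of a block, by brute force.
oracle_failing_windows <- function(block, win, step, predicate, params) {
  cm <- char_matrix(block)
  scores <- if (predicate == "quality_mean")
    do.call(rbind, lapply(block$sequences, function(s)
      if (is.null(s$scores)) rep(-1L, nchar(s$text)) else s$scores))
  else NULL
  L <- ncol(cm)
  if (L < win) return(integer(0))
  starts <- seq(1L, L - win + 1L, by = step)
  starts[vapply(starts, function(a)
    oracle_window_fails(cm, scores, a, win, predicate, params), logical(1))]
}
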