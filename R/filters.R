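# Streaming block filters. Every filter consumes a maf_iterator and returns
# one, so chains compose: source |> flt_subset(...) |> flt_window_split(...).

# Internal: logical keep-mask -> list of c(from, to) runs of TRUE (1-based).
keep_runs <- function(keep) {
  if (!any(keep)) return(list())
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) c(starts[i], ends[i]))
}

# Internal: excise the TRUE columns of `bad`, returning surviving fragments.
excise_columns <- function(block, bad) {
  runs <- keep_runs(!bad)
  lapply(runs, function(r) subblock(block, r[1], r[2]))
}

#' Subset a stream to a set of species
#'
#' Rows whose species is not listed are dropped unless `keep_others`. With
#' `strict`, blocks missing any listed species are discarded entirely. With
#' `remove_duplicates`, blocks where a listed species occurs more than once
#' are discarded (the safe default for downstream phylogenetics); set
#' `keep_first` to instead keep the first occurrence. Blocks left without
#' rows are dropped.
#'
#' @param source a `maf_iterator`.
#' @param species character vector of species to keep.
#' @param strict drop blocks missing a listed species.
#' @param keep_others keep rows of unlisted species.
#' @param remove_duplicates drop blocks with duplicated listed species.
#' @param keep_first resolve duplicates by keeping the first row instead.
#' @return a `maf_iterator`.
#' @export
flt_subset <- function(source, species, strict = FALSE, keep_others = FALSE,
                       remove_duplicates = FALSE, keep_first = FALSE) {
  stopifnot(length(species) > 0L)
  iter_flatmap(source, function(b) {
    sp <- block_species(b)
    if (strict && !all(species %in% sp)) return(list())
    counts <- table(sp[sp %in% species])
    if (any(counts > 1L)) {
      if (remove_duplicates && !keep_first) return(list())
    }
    keep <- sp %in% species
    if (keep_first) {
      listed_dup <- keep & duplicated(sp)
      keep <- keep & !listed_dup
    }
    if (keep_others) keep <- keep | !(sp %in% species)
    if (!any(keep)) return(list())
    list(maf_block(b$sequences[keep], score = b$score, tree = b$tree))
  })
}

# Internal: test whether two consecutive blocks are syntenic for all focal
# species; returns per-species gap distances or NULL.
merge_distances <- function(prev, nxt, species, max_dist) {
  dists <- integer(0)
  for (s in species) {
    ip <- which(block_species(prev) == s)
    inx <- which(block_species(nxt) == s)
    if (length(ip) != 1L || length(inx) != 1L) return(NULL)
    a <- prev$sequences[[ip]]; b <- nxt$sequences[[inx]]
    if (!identical(a$chromosome, b$chromosome) ||
        !identical(a$strand, b$strand)) return(NULL)
    d <- b$start - (a$start + a$size)
    if (d < 0L || d > max_dist) return(NULL)
    dists[s] <- d
  }
  dists
}

# Internal: merge two syntenic blocks. Focal rows are joined with 'N' runs
# covering their genomic gap; non-focal rows present on both sides with
# compatible coordinates are joined with '-' fill; one-sided rows are
# '-'-padded. Inserted columns are grouped per focal species.
merge_two_blocks <- function(prev, nxt, species, dists) {
  Lp <- block_length(prev); Ln <- block_length(nxt)
  # one inserted segment per distinct positive gap distance; focal species
  # sharing a distance share the segment (the common case: one segment of
  # N columns when all focal rows are equally far apart)
  udists <- sort(unique(dists[dists > 0L]))
  ins_len <- sum(udists)
  seg_off <- stats::setNames(c(0L, cumsum(udists))[seq_along(udists)],
                             as.character(udists))

  spp <- block_species(prev); spn <- block_species(nxt)
  used_n <- rep(FALSE, length(spn))
  seqs <- list()
  for (i in seq_along(prev$sequences)) {
    a <- prev$sequences[[i]]
    s <- spp[i]
    j <- which(spn == s & !used_n)
    joined <- FALSE
    if (length(j) >= 1L) {
      j <- j[1L]
      b <- nxt$sequences[[j]]
      focal <- s %in% species
      compatible <- identical(a$chromosome, b$chromosome) &&
        identical(a$strand, b$strand) && b$start >= a$start + a$size
      if (focal || compatible) {
        used_n[j] <- TRUE
        insert <- rep("-", ins_len)
        d <- if (focal) dists[[s]] else 0L
        if (focal && d > 0L) {
          o <- seg_off[[as.character(d)]]
          insert[(o + 1L):(o + d)] <- "N"
        }
        text <- paste0(a$text, paste(insert, collapse = ""), b$text)
        scores <- if (!is.null(a$scores) && !is.null(b$scores))
          c(a$scores, rep(-1L, ins_len), b$scores) else NULL
        size <- a$size + (if (focal) d else 0L) + b$size
        seqs[[length(seqs) + 1L]] <- maf_sequence(
          s, a$chromosome, a$start, size, a$strand,
          max(a$src_size, b$src_size),
          text, scores)
        joined <- TRUE
      }
    }
    if (!joined) {
      pad <- paste(rep("-", ins_len + Ln), collapse = "")
      seqs[[length(seqs) + 1L]] <- maf_sequence(
        s, a$chromosome, a$start, a$size, a$strand, a$src_size,
        paste0(a$text, pad),
        if (!is.null(a$scores)) c(a$scores, rep(-1L, ins_len + Ln)) else NULL)
    }
  }
  for (j in which(!used_n)) {
    b <- nxt$sequences[[j]]
    pad <- paste(rep("-", Lp + ins_len), collapse = "")
    seqs[[length(seqs) + 1L]] <- maf_sequence(
      b$species, b$chromosome, b$start, b$size, b$strand, b$src_size,
      paste0(pad, b$text),
      if (!is.null(b$scores)) c(rep(-1L, Lp + ins_len), b$scores) else NULL)
  }
  maf_block(seqs)
}

#' Merge consecutive syntenic blocks
#'
#' Two consecutive blocks merge when every listed species occurs exactly
#' once in both, on the same chromosome and strand, with a non-negative
#' genomic gap of at most `max_dist` between them. The gap is filled with
#' `N` in the focal rows (unknown sequence, not deletion). Merging is
#' greedy left to right, so runs of syntenic blocks collapse into one.
#'
#' @param source a `maf_iterator`.
#' @param species focal species that must be syntenic.
#' @param max_dist maximum genomic distance bridged (default 0: contiguity).
#' @return a `maf_iterator`.
#' @export
flt_merge <- function(source, species, max_dist = 0L) {
  force(source)
  cur <- NULL
  done <- FALSE
  block_iterator(function() {
    if (done) return(NULL)
    if (is.null(cur)) {
      cur <<- iter_next(source)
      if (is.null(cur)) { done <<- TRUE; return(NULL) }
    }
    repeat {
      nb <- iter_next(source)
      if (is.null(nb)) {
        done <<- TRUE
        out <- cur; cur <<- NULL
        return(out)
      }
      d <- merge_distances(cur, nb, species, max_dist)
      if (is.null(d)) {
        out <- cur; cur <<- nb
        return(out)
      }
      cur <<- merge_two_blocks(cur, nb, species, d)
    }
  }, close = function() iter_close(source))
}

# Internal: concatenate a buffered run of blocks sharing a species multiset.
concat_blocks <- function(buf) {
  if (length(buf) == 1L) {
    b <- buf[[1L]]
    return(b)
  }
  first <- buf[[1L]]
  sp1 <- block_species(first)
  seqs <- first$sequences
  for (k in 2L:length(buf)) {
    b <- buf[[k]]
    spk <- block_species(b)
    used <- rep(FALSE, length(spk))
    for (i in seq_along(seqs)) {
      j <- which(spk == sp1[i] & !used)[1L]
      used[j] <- TRUE
      a <- seqs[[i]]; x <- b$sequences[[j]]
      text <- paste0(a$text, x$text)
      size <- a$size + x$size
      seqs[[i]] <- maf_sequence(a$species, a$chromosome, a$start, size,
                                a$strand, max(a$src_size, a$start + size),
                                text,
                                if (!is.null(a$scores) && !is.null(x$scores))
                                  c(a$scores, x$scores) else NULL)
    }
  }
  out <- maf_block(seqs)
  attr(out, "coordinateless") <- TRUE
  out
}

#' Concatenate consecutive blocks regardless of coordinates
#'
#' Blocks are appended species-wise until the running alignment length
#' reaches `min_length`, then emitted. A change in the species multiset
#' flushes the buffer first. Concatenated rows keep the first block's
#' coordinates with sizes recounted; the resulting blocks are flagged with
#' attribute `coordinateless = TRUE` since their coordinates no longer
#' describe a contiguous region.
#'
#' @param source a `maf_iterator`.
#' @param min_length emit once the concatenated length reaches this.
#' @return a `maf_iterator`.
#' @export
flt_concatenate <- function(source, min_length) {
  buf <- list()
  key <- NULL
  take <- function() {
    out <- concat_blocks(buf)
    buf <<- list(); key <<- NULL
    out
  }
  iter_flatmap(source, function(b) {
    k <- paste(sort(block_species(b)), collapse = "\r")
    out <- list()
    if (length(buf) > 0L && !identical(k, key)) out <- c(out, list(take()))
    buf[[length(buf) + 1L]] <<- b
    key <<- k
    total <- sum(vapply(buf, block_length, integer(1)))
    if (total >= min_length) out <- c(out, list(take()))
    out
  }, flush = function() if (length(buf) > 0L) list(take()) else list())
}

#' Remove columns gapped in an entire ingroup
#'
#' Deletes every column in which all rows of the listed species carry a
#' gap. Other rows may lose residues in such columns: their sizes are
#' recounted and their start coordinates left untouched (so coordinates of
#' non-ingroup rows become approximate, as documented).
#'
#' @param source a `maf_iterator`.
#' @param species the ingroup species.
#' @return a `maf_iterator`.
#' @export
flt_remove_full_gap_columns <- function(source, species) {
  iter_flatmap(source, function(b) {
    idx <- which(block_species(b) %in% species)
    if (length(idx) == 0L || block_length(b) == 0L) return(list(b))
    m <- block_matrix(b)[idx, , drop = FALSE]
    bad <- apply(m == GAP_RAW, 2L, all)
    if (!any(bad)) return(list(b))
    list(subblock_columns(b, !bad, advance_start = FALSE))
  })
}

# Internal: map a forward-strand interval [fs, fe) to the (1-based,
# inclusive) alignment column range it occupies in `ref`; NULL when empty.
fwd_interval_to_columns <- function(ref, fs, fe) {
  coord <- column_coordinates(ref)                  # strand-relative
  if (ref$strand == "+") {
    hit <- !is.na(coord) & coord >= fs & coord < fe
  } else {
    lo <- ref$src_size - fe; hi <- ref$src_size - fs  # [lo, hi)
    hit <- !is.na(coord) & coord >= lo & coord < hi
  }
  if (!any(hit)) return(NULL)
  c(min(which(hit)), max(which(hit)))
}

#' Remove featured regions from a stream
#'
#' Forward-strand intervals of the reference row that overlap any feature
#' are mapped back to alignment columns, excised, and each surviving
#' fragment is emitted as its own block. Blocks lacking the reference
#' species pass unmodified with a warning.
#'
#' @param source a `maf_iterator`.
#' @param features a [feature_set()].
#' @param reference_species species whose coordinates features refer to.
#' @return a `maf_iterator`.
#' @export
flt_feature_filter <- function(source, features, reference_species) {
  iter_flatmap(source, function(b) {
    i <- which(block_species(b) == reference_species)[1L]
    if (is.na(i)) {
      warning("feature_filter: block without reference species '",
              reference_species, "' passed unmodified")
      return(list(b))
    }
    ref <- b$sequences[[i]]
    iv <- to_plus_strand_interval(ref)
    feats <- features_for(features, reference_species, ref$chromosome)
    bad <- rep(FALSE, block_length(b))
    for (f in feats) {
      fs <- max(f$start, iv$start); fe <- min(f$end, iv$end)
      if (fs >= fe) next
      rng <- fwd_interval_to_columns(ref, fs, fe)
      if (!is.null(rng)) bad[rng[1]:rng[2]] <- TRUE
    }
    if (!any(bad)) return(list(b))
    excise_columns(b, bad)
  })
}

# Internal: reverse-complement every row of a block (minus-strand feature
# extraction). Strands flip and starts are re-derived on the new strand.
revcomp_block <- function(block) {
  seqs <- lapply(block$sequences, function(s) {
    maf_sequence(s$species, s$chromosome,
                 as.integer(s$src_size - s$start - s$size), s$size,
                 if (s$strand == "+") "-" else "+", s$src_size,
                 revcomp_text(s$text),
                 if (!is.null(s$scores)) rev(s$scores) else NULL)
  })
  maf_block(seqs)
}

#' Extract featured regions from a stream
#'
#' Emits one block per (block, overlapping feature) intersection, carrying
#' the feature id in attribute `feature_id`. With `complete_only`, only
#' features entirely contained in the block's reference interval are
#' emitted. Minus-strand features cause reverse-complementation of all
#' rows, so the extracted block reads in the feature's orientation.
#'
#' @inheritParams flt_feature_filter
#' @param complete_only require the full feature inside the block.
#' @return a `maf_iterator`.
#' @export
flt_extract_features <- function(source, features, reference_species,
                                 complete_only = FALSE) {
  iter_flatmap(source, function(b) {
    i <- which(block_species(b) == reference_species)[1L]
    if (is.na(i)) {
      warning("extract_features: block without reference species '",
              reference_species, "' skipped")
      return(list())
    }
    ref <- b$sequences[[i]]
    iv <- to_plus_strand_interval(ref)
    feats <- features_for(features, reference_species, ref$chromosome)
    out <- list()
    for (f in feats) {
      if (complete_only && !(f$start >= iv$start && f$end <= iv$end)) next
      fs <- max(f$start, iv$start); fe <- min(f$end, iv$end)
      if (fs >= fe) next
      rng <- fwd_interval_to_columns(ref, fs, fe)
      if (is.null(rng)) next
      sub <- subblock(b, rng[1], rng[2])
      if (identical(f$strand, "-")) sub <- revcomp_block(sub)
      attr(sub, "feature_id") <- f$id
      out[[length(out) + 1L]] <- sub
    }
    out
  })
}

#' Keep blocks from one chromosome of a reference species
#' @inheritParams flt_feature_filter
#' @param chromosome chromosome name (exact match).
#' @return a `maf_iterator`.
#' @export
flt_select_chromosome <- function(source, reference_species, chromosome) {
  iter_flatmap(source, function(b) {
    i <- which(block_species(b) == reference_species)[1L]
    if (is.na(i)) return(list())
    if (identical(b$sequences[[i]]$chromosome, chromosome)) list(b) else list()
  })
}

#' Threshold filters on block length and block size
#'
#' Keep blocks with at least `min_columns` alignment columns /
#' `min_sequences` rows (inclusive thresholds).
#'
#' @param source a `maf_iterator`.
#' @param min_columns,min_sequences inclusive minimum.
#' @return a `maf_iterator`.
#' @export
flt_min_block_length <- function(source, min_columns) {
  iter_flatmap(source, function(b)
    if (block_length(b) >= min_columns) list(b) else list())
}

#' @rdname flt_min_block_length
#' @export
flt_min_block_size <- function(source, min_sequences) {
  iter_flatmap(source, function(b)
    if (block_size(b) >= min_sequences) list(b) else list())
}

#' Split blocks into fixed-size windows
#'
#' Partitions each block into consecutive windows of `window_size` columns.
#' The remainder is dropped on the right (`"left"` alignment), split evenly
#' on both sides (`"center"`), dropped on the left (`"right"`), or windows
#' are rebalanced into `ceiling(L / window_size)` nearly equal pieces
#' (`"adjust"`). Blocks shorter than `window_size` yield nothing, except
#' with `"adjust"` where they pass whole.
#'
#' @param source a `maf_iterator`.
#' @param window_size window width in columns.
#' @param alignment one of `"left"`, `"center"`, `"right"`, `"adjust"`.
#' @return a `maf_iterator`.
#' @export
flt_window_split <- function(source, window_size,
                             alignment = c("left", "center", "right", "adjust")) {
  alignment <- match.arg(alignment)
  stopifnot(window_size >= 1L)
  iter_flatmap(source, function(b) {
    L <- block_length(b)
    if (alignment == "adjust") {
      if (L <= window_size) return(list(b))
      nwin <- ceiling(L / window_size)
      base <- L %/% nwin
      rem <- L - base * nwin
      widths <- c(rep(base + 1L, rem), rep(base, nwin - rem))
      froms <- cumsum(c(1L, widths[-length(widths)]))
      return(Map(function(f, w) subblock(b, f, f + w - 1L),
                 froms, widths))
    }
    k <- L %/% window_size
    if (k == 0L) return(list())
    off <- switch(alignment,
                  left = 0L,
                  right = L - k * window_size,
                  center = (L - k * window_size) %/% 2L)
    lapply(seq_len(k), function(i)
      subblock(b, off + (i - 1L) * window_size + 1L, off + i * window_size))
  })
}

# ---- sliding-window cleaning ---------------------------------------------

# Internal: 1-based start columns of failing windows for one block.
# Predicates operate on the focal rows only (default: all rows).
failing_window_starts <- function(block, window_size, step, predicate, params,
                                  focal_species = NULL) {
  L <- block_length(block)
  if (L < window_size) return(integer(0))
  sp <- block_species(block)
  idx <- if (is.null(focal_species)) seq_along(sp)
         else which(sp %in% focal_species)
  if (length(idx) == 0L) return(integer(0))
  starts <- seq(1L, L - window_size + 1L, by = step)
  m <- block_matrix(block)[idx, , drop = FALSE]
  gaps <- m == GAP_RAW

  win_sum <- function(percol) {           # sum of a per-column vector in windows
    cs <- c(0, cumsum(percol))
    cs[starts + window_size] - cs[starts]
  }

  fails <- switch(predicate,
    gap_count = {
      win_sum(colSums(gaps)) > params$max_gap
    },
    gap_events = {
      openings <- gaps & !cbind(FALSE, gaps[, -ncol(gaps), drop = FALSE])
      ev <- win_sum(colSums(openings))
      # a gap run continuing into the window from the left counts as one event
      carry <- vapply(starts, function(a)
        sum(gaps[, a] & !openings[, a]), integer(1))
      (ev + carry) > params$max_events
    },
    entropy = {
      H <- column_entropies(m)
      win_sum(as.numeric(H > params$entropy_threshold)) > params$max_columns
    },
    mask_count = {
      lower <- m >= as.raw(97L) & m <= as.raw(122L)
      win_sum(colSums(lower)) > params$max_masked
    },
    quality_mean = {
      have <- vapply(block$sequences[idx], function(s) !is.null(s$scores),
                     logical(1))
      if (!any(have)) {
        warning("quality filter: block without quality scores passed unchanged")
        return(integer(0))
      }
      sm <- do.call(rbind, lapply(block$sequences[idx][have],
                                  function(s) s$scores))
      valid <- sm >= 0L
      tot <- win_sum(colSums(sm * valid))
      cnt <- win_sum(colSums(valid))
      means <- ifelse(cnt > 0, tot / cnt, Inf)
      means < params$min_quality
    },
    stop("unknown window predicate: ", predicate))
  starts[fails]
}

# Internal: per-column Shannon entropy (bits) over A/C/G/T frequencies of a
# raw matrix; gaps and N excluded, 0*log(0) = 0.
column_entropies <- function(m) {
  mf <- fold_raw(m)
  apply(mf, 2L, function(col) {
    counts <- c(sum(col == RAW_A), sum(col == RAW_C),
                sum(col == RAW_G), sum(col == RAW_T))
    n <- sum(counts)
    if (n == 0L) return(0)
    p <- counts[counts > 0L] / n
    -sum(p * log2(p))
  })
}

# Internal: one cleaning pass + fixed-point recursion for action = remove.
clean_block_remove <- function(block, window_size, step, predicate, params,
                               focal_species) {
  fs <- failing_window_starts(block, window_size, step, predicate, params,
                              focal_species)
  if (length(fs) == 0L) return(list(block))
  bad <- rep(FALSE, block_length(block))
  for (a in fs) bad[a:(a + window_size - 1L)] <- TRUE
  frags <- excise_columns(block, bad)
  # fragment-local window offsets differ from the parent's, so re-clean
  # until no window fails (guaranteed to terminate: fragments are shorter)
  unlist(lapply(frags, clean_block_remove, window_size = window_size,
                step = step, predicate = predicate, params = params,
                focal_species = focal_species),
         recursive = FALSE)
}

#' Sliding-window alignment cleaning
#'
#' Slides a window of `window_size` columns by `step` over each block and
#' flags windows failing a predicate:
#' \describe{
#'   \item{gap_count}{total gap characters across focal rows `> max_gap`
#'     (ambiguously aligned regions).}
#'   \item{gap_events}{distinct maximal gap runs across focal rows
#'     `> max_events` (the gap-opening variant).}
#'   \item{entropy}{more than `max_columns` columns whose Shannon entropy
#'     over A/C/G/T frequencies (gaps and N excluded, log base 2) exceeds
#'     `entropy_threshold` (highly variable regions).}
#'   \item{mask_count}{soft-masked (lowercase) characters across focal rows
#'     `> max_masked`.}
#'   \item{quality_mean}{mean of non-sentinel quality scores across focal
#'     rows `< min_quality`; blocks without scores pass with a warning.}
#' }
#' The union of failing windows is excised (`action = "remove"`, splitting
#' the block into surviving fragments, re-scanned to a fixed point so that
#' no emitted fragment contains a failing window) or overwritten with `N`
#' (`action = "mask"`; gaps are left in place so coordinates stay exact).
#'
#' @param source a `maf_iterator`.
#' @param window_size,step window geometry in columns (`step <= window_size`).
#' @param predicate one of `"gap_count"`, `"gap_events"`, `"entropy"`,
#'   `"mask_count"`, `"quality_mean"`.
#' @param params named list of predicate parameters (see above).
#' @param focal_species rows the predicate inspects (default: all).
#' @param action `"remove"` or `"mask"`.
#' @return a `maf_iterator`.
#' @export
flt_sliding_window_clean <- function(source, window_size, step, predicate,
                                     params, focal_species = NULL,
                                     action = c("remove", "mask")) {
  action <- match.arg(action)
  stopifnot(window_size >= 1L, step >= 1L, step <= window_size)
  iter_flatmap(source, function(b) {
    if (action == "remove")
      return(clean_block_remove(b, window_size, step, predicate, params,
                                focal_species))
    fs <- failing_window_starts(b, window_size, step, predicate, params,
                                focal_species)
    if (length(fs) == 0L) return(list(b))
    bad <- rep(FALSE, block_length(b))
    for (a in fs) bad[a:(a + window_size - 1L)] <- TRUE
    seqs <- lapply(b$sequences, function(s) {
      r <- charToRaw(s$text)
      mask <- bad & r != GAP_RAW
      r[mask] <- charToRaw("N")
      maf_sequence(s$species, s$chromosome, s$start, s$size, s$strand,
                   s$src_size, rawToChar(r), s$scores)
    })
    list(maf_block(seqs, score = b$score, tree = b$tree))
  })
}
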