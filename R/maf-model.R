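GAP_RAW <- as.raw(45L)   # '-'

# Internal: text -> raw byte vector (fast column arithmetic).
seq_raw <- function(text) charToRaw(text)

# Internal: number of non-gap characters in a text.
count_residues <- function(text) sum(charToRaw(text) != GAP_RAW)

#' One aligned row of a synteny block
#'
#' A `maf_sequence` follows the UCSC MAF conventions: `start` is 0-based and
#' strand-relative (for `-` strand rows it counts from the start of the
#' reverse-complemented source), `size` counts non-gap residues, and
#' `src_size` is the full length of the source chromosome. Lowercase
#' residues denote soft-masking and are preserved. Quality scores, when
#' present, are stored gap-expanded: one integer per alignment column with
#' `-1` at gap positions, so that column slicing treats text and scores
#' uniformly.
#'
#' @param species species label (the part of the MAF `src` field before the
#'   first dot).
#' @param chromosome chromosome/contig label (the rest of the `src` field).
#' @param start 0-based strand-relative start position.
#' @param size number of non-gap residues; recomputed from `text` if `NULL`.
#' @param strand `"+"` or `"-"`.
#' @param src_size total source sequence length (`>= start + size`).
#' @param text gapped sequence text over `A,C,G,T,N,a,c,g,t,n,-`.
#' @param scores optional integer vector of per-column quality scores
#'   (`-1` at gaps, values `0..9` or `99` elsewhere).
#' @return an object of class `maf_sequence`.
#' @export
maf_sequence <- function(species, chromosome, start, size = NULL, strand = "+",
                         src_size = NULL, text = "", scores = NULL) {
  nres <- count_residues(text)
  if (is.null(size)) size <- nres
  if (is.null(src_size)) src_size <- start + size
  start <- as.integer(start); size <- as.integer(size)
  src_size <- as.double(src_size)
  if (size != nres)
    stop("maf_sequence: size (", size, ") != non-gap residue count (", nres,
         ") for ", species, ".", chromosome)
  if (start < 0L) stop("maf_sequence: negative start")
  if (start + size > src_size)
    stop("maf_sequence: start + size exceeds src_size for ",
         species, ".", chromosome)
  if (!strand %in% c("+", "-")) stop("maf_sequence: bad strand '", strand, "'")
  if (!is.null(scores)) {
    scores <- as.integer(scores)
    if (length(scores) != nchar(text))
      stop("maf_sequence: scores length != text length")
    gaps <- charToRaw(text) == GAP_RAW
    if (any(scores[gaps] != -1L))
      stop("maf_sequence: gap positions must carry sentinel score -1")
  }
  structure(list(species = species, chromosome = chromosome, start = start,
                 size = size, strand = strand, src_size = src_size,
                 text = text, scores = scores),
            class = "maf_sequence")
}

#' One synteny block
#'
#' An ordered set of [maf_sequence()] rows of identical gapped length, with
#' an optional alignment score (the MAF `a score=` value) and an optional
#' attached phylogeny (an [ape::read.tree()] `phylo` object, set by the
#' tree-building filters). Duplicate species labels are legal input.
#'
#' @param sequences list of `maf_sequence`.
#' @param score optional numeric alignment score.
#' @param tree optional `phylo` object.
#' @return an object of class `maf_block`.
#' @export
maf_block <- function(sequences = list(), score = NULL, tree = NULL) {
  if (length(sequences) > 0L) {
    lens <- vapply(sequences, function(s) nchar(s$text), integer(1))
    if (length(unique(lens)) > 1L)
      stop("maf_block: sequences have unequal gapped lengths")
  }
  structure(list(sequences = sequences, score = score, tree = tree),
            class = "maf_block")
}

#' @export
print.maf_block <- function(x, ...) {
  cat(sprintf("<maf_block: %d sequence(s), %d column(s)%s%s>\n",
              length(x$sequences), block_length(x),
              if (!is.null(x$score)) sprintf(", score=%g", x$score) else "",
              if (!is.null(x$tree)) ", tree attached" else ""))
  for (s in x$sequences)
    cat(sprintf("  %s.%s %d %d %s %.0f %s\n", s$species, s$chromosome,
                s$start, s$size, s$strand, s$src_size,
                if (nchar(s$text) > 50) paste0(substr(s$text, 1, 47), "...")
                else s$text))
  invisible(x)
}

#' Species labels of a block's rows
#' @param block a `maf_block`.
#' @return character vector (possibly with duplicates).
#' @export
block_species <- function(block)
  vapply(block$sequences, function(s) s$species, character(1))

#' Alignment length of a block
#'
#' Number of gapped columns; 0 for an empty block.
#' @param block a `maf_block`.
#' @return integer column count.
#' @export
block_length <- function(block) {
  if (length(block$sequences) == 0L) return(0L)
  nchar(block$sequences[[1L]]$text)
}

#' Number of sequences in a block
#' @param block a `maf_block`.
#' @return integer row count.
#' @export
block_size <- function(block) length(block$sequences)

#' Map an alignment column to a source coordinate
#'
#' Returns the 0-based strand-relative source position of the residue in
#' `column` (1-based, as usual in R), or `NA` if that column is a gap in
#' this row. Positions increase left to right, one per non-gap character,
#' starting at `seq$start`.
#'
#' @param seq a `maf_sequence`.
#' @param column 1-based column index.
#' @return integer position or `NA_integer_`.
#' @export
column_to_coordinate <- function(seq, column) {
  L <- nchar(seq$text)
  if (column < 1L || column > L)
    stop("column_to_coordinate: column ", column, " out of range [1, ", L, "]")
  r <- charToRaw(seq$text)
  if (r[column] == GAP_RAW) return(NA_integer_)
  seq$start + sum(r[seq_len(column - 1L)] != GAP_RAW)
}

# Internal: vectorized coordinate map for a whole row; NA at gaps.
column_coordinates <- function(seq) {
  r <- charToRaw(seq$text)
  resid <- r != GAP_RAW
  pos <- rep(NA_integer_, length(r))
  pos[resid] <- seq$start + seq_along(which(resid)) - 1L
  pos
}

#' Extract a column range of a block as a new block
#'
#' Columns `from..to` (1-based, inclusive). Each row's `start` is advanced
#' by its residue count left of `from`, `size` is recounted and scores are
#' sliced in parallel. The block score is dropped: an aligner's total score
#' is not meaningful for a fragment. Any attached tree is dropped too.
#'
#' @param block a `maf_block`.
#' @param from,to 1-based inclusive column bounds, `1 <= from <= to <= L`.
#' @return a new `maf_block`.
#' @export
subblock <- function(block, from, to) {
  L <- block_length(block)
  if (from < 1L || to > L || from > to)
    stop("subblock: bad column range [", from, ", ", to, "] for length ", L)
  keep <- logical(L); keep[from:to] <- TRUE
  subblock_columns(block, keep)
}

# Internal: keep an arbitrary logical column mask (contiguous or not).
# Starts advance by residues left of the first kept column only when the
# mask is contiguous; for general masks starts stay put and sizes recount
# (used by column-removing filters where coordinates become approximate).
subblock_columns <- function(block, keep, advance_start = TRUE) {
  seqs <- lapply(block$sequences, function(s) {
    r <- charToRaw(s$text)
    newtext <- rawToChar(r[keep])
    first <- which(keep)[1L]
    adv <- if (advance_start && !is.na(first) && first > 1L)
      sum(r[seq_len(first - 1L)] != GAP_RAW) else 0L
    maf_sequence(s$species, s$chromosome, s$start + adv,
                 size = NULL, strand = s$strand, src_size = s$src_size,
                 text = newtext,
                 scores = if (!is.null(s$scores)) s$scores[keep] else NULL)
  })
  maf_block(seqs, score = NULL, tree = NULL)
}

#' Forward-strand interval of a row
#'
#' The 0-based half-open interval the row covers on the forward (plus)
#' strand of its source sequence: `[start, start+size)` for `+` rows and
#' the reflection `[src_size - start - size, src_size - start)` for `-`
#' rows, per the MAF standard.
#'
#' @param seq a `maf_sequence`.
#' @return list with `chromosome`, `start`, `end` (0-based half-open).
#' @export
to_plus_strand_interval <- function(seq) {
  if (seq$strand == "+") {
    list(chromosome = seq$chromosome, start = seq$start,
         end = seq$start + seq$size)
  } else {
    list(chromosome = seq$chromosome,
         start = as.integer(seq$src_size - seq$start - seq$size),
         end = as.integer(seq$src_size - seq$start))
  }
}

#' A strand-aware genomic feature
#'
#' Intervals are held 0-based half-open internally regardless of the file
#' format they came from.
#'
#' @param species species label (`NA` to match any species).
#' @param chromosome chromosome label.
#' @param start,end 0-based half-open bounds, `end > start`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param kind feature type, e.g. `"exon"`.
#' @param id feature identifier.
#' @return an object of class `maf_feature`.
#' @export
maf_feature <- function(species = NA_character_, chromosome, start, end,
                        strand = ".", kind = "region", id = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start)
    stop("maf_feature: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(species = species, chromosome = chromosome, start = start,
                 end = end, strand = strand, kind = kind, id = id),
            class = "maf_feature")
}

#' A set of genomic features keyed by (species, chromosome)
#' @param features list of [maf_feature()].
#' @return object of class `feature_set`.
#' @export
feature_set <- function(features = list()) {
  structure(list(features = features), class = "feature_set")
}

#' @export
length.feature_set <- function(x) length(x$features)

# Internal: features of a set overlapping a (species, chromosome) pair.
# Feature species NA matches anything.
features_for <- function(fset, species, chromosome) {
  Filter(function(f) {
    (is.na(f$species) || identical(f$species, species)) &&
      identical(f$chromosome, chromosome)
  }, fset$features)
}

# Internal: reverse-complement a text preserving case and gaps.
revcomp_text <- function(text) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n", "-" = "-")
  ch <- rev(strsplit(text, "", fixed = TRUE)[[1L]])
  out <- map[ch]
  if (anyNA(out)) stop("revcomp_text: unexpected character in sequence text")
  paste0(out, collapse = "")
}

# Internal: block as a raw byte matrix (rows x columns).
block_matrix <- function(block) {
  L <- block_length(block)
  n <- length(block$sequences)
  m <- matrix(as.raw(0L), nrow = n, ncol = L)
  for (i in seq_len(n)) m[i, ] <- charToRaw(block$sequences[[i]]$text)
  m
}

# Internal: case-fold a raw matrix/vector of nucleotide bytes to uppercase.
fold_raw <- function(r) {
  lower <- r >= as.raw(97L) & r <= as.raw(122L)
  r[lower] <- as.raw(as.integer(r[lower]) - 32L)
  r
}

RAW_A <- charToRaw("A"); RAW_C <- charToRaw("C")
RAW_G <- charToRaw("G"); RAW_T <- charToRaw("T")
RAW_N <- charToRaw("N")

# Internal: TRUE for unambiguous upper-cased residues (A/C/G/T).
is_acgt <- function(rfolded)
  rfolded == RAW_A | rfolded == RAW_C | rfolded == RAW_G | rfolded == RAW_T
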