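#' Compression kinds
#'
#' Readers and writers accept `none`, `gzip`, `bzip2` or `zip`, or `"auto"`
#' to detect from the filename extension (`.gz`, `.bz2`, `.zip`). When an
#' explicit kind is given, the file's magic bytes must agree; reading a file
#' with the wrong declared kind is an error. Zip archives are restricted to
#' single-member use: the first member is read, and writing produces a
#' single-member archive.
#'
#' @param path file path.
#' @return one of `"none"`, `"gzip"`, `"bzip2"`, `"zip"`.
#' @export
detect_compression <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, gz = "gzip", bz2 = "bzip2", zip = "zip", "none")
}

COMPRESSION_KINDS <- c("none", "gzip", "bzip2", "zip")

resolve_compression <- function(path, compression) {
  if (identical(compression, "auto")) return(detect_compression(path))
  compression <- match.arg(compression, COMPRESSION_KINDS)
  compression
}

# Internal: verify file magic agrees with the declared compression kind.
check_magic <- function(path, compression) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  kind <-
    if (length(magic) >= 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) "gzip"
    else if (length(magic) >= 3L && rawToChar(magic) == "BZh") "bzip2"
    else if (length(magic) >= 2L && magic[1] == as.raw(0x50) && magic[2] == as.raw(0x4b)) "zip"
    else "none"
  if (!identical(kind, compression))
    stop("file ", path, " looks ", kind, "-compressed but was declared ",
         compression)
  invisible(TRUE)
}

# Internal: open a text-mode input connection honouring compression.
open_input <- function(path, compression) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_magic(path, compression)
  switch(compression,
    none  = file(path, "r"),
    gzip  = gzfile(path, "r"),
    bzip2 = bzfile(path, "r"),
    zip   = {
      # unz connections are not line-readable; decompress the first member
      # into memory (zip input is the one non-streaming compression kind)
      members <- utils::unzip(path, list = TRUE)$Name
      if (length(members) == 0L) stop("empty zip archive: ", path)
      con <- unz(path, members[[1L]], "rb")
      raw <- readBin(con, "raw", n = 64L * 1024L^2)
      close(con)
      textConnection(strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1L]])
    })
}

# ---- single-member zip writing -------------------------------------------
# Base R reads zip members (unz) but cannot write them, and no external zip
# binary is assumed. memCompress(type = "gzip") yields a zlib stream; its
# payload minus the 2-byte header and 4-byte Adler trailer is the raw
# DEFLATE data a zip member needs. The CRC32 the zip headers require is
# computed here (table-driven).

le_bytes <- function(x, nbytes) {
  x <- as.numeric(x)
  vapply(seq_len(nbytes) - 1L,
         function(i) as.raw((x %/% 256^i) %% 256), raw(1))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(bitwShiftR(c, 1L), -306674912L)   # 0xEDB88320
          else bitwShiftR(c, 1L)
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(data_raw) {
  tab <- crc32_table()
  crc <- -1L                                          # 0xFFFFFFFF
  bytes <- as.integer(data_raw)
  for (b in bytes)
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

zip_write_single <- function(data_raw, path, member_name) {
  zl <- memCompress(data_raw, type = "gzip")          # zlib framing
  n <- length(zl)
  deflate <- zl[3:(n - 4L)]
  crcv <- crc32(data_raw)
  # two's-complement int -> unsigned value for byte emission
  crc <- le_bytes(if (crcv < 0) crcv + 2^32 else crcv, 4)
  fname <- charToRaw(member_name)
  csize <- le_bytes(length(deflate), 4)
  usize <- le_bytes(length(data_raw), 4)
  common <- c(le_bytes(20, 2), le_bytes(0, 2), le_bytes(8, 2),  # vers/flags/deflate
              le_bytes(0, 2), le_bytes(0x21, 2),                 # time/date
              crc, csize, usize, le_bytes(length(fname), 2), le_bytes(0, 2))
  local_hdr <- c(le_bytes(0x04034b50, 4), common, fname)
  central <- c(le_bytes(0x02014b50, 4), le_bytes(20, 2), common,
               le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),  # comment/disk/int
               le_bytes(0, 4),                                   # ext attrs
               le_bytes(0, 4), fname)                            # local offset
  eocd <- c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(1, 2), le_bytes(1, 2),
            le_bytes(length(central), 4),
            le_bytes(length(local_hdr) + length(deflate), 4),
            le_bytes(0, 2))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(local_hdr, deflate, central, eocd), con)
  invisible(path)
}

# Internal: a line sink honouring compression. For zip, lines are buffered
# and compressed on close (zip archives are not stream-writable this way).
open_output_lines <- function(path, compression) {
  if (compression == "zip") {
    buf <- character(0)
    list(write = function(lines) buf <<- c(buf, lines),
         close = function() {
           data <- charToRaw(paste0(paste(buf, collapse = "\n"), "\n"))
           member <- sub("\\.zip$", "", basename(path))
           if (identical(member, basename(path)))
             member <- paste0(basename(path), ".txt")
           zip_write_single(data, path, member)
         })
  } else {
    con <- switch(compression,
                  none = file(path, "w"),
                  gzip = gzfile(path, "w"),
                  bzip2 = bzfile(path, "w"))
    list(write = function(lines) writeLines(lines, con),
         close = function() close(con))
  }
}

# ---- MAF parsing ----------------------------------------------------------

parse_error <- function(lineno, msg) {
  stop(sprintf("MAF parse error at line %d: %s", lineno, msg), call. = FALSE)
}

split_src <- function(src) {
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot < 0L) list(species = src, chromosome = src)
  else list(species = substr(src, 1L, dot - 1L),
            chromosome = substr(src, dot + 1L, nchar(src)))
}

q_char_to_score <- function(ch) {
  if (ch == "-" || ch == ".") return(-1L)
  if (ch == "F" || ch == "f") return(99L)
  v <- suppressWarnings(as.integer(ch))
  if (is.na(v)) NA_integer_ else v
}

score_to_q_char <- function(v) {
  if (v < 0L) "-" else if (v >= 99L) "F"
  else if (v <= 9L) as.character(v)
  else stop("quality score ", v, " not representable in MAF q line (0-9, 99)")
}

#' Stream blocks from a MAF file
#'
#' Returns a lazy iterator over the alignment blocks of a MAF file. Only
#' one block is parsed at a time; the file is consumed as the stream is
#' pulled, so arbitrarily large files are processed in bounded memory.
#' `s` lines become [maf_sequence()] rows (the `src` field is split into
#' species and chromosome on the first dot), `q` lines attach quality
#' scores to the preceding `s` line, and a blank line terminates a block.
#'
#' @param path MAF file, possibly compressed.
#' @param compression see [detect_compression()]; default auto-detect.
#' @return a `maf_iterator` of `maf_block`.
#' @export
read_maf <- function(path, compression = "auto") {
  compression <- resolve_compression(path, compression)
  con <- open_input(path, compression)
  lineno <- 0L
  finished <- FALSE

  finish <- function() {
    if (!finished) { close(con); finished <<- TRUE }
  }

  parse_s_line <- function(fields) {
    if (length(fields) != 7L)
      parse_error(lineno, paste0("'s' line has ", length(fields),
                                 " fields, expected 7"))
    start <- suppressWarnings(as.integer(fields[3]))
    size <- suppressWarnings(as.integer(fields[4]))
    src_size <- suppressWarnings(as.numeric(fields[6]))
    if (is.na(start) || is.na(size) || is.na(src_size))
      parse_error(lineno, "non-numeric coordinate field in 's' line")
    if (!fields[5] %in% c("+", "-"))
      parse_error(lineno, paste0("bad strand '", fields[5], "'"))
    sc <- split_src(fields[2])
    text <- fields[7]
    if (count_residues(text) != size)
      parse_error(lineno, sprintf(
        "declared size %d != non-gap residue count %d", size,
        count_residues(text)))
    tryCatch(
      maf_sequence(sc$species, sc$chromosome, start, size, fields[5],
                   src_size, text),
      error = function(e) parse_error(lineno, conditionMessage(e)))
  }

  attach_q <- function(seq, qstring) {
    textlen <- nchar(seq$text)
    chs <- strsplit(qstring, "", fixed = TRUE)[[1L]]
    vals <- vapply(chs, q_char_to_score, integer(1), USE.NAMES = FALSE)
    if (anyNA(vals))
      parse_error(lineno, "invalid character in 'q' line")
    gaps <- charToRaw(seq$text) == GAP_RAW
    if (length(vals) == textlen) {
      vals[gaps] <- -1L
    } else if (length(vals) == seq$size) {
      full <- rep(-1L, textlen)
      full[!gaps] <- vals
      vals <- full
    } else {
      parse_error(lineno, sprintf(
        "'q' line length %d matches neither text length %d nor residue count %d",
        length(vals), textlen, seq$size))
    }
    seq$scores <- vals
    seq
  }

  nxt <- function() {
    tryCatch(nxt_impl(), error = function(e) {
      finish()                               # do not leak the connection
      stop(e)
    })
  }

  nxt_impl <- function() {
    if (finished) return(NULL)
    seqs <- list()
    score <- NULL
    in_block <- FALSE
    repeat {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (length(line) == 0L) {                       # EOF
        finish()
        if (in_block && length(seqs) > 0L)
          return(maf_block(seqs, score = score))
        return(NULL)
      }
      lineno <<- lineno + 1L
      if (grepl("^\\s*$", line)) {
        if (in_block && length(seqs) > 0L)
          return(maf_block(seqs, score = score))
        next
      }
      first <- substr(line, 1L, 1L)
      if (first == "#") next
      fields <- strsplit(trimws(line), "\\s+")[[1L]]
      if (fields[1] == "a") {
        if (in_block && length(seqs) > 0L) {
          # block not blank-line terminated; treat 'a' as separator is not
          # legal MAF, flag it
          parse_error(lineno, "'a' line before previous block was terminated")
        }
        in_block <- TRUE
        score <- NULL
        for (kv in fields[-1]) {
          p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
          if (length(p) == 2L && p[1] == "score")
            score <- suppressWarnings(as.numeric(p[2]))
        }
      } else if (fields[1] == "s") {
        if (!in_block) parse_error(lineno, "'s' line outside a block")
        seqs[[length(seqs) + 1L]] <- parse_s_line(fields)
      } else if (fields[1] == "q") {
        if (length(seqs) == 0L)
          parse_error(lineno, "'q' line without preceding 's' line")
        if (length(fields) != 3L)
          parse_error(lineno, "'q' line must have 3 fields")
        seqs[[length(seqs)]] <- attach_q(seqs[[length(seqs)]], fields[3])
      } else if (fields[1] %in% c("e", "i", "track")) {
        next                                           # tolerated, ignored
      } else {
        parse_error(lineno, paste0("unrecognized line type '", fields[1], "'"))
      }
    }
  }
  block_iterator(nxt, close = finish)
}

# Internal: serialize one block to MAF lines.
format_maf_block <- function(block) {
  srcs <- vapply(block$sequences, function(s)
    paste0(s$species, ".", s$chromosome), character(1))
  starts <- vapply(block$sequences, function(s) as.character(s$start), character(1))
  sizes <- vapply(block$sequences, function(s) as.character(s$size), character(1))
  srcsz <- vapply(block$sequences, function(s)
    format(s$src_size, scientific = FALSE, trim = TRUE), character(1))
  wsrc <- max(nchar(srcs)); wst <- max(nchar(starts))
  wsz <- max(nchar(sizes)); wss <- max(nchar(srcsz))
  aline <- if (!is.null(block$score))
    sprintf("a score=%s", format(block$score, scientific = FALSE, trim = TRUE))
  else "a"
  lines <- aline
  for (i in seq_along(block$sequences)) {
    s <- block$sequences[[i]]
    lines <- c(lines, sprintf("s %-*s %*s %*s %s %*s %s",
                              wsrc, srcs[i], wst, starts[i], wsz, sizes[i],
                              s$strand, wss, srcsz[i], s$text))
    if (!is.null(s$scores)) {
      qstr <- paste0(vapply(s$scores, score_to_q_char, character(1)),
                     collapse = "")
      lines <- c(lines, sprintf("q %-*s %*s %s",
                                wsrc, srcs[i],
                                wst + wsz + wss + 4L, "", qstr))
    }
  }
  c(lines, "")
}

#' A streaming MAF writer
#'
#' Lower-level interface used by [write_maf()] and the `Output` pipeline
#' filter: call `$write_block(block)` for each block, then `$close()`.
#'
#' @param path output path.
#' @param compression see [detect_compression()].
#' @return list with `write_block` and `close` closures.
#' @export
maf_writer <- function(path, compression = "auto") {
  compression <- resolve_compression(path, compression)
  sink <- open_output_lines(path, compression)
  sink$write("##maf version=1")
  sink$write("")
  list(write_block = function(block) sink$write(format_maf_block(block)),
       close = function() sink$close())
}

#' Write blocks to a MAF file
#'
#' @param blocks a list of blocks or a `maf_iterator`.
#' @param path output path.
#' @param compression see [detect_compression()].
#' @return invisibly the number of blocks written.
#' @export
write_maf <- function(blocks, path, compression = "auto") {
  if (is.list(blocks) && !inherits(blocks, "maf_iterator"))
    blocks <- iter_from_list(blocks)
  w <- maf_writer(path, compression)
  n <- 0L
  repeat {
    b <- iter_next(blocks)
    if (is.null(b)) break
    w$write_block(b)
    n <- n + 1L
  }
  w$close()
  iter_close(blocks)
  invisible(n)
}

# ---- Fasta import ---------------------------------------------------------

#' Import a whole-genome Fasta file as single-sequence blocks
#'
#' Each record becomes one block with a single row starting at position 0 on
#' the `+` strand; this is only meaningful when records are comprehensive,
#' i.e. every contig's sequence starts at its first nucleotide. Record
#' headers are interpreted as `species.chromosome` (split on the first dot);
#' alternatively pass a fixed `species` and the whole header is used as the
#' chromosome name.
#'
#' @param path Fasta file (optionally gzip/bzip2/zip compressed).
#' @param species optional fixed species label overriding header splitting.
#' @param compression see [detect_compression()].
#' @return a `maf_iterator` of single-sequence blocks.
#' @export
read_fasta_as_blocks <- function(path, species = NULL, compression = "auto") {
  compression <- resolve_compression(path, compression)
  fapath <- path
  if (compression %in% c("zip", "bzip2")) {
    # Biostrings reads gzip natively; decompress other kinds to a tempfile
    con <- open_input(path, compression)
    fapath <- tempfile(fileext = ".fa")
    writeLines(readLines(con, warn = FALSE), fapath)
    close(con)
  } else if (compression != "none") {
    check_magic(path, compression)
  }
  dss <- Biostrings::readDNAStringSet(fapath)
  headers <- sub("\\s.*$", "", names(dss))
  blocks <- lapply(seq_along(dss), function(i) {
    hdr <- headers[[i]]
    if (is.null(species)) {
      sc <- split_src(hdr)
    } else {
      sc <- list(species = species, chromosome = hdr)
    }
    txt <- as.character(dss[[i]])
    maf_block(list(maf_sequence(sc$species, sc$chromosome, 0L,
                                strand = "+", src_size = nchar(txt),
                                text = txt)))
  })
  iter_from_list(blocks)
}

# ---- feature files --------------------------------------------------------

#' Read genomic features from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) and BED coordinates (0-based
#' half-open) are unified to the internal 0-based half-open convention:
#' a GFF3 record `start=s, end=e` becomes `[s-1, e)`.
#'
#' If `species` is `NULL` and a seqid contains a dot it is split into
#' `species.chromosome`; otherwise the seqid is the chromosome and the
#' feature's species is `NA`, which matches any species during filtering.
#'
#' @param path feature file.
#' @param format `"gff3"` or `"bed"`.
#' @param species optional fixed species label.
#' @param kinds optional character vector restricting GFF3 `type` values
#'   (e.g. `"gene"`).
#' @return a [feature_set()].
#' @export
read_features <- function(path, format = c("gff3", "bed"), species = NULL,
                          kinds = NULL) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  df <- as.data.frame(gr)
  if (!is.null(kinds) && "type" %in% names(df))
    df <- df[as.character(df$type) %in% kinds, , drop = FALSE]
  feats <- lapply(seq_len(nrow(df)), function(i) {
    seqid <- as.character(df$seqnames[i])
    if (is.null(species)) {
      if (grepl(".", seqid, fixed = TRUE)) {
        sc <- split_src(seqid)
      } else {
        sc <- list(species = NA_character_, chromosome = seqid)
      }
    } else sc <- list(species = species, chromosome = seqid)
    id <- ""
    for (col in c("ID", "Name", "name", "gene_id"))
      if (col %in% names(df) && !is.na(df[[col]][i]) && nzchar(df[[col]][i])) {
        id <- as.character(df[[col]][i]); break
      }
    kind <- if ("type" %in% names(df)) as.character(df$type[i]) else "region"
    # rtracklayer reports 1-based inclusive for both formats
    maf_feature(sc$species, sc$chromosome,
                start = df$start[i] - 1L, end = df$end[i],
                strand = as.character(df$strand[i]),
                kind = kind, id = id)
  })
  feature_set(feats)
}

# ---- coordinate-bearing alignment export ---------------------------------

#' Ensembl-style coordinate headers
#'
#' Exported alignments name each row `species.chromosome/first-last(strand)`
#' with 1-based inclusive forward-strand positions. `format_coord_header()`
#' builds the name from a [maf_sequence()]; `parse_coord_header()` inverts
#' it exactly.
#'
#' @param seq a `maf_sequence`.
#' @return a header string.
#' @export
format_coord_header <- function(seq) {
  iv <- to_plus_strand_interval(seq)
  sprintf("%s.%s/%d-%d(%s)", seq$species, seq$chromosome,
          iv$start + 1L, iv$end, seq$strand)
}

#' @rdname format_coord_header
#' @param header a header string produced by `format_coord_header()`.
#' @return list with `species`, `chromosome`, `start`, `size`, `strand`,
#'   where `start` is the 0-based strand-relative MAF start (requires
#'   `src_size` to invert `-` strand rows; returned here as the
#'   forward-strand 0-based half-open `fwd_start`/`fwd_end` plus strand).
#' @export
parse_coord_header <- function(header) {
  m <- regmatches(header,
    regexec("^(.+?)\\.(.+)/(\\d+)-(\\d+)\\(([+-])\\)$", header))[[1L]]
  if (length(m) != 6L) stop("unparseable coordinate header: ", header)
  list(species = m[2], chromosome = m[3],
       fwd_start = as.integer(m[4]) - 1L, fwd_end = as.integer(m[5]),
       strand = m[6])
}

#' Write one block as a standalone alignment file
#'
#' Sequence names carry genomic provenance via [format_coord_header()].
#' Phylip output is strict (10-character names) unless `relaxed = TRUE`;
#' strict mode errors on overflow rather than truncating silently.
#'
#' @param block a `maf_block`.
#' @param path output path.
#' @param format `"fasta"`, `"clustal"` or `"phylip"`.
#' @param relaxed allow long names in phylip output.
#' @return invisibly `path`.
#' @export
write_alignment <- function(block, path, format = c("fasta", "clustal", "phylip"),
                            relaxed = FALSE) {
  format <- match.arg(format)
  names_ <- vapply(block$sequences, format_coord_header, character(1))
  texts <- vapply(block$sequences, function(s) s$text, character(1))
  lines <- switch(format,
    fasta = unlist(lapply(seq_along(names_), function(i)
      c(paste0(">", names_[i]),
        substring(texts[i], seq(1, nchar(texts[i]), 60),
                  pmin(seq(1, nchar(texts[i]), 60) + 59, nchar(texts[i])))))),
    clustal = {
      w <- max(nchar(names_)) + 3L
      out <- c("CLUSTAL W multiple sequence alignment", "")
      L <- nchar(texts[1])
      for (off in seq(1, max(L, 1), 60)) {
        for (i in seq_along(names_))
          out <- c(out, sprintf("%-*s%s", w, names_[i],
                                substr(texts[i], off, min(off + 59, L))))
        out <- c(out, "")
      }
      out
    },
    phylip = {
      if (!relaxed && any(nchar(names_) > 10L))
        stop("phylip name overflow (use relaxed = TRUE): ",
             names_[which.max(nchar(names_))])
      w <- if (relaxed) max(nchar(names_)) + 2L else 10L
      c(sprintf(" %d %d", length(names_), nchar(texts[1])),
        vapply(seq_along(names_), function(i)
          sprintf("%-*s%s", w, substr(names_[i], 1, w), texts[i]),
          character(1)))
    })
  writeLines(lines, path)
  invisible(path)
}

# ---- Newick output --------------------------------------------------------

#' Write the trees attached to a stream of blocks
#'
#' One Newick line per block, in stream order; blocks without an attached
#' tree are skipped with a warning.
#'
#' @param blocks list of blocks or a `maf_iterator`.
#' @param path output path.
#' @return invisibly the number of trees written.
#' @export
write_trees <- function(blocks, path) {
  if (is.list(blocks) && !inherits(blocks, "maf_iterator"))
    blocks <- iter_from_list(blocks)
  con <- file(path, "w")
  on.exit(close(con))
  n <- 0L; skipped <- 0L
  repeat {
    b <- iter_next(blocks)
    if (is.null(b)) break
    if (is.null(b$tree)) { skipped <- skipped + 1L; next }
    writeLines(ape::write.tree(b$tree), con)
    n <- n + 1L
  }
  if (skipped > 0L)
    warning(skipped, " block(s) had no attached tree and were skipped")
  invisible(n)
}

# ---- VCF export -----------------------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Internal: SNP records for one block relative to a reference row.
block_snps <- function(block, reference_species) {
  idx <- which(block_species(block) == reference_species)
  if (length(idx) == 0L) return(NULL)     # caller warns & skips
  if (length(idx) > 1L)
    stop("reference species '", reference_species,
         "' occurs ", length(idx), " times in block")
  ref <- block$sequences[[idx]]
  others <- block$sequences[-idx]
  if (length(others) == 0L) return(data.frame())
  rref <- fold_raw(charToRaw(ref$text))
  mat <- fold_raw(block_matrix(maf_block(others)))
  refpos <- column_coordinates(ref)       # strand-relative, NA at gaps
  minus <- ref$strand == "-"
  recs <- list()
  for (col in seq_len(nchar(ref$text))) {
    rb <- rref[col]
    if (!is_acgt(rb)) next
    alt_raw <- mat[, col]
    callable <- is_acgt(alt_raw)
    alts_chr <- rawToChar(alt_raw[callable & alt_raw != rb], multiple = TRUE)
    ref_chr <- rawToChar(rb)
    if (minus) {
      ref_chr <- COMPLEMENT[[ref_chr]]
      alts_chr <- unname(COMPLEMENT[alts_chr])
    }
    alts <- unique(alts_chr)
    if (length(alts) == 0L) next
    pos1 <- if (minus) as.integer(ref$src_size - refpos[col])   # 1-based fwd
            else refpos[col] + 1L
    calls <- rep(NA_character_, length(others))
    basechr <- rawToChar(alt_raw, multiple = TRUE)
    if (minus) basechr <- ifelse(basechr %in% names(COMPLEMENT),
                                 unname(COMPLEMENT[basechr]), basechr)
    for (j in seq_along(others)) {
      if (!callable[j]) next
      calls[j] <- if (basechr[j] == ref_chr) "0"
                  else as.character(match(basechr[j], alts))
    }
    an <- sum(callable)
    ac <- vapply(seq_along(alts), function(k)
      sum(calls == as.character(k), na.rm = TRUE), integer(1))
    recs[[length(recs) + 1L]] <- list(
      chrom = ref$chromosome, pos = pos1, ref = ref_chr,
      alt = paste(alts, collapse = ","), an = an,
      ac = paste(ac, collapse = ","), calls = calls)
  }
  if (length(recs) == 0L) return(data.frame())
  ord <- order(vapply(recs, function(r) r$pos, integer(1)))
  recs[ord]
}

#' A streaming VCF writer
#'
#' Lower-level interface used by [write_vcf()] and the `VcfOutput` pipeline
#' filter: call `$write_block(block)` per block, then `$close()`; the
#' number of records written so far is available via `$records()`.
#'
#' @param path output path.
#' @param reference_species reference row species label.
#' @param genotypes emit per-sequence haploid genotype columns.
#' @return list of closures `write_block`, `close`, `records`.
#' @export
vcf_writer <- function(path, reference_species, genotypes = FALSE) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mafstream",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called allele number\">",
               if (genotypes)
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">"),
             con)
  samples <- NULL
  header_written <- FALSE
  nrec <- 0L
  write_header <- function() {
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (genotypes) cols <- c(cols, "FORMAT", samples)
    writeLines(paste(cols, collapse = "\t"), con)
    header_written <<- TRUE
  }
  list(
    write_block = function(b) {
      sp <- block_species(b)
      if (!reference_species %in% sp) {
        warning("block without reference species '", reference_species,
                "' skipped in VCF export")
        return(invisible(0L))
      }
      recs <- block_snps(b, reference_species)
      others_sp <- sp[-match(reference_species, sp)]
      if (!header_written) {
        samples <<- if (genotypes) others_sp else NULL
        write_header()
      }
      if (length(recs) == 0L || is.data.frame(recs)) return(invisible(0L))
      for (r in recs) {
        fields <- c(r$chrom, r$pos, ".", r$ref, r$alt, ".", ".",
                    sprintf("AC=%s;AN=%d", r$ac, r$an))
        if (genotypes) {
          gt <- vapply(samples, function(s) {
            j <- match(s, others_sp)
            if (is.na(j) || is.na(r$calls[j])) "." else r$calls[j]
          }, character(1))
          fields <- c(fields, "GT", gt)
        }
        writeLines(paste(fields, collapse = "\t"), con)
        nrec <<- nrec + 1L
      }
      invisible(length(recs))
    },
    close = function() {
      if (!header_written) write_header()
      close(con)
    },
    records = function() nrec)
}

#' Call SNPs against a reference species and write a VCF
#'
#' For every alignment column where the reference row holds an unambiguous
#' residue and at least one other row differs with an unambiguous residue,
#' one VCF 4.2 record is emitted: `POS` is the 1-based forward-strand
#' reference position (reverse-strand reference rows are reflected and
#' their alleles complemented), `ALT` lists distinct non-reference residues
#' in order of first appearance, and `INFO` carries `AN` (called alleles
#' among non-reference rows) and `AC` (per-ALT counts). With
#' `genotypes = TRUE` one haploid `GT` column is written per non-reference
#' sequence; the sample set is fixed from the first block of the stream.
#' Blocks lacking the reference species are skipped with a warning;
#' a duplicated reference row is an error.
#'
#' @param blocks list of blocks or a `maf_iterator`.
#' @param reference_species reference row species label.
#' @param path output path.
#' @param genotypes emit per-sequence haploid genotype columns.
#' @return invisibly the number of records written.
#' @export
write_vcf <- function(blocks, reference_species, path, genotypes = FALSE) {
  if (is.list(blocks) && !inherits(blocks, "maf_iterator"))
    blocks <- iter_from_list(blocks)
  w <- vcf_writer(path, reference_species, genotypes)
  tryCatch({
    repeat {
      b <- iter_next(blocks)
      if (is.null(b)) break
      w$write_block(b)
    }
  }, finally = w$close())
  iter_close(blocks)
  invisible(w$records())
}
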