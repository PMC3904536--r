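maf_text_two_blocks <- c(
  "##maf version=1",
  "",
  "a score=23262.0",
  "s hg18.chr7    27578828 38 + 158545518 AAA-GGGAATGTTAACCAAATGA---ATTGTCTCTTACGGTG",
  "s panTro1.chr6 28741140 38 + 161576975 AAA-GGGAATGTTAACCAAATGA---GTTGTCTCTTATGGTG",
  "q panTro1.chr6                         999-9999999999999999999---9999999999999999",
  "",
  "a",
  "s hg18.chr7 27699739 6 + 158545518 TAAAGA",
  "s baboon.chr3    241163 6 -   4622798 TAAAGA",
  "")

test_that("hand-written MAF parses field-exactly", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(maf_text_two_blocks, path)
  blocks <- iter_collect(read_maf(path))
  expect_length(blocks, 2)
  b1 <- blocks[[1]]
  expect_equal(b1$score, 23262.0)
  expect_equal(block_species(b1), c("hg18", "panTro1"))
  s1 <- b1$sequences[[1]]
  expect_equal(s1$chromosome, "chr7")
  expect_equal(s1$start, 27578828L)
  expect_equal(s1$size, 38L)
  expect_equal(s1$strand, "+")
  expect_equal(s1$src_size, 158545518)
  s2 <- b1$sequences[[2]]
  expect_length(s2$scores, nchar(s2$text))
  expect_equal(s2$scores[4], -1L)      # gap sentinel
  expect_equal(s2$scores[1], 9L)
  b2 <- blocks[[2]]
  expect_null(b2$score)
  expect_equal(b2$sequences[[2]]$strand, "-")
  expect_equal(b2$sequences[[2]]$src_size, 4622798)
})

test_that("malformed MAF lines raise parse errors naming the line", {
  bad <- function(lines) {
    path <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("##maf version=1", "", lines, ""), path)
    iter_collect(read_maf(path))
  }
  expect_error(bad(c("a", "s hg.chr1 0 5 + 100 ACGT")), "line 4")
  expect_error(bad(c("a", "s hg.chr1 x 4 + 100 ACGT")), "non-numeric")
  expect_error(bad(c("a", "s hg.chr1 0 4 + 100 ACGT", "q hg.chr1 999")),
               "matches neither")
  expect_error(bad(c("a", "s hg.chr1 0 4 ? 100 ACGT")), "strand")
})

test_that("MAF round-trip is the identity across all compression kinds", {
  fx <- make_synteny_fixture(8, gaps_between = c(0, 2, 0, 5, 0, 0, 1), seed = 3)
  src <- withr::local_tempfile(fileext = ".maf")
  writeLines(fx$maf_lines, src)
  blocks <- iter_collect(read_maf(src))
  expect_length(blocks, 8)
  for (ext in c(".maf", ".maf.gz", ".maf.bz2", ".maf.zip")) {
    path <- withr::local_tempfile(fileext = ext)
    write_maf(blocks, path)
    expect_identical(iter_collect(read_maf(path)), blocks, label = ext)
  }
})

test_that("quality scores survive the MAF round-trip", {
  b <- simulate_k80_block("(a:0.1,b:0.1);", length = 60, seed = 5,
                          gap_rate = 0.1, quality = TRUE)
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(list(b), path)
  lines <- readLines(path)
  expect_length(grep("^q ", lines), 2)
  back <- iter_collect(read_maf(path))[[1]]
  expect_identical(back$sequences[[1]]$scores, b$sequences[[1]]$scores)
})

test_that("declared compression must match the file contents", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(maf_text_two_blocks, path)
  expect_error(read_maf(path, compression = "gzip"), "declared gzip")
  gzpath <- withr::local_tempfile(fileext = ".maf.gz")
  con <- gzfile(gzpath, "w"); writeLines(maf_text_two_blocks, con); close(con)
  expect_error(read_maf(gzpath, compression = "none"), "declared none")
  expect_length(iter_collect(read_maf(gzpath)), 2)  # auto-detects gzip
})

test_that("bzip2 output decompresses to the plain serialization", {
  fx <- make_synteny_fixture(3, seed = 11)
  plain <- withr::local_tempfile(fileext = ".maf")
  bz <- withr::local_tempfile(fileext = ".maf.bz2")
  write_maf(fx$blocks, plain)
  write_maf(fx$blocks, bz)
  con <- bzfile(bz, "r")
  expect_identical(readLines(con), readLines(plain))
  close(con)
})

test_that("the MAF reader is block-lazy", {
  fx <- make_synteny_fixture(50, block_cols = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(fx$maf_lines, path)
  it <- read_maf(path)
  first3 <- iter_collect(it, n = 3)
  expect_length(first3, 3)
  expect_identical(first3[[2]]$sequences[[1]]$text,
                   fx$blocks[[2]]$sequences[[1]]$text)
  iter_close(it)  # closing early must not error
  expect_silent(iter_close(it))
})

test_that("Fasta import yields comprehensive single-row blocks", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">umay.chr1", "ACGTACGTAC", ">umay.chr2", "GGGTTTACAGATG"), fa)
  blocks <- iter_collect(read_fasta_as_blocks(fa))
  expect_length(blocks, 2)
  s <- blocks[[1]]$sequences[[1]]
  expect_equal(s$species, "umay")
  expect_equal(s$chromosome, "chr1")
  expect_equal(s$start, 0L)
  expect_equal(s$size, 10L)
  expect_equal(s$src_size, 10)
  expect_equal(blocks[[2]]$sequences[[1]]$src_size, 13)
  # fixed-species mode: header becomes the chromosome
  blocks2 <- iter_collect(read_fasta_as_blocks(fa, species = "um"))
  expect_equal(blocks2[[1]]$sequences[[1]]$species, "um")
  expect_equal(blocks2[[1]]$sequences[[1]]$chromosome, "umay.chr1")
})

test_that("GFF3 and BED features convert to 0-based half-open intervals", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr2\tsrc\texon\t25\t40\t.\t-\t.\tID=e2"), gff)
  fs <- read_features(gff, "gff3")
  expect_length(fs, 2)
  expect_equal(fs$features[[1]]$start, 0L)
  expect_equal(fs$features[[1]]$end, 10L)
  expect_equal(fs$features[[2]]$start, 24L)
  expect_equal(fs$features[[2]]$end, 40L)
  expect_equal(fs$features[[2]]$strand, "-")
  expect_equal(fs$features[[1]]$id, "g1")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10\tfeat1\t0\t+", bed)
  fb <- read_features(bed, "bed")
  expect_equal(fb$features[[1]]$start, 0L)
  expect_equal(fb$features[[1]]$end, 10L)
})

test_that("coordinate headers follow the species.chr/first-last(strand) dialect", {
  s <- maf_sequence("hg18", "chr1", 10L, strand = "+", src_size = 100,
                    text = "ACGTA")
  expect_equal(format_coord_header(s), "hg18.chr1/11-15(+)")
  p <- parse_coord_header("hg18.chr1/11-15(+)")
  expect_equal(p$fwd_start, 10L)
  expect_equal(p$fwd_end, 15L)
  expect_equal(p$species, "hg18")
  # minus-strand rows advertise the forward-strand interval
  m <- maf_sequence("hg18", "chr1", 10L, strand = "-", src_size = 100,
                    text = "ACGTA")
  expect_equal(format_coord_header(m), "hg18.chr1/86-90(-)")
  pm <- parse_coord_header(format_coord_header(m))
  iv <- to_plus_strand_interval(m)
  expect_equal(pm$fwd_start, iv$start)
  expect_equal(pm$fwd_end, iv$end)
})

test_that("alignment export writes fasta, clustal and phylip", {
  b <- blk(hg18 = "ACGTACGTAC", panTro = "ACGTACGTAT", src_size = 100)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_alignment(b, fa, "fasta")
  lines <- readLines(fa)
  expect_equal(lines[1], ">hg18.chr1/1-10(+)")
  expect_equal(lines[2], "ACGTACGTAC")
  cl <- withr::local_tempfile(fileext = ".aln")
  write_alignment(b, cl, "clustal")
  expect_match(readLines(cl)[1], "CLUSTAL")
  ph <- withr::local_tempfile(fileext = ".phy")
  expect_error(write_alignment(b, ph, "phylip"), "overflow")
  write_alignment(b, ph, "phylip", relaxed = TRUE)
  expect_match(readLines(ph)[1], "^ 2 10$")
})

test_that("write_trees emits one Newick line per tree-bearing block", {
  t1 <- ape::read.tree(text = "(a:1,(b:0.5,c:0.5):0.5);")
  b1 <- blk(a = "ACGT", b = "ACGT", c = "ACGT"); b1$tree <- t1
  b2 <- blk(a = "ACGT", b = "ACGT", c = "ACGT")
  b3 <- blk(a = "ACGT", b = "ACGT", c = "ACGT"); b3$tree <- t1
  path <- withr::local_tempfile(fileext = ".nwk")
  expect_warning(write_trees(list(b1, b2, b3), path), "no attached tree")
  trees <- ape::read.tree(path)
  expect_length(trees, 2)
  expect_setequal(trees[[1]]$tip.label, c("a", "b", "c"))
  expect_equal(sort(trees[[1]]$edge.length), sort(t1$edge.length))
})

test_that("VCF export maps columns to forward-strand positions", {
  b <- maf_block(list(
    maf_sequence("hg", "chr1", 10L, strand = "+", src_size = 1000,
                 text = "ACGT"),
    maf_sequence("pt", "chr9", 0L, strand = "+", src_size = 1000,
                 text = "ACAT")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(b), "hg", path)
  rec <- grep("^[^#]", readLines(path), value = TRUE)
  expect_length(rec, 1)
  f <- strsplit(rec, "\t")[[1]]
  expect_equal(f[1], "chr1")
  expect_equal(f[2], "13")
  expect_equal(f[4], "G")
  expect_equal(f[5], "A")
  # identical rows: no records
  b0 <- blk(hg = "ACGT", pt = "ACGT", src_size = 100)
  p0 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(b0), "hg", p0)
  expect_length(grep("^[^#]", readLines(p0)), 0)
})

test_that("VCF export reflects minus-strand reference rows", {
  b <- maf_block(list(
    maf_sequence("hg", "chr2", 10L, strand = "-", src_size = 100,
                 text = "ACGT"),
    maf_sequence("pt", "chr2", 0L, strand = "+", src_size = 100,
                 text = "AGGT")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(b), "hg", path, genotypes = TRUE)
  rec <- grep("^[^#]", readLines(path), value = TRUE)
  f <- do.call(rbind, strsplit(rec, "\t"))
  pos <- as.integer(f[, 2])
  expect_true(all(pos >= 87 & pos <= 90))
  expect_false(is.unsorted(pos))
  # column 2 (C vs G): reference C on '-' becomes G on the forward strand,
  # at forward position src - q = 100 - 11 = 89
  expect_true(any(f[, 2] == "89" & f[, 4] == "G" & f[, 5] == "C"))
  # genotype column present (one haploid sample)
  expect_equal(f[1, 9], "GT")
})

test_that("VCF positions stay inside the reference interval and REF matches", {
  set.seed(99)
  for (rep in 1:10) {
    strand <- sample(c("+", "-"), 1)
    ncol <- 30
    b <- random_block(3, ncol, gap_rate = 0.15, n_rate = 0.05,
                      species = c("ref", "s1", "s2"))
    b$sequences[[1]] <- maf_sequence("ref", "chr1", 5L, strand = strand,
                                     src_size = 500,
                                     text = b$sequences[[1]]$text)
    path <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(list(b), "ref", path)
    rec <- grep("^[^#]", readLines(path), value = TRUE)
    if (length(rec) == 0) next
    f <- do.call(rbind, strsplit(rec, "\t"))
    pos <- as.integer(f[, 2])
    iv <- to_plus_strand_interval(b$sequences[[1]])
    expect_true(all(pos >= iv$start + 1 & pos <= iv$end))
    expect_false(any(duplicated(pos)))
    # REF equals the (strand-adjusted) reference text at the mapped column
    cm <- char_matrix(b)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (k in seq_along(pos)) {
      cols <- which(toupper(cm[1, ]) != "-")
      coords <- vapply(cols, function(cc)
        column_to_coordinate(b$sequences[[1]], cc), integer(1))
      fwd <- if (strand == "+") coords + 1L
             else as.integer(b$sequences[[1]]$src_size - coords)
      col <- cols[match(pos[k], fwd)]
      base <- toupper(cm[1, col])
      if (strand == "-") base <- comp[[base]]
      expect_equal(f[k, 4], base)
    }
  }
})

test_that("duplicate reference rows abort VCF export", {
  b <- maf_block(list(maf_sequence("hg", "c", 0L, text = "ACGT"),
                      maf_sequence("hg", "c", 0L, text = "ACGA")))
  expect_error(write_vcf(list(b), "hg", tempfile()), "occurs 2")
})
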