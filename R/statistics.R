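# Per-block statistics. All per-column classifiers case-fold residues;
# a "complete" site has no gap and no N/ambiguity in the rows considered.

# Internal: folded raw matrix for selected species rows (all rows when NULL).
group_matrix <- function(block, species = NULL) {
  sp <- block_species(block)
  idx <- if (is.null(species)) seq_along(sp) else which(sp %in% species)
  fold_raw(block_matrix(block)[idx, , drop = FALSE])
}

#' Character counts in a block
#'
#' Case-folded counts of `A`, `C`, `G`, `T`, `N` and gap over all rows;
#' the counts sum to rows x columns.
#'
#' @param block a `maf_block`.
#' @return named integer vector with elements `A,C,G,T,N,gap`.
#' @export
block_counts <- function(block) {
  m <- group_matrix(block)
  c(A = sum(m == RAW_A), C = sum(m == RAW_C), G = sum(m == RAW_G),
    T = sum(m == RAW_T), N = sum(m == RAW_N), gap = sum(m == GAP_RAW))
}

#' Site-class counts for a block
#'
#' Counts of gap-free sites, complete sites (no gap, no unresolved
#' character), and parsimony-informative sites (at least two distinct
#' residues each present in at least two rows; gaps and N are not counted
#' as states, but a column containing them can still qualify — set
#' `gap_as_state = TRUE` to treat the gap as a fifth state).
#'
#' @param block a `maf_block`.
#' @param gap_as_state count the gap character as a state.
#' @return named integer vector `gap_free`, `complete`,
#'   `parsimony_informative`.
#' @export
site_statistics <- function(block, gap_as_state = FALSE) {
  m <- group_matrix(block)
  if (ncol(m) == 0L)
    return(c(gap_free = 0L, complete = 0L, parsimony_informative = 0L))
  gapfree <- colSums(m == GAP_RAW) == 0L
  complete <- gapfree & colSums(!is_acgt(m)) == 0L
  informative <- apply(m, 2L, function(col) {
    states <- col[is_acgt(col)]
    if (gap_as_state) states <- c(states, col[col == GAP_RAW])
    tab <- table(as.integer(states))
    sum(tab >= 2L) >= 2L
  })
  c(gap_free = sum(gapfree), complete = sum(complete),
    parsimony_informative = sum(informative))
}

#' Pairwise divergence between two rows
#'
#' Percent mismatches over columns where both rows hold unambiguous
#' residues; `NA` when no column qualifies.
#'
#' @param block a `maf_block`.
#' @param sp1,sp2 species labels, each present exactly once.
#' @return percent divergence in `[0, 100]`, or `NA`.
#' @export
pairwise_divergence <- function(block, sp1, sp2) {
  sp <- block_species(block)
  i <- which(sp == sp1); j <- which(sp == sp2)
  if (length(i) != 1L || length(j) != 1L)
    stop("pairwise_divergence: species must each be present exactly once")
  a <- fold_raw(charToRaw(block$sequences[[i]]$text))
  b <- fold_raw(charToRaw(block$sequences[[j]]$text))
  ok <- is_acgt(a) & is_acgt(b)
  if (!any(ok)) return(NA_real_)
  100 * sum(a[ok] != b[ok]) / sum(ok)
}

#' Fixed and polymorphic site counts between two groups
#'
#' Per complete column (no gap/N in any row of either group):
#' `P1`/`P2` polymorphic within one group only, `PS` polymorphic in both,
#' `FD` fixed difference (both monomorphic, different alleles). `F1`/`F2`
#' report sites fixed in that group while polymorphic in the other, i.e.
#' the complementary view `F1 = P2`, `F2 = P1`, as used in
#' McDonald-Kreitman style tables. The categories `P1`, `P2`, `PS`, `FD`
#' are mutually exclusive and sum to the number of variable complete sites.
#'
#' @param block a `maf_block`.
#' @param group1,group2 disjoint species sets, each with at least one row.
#' @return named integer vector `P1,P2,F1,F2,FD,PS`.
#' @export
polymorphism_statistics <- function(block, group1, group2) {
  if (length(intersect(group1, group2)) > 0L)
    stop("polymorphism_statistics: groups must be disjoint")
  m1 <- group_matrix(block, group1)
  m2 <- group_matrix(block, group2)
  if (nrow(m1) == 0L || nrow(m2) == 0L)
    stop("polymorphism_statistics: both groups need at least one row")
  out <- c(P1 = 0L, P2 = 0L, F1 = 0L, F2 = 0L, FD = 0L, PS = 0L)
  for (col in seq_len(ncol(m1))) {
    a <- m1[, col]; b <- m2[, col]
    if (!all(is_acgt(a)) || !all(is_acgt(b))) next
    p1 <- length(unique(a)) > 1L
    p2 <- length(unique(b)) > 1L
    if (p1 && p2) out["PS"] <- out["PS"] + 1L
    else if (p1) out["P1"] <- out["P1"] + 1L
    else if (p2) out["P2"] <- out["P2"] + 1L
    else if (a[1] != b[1]) out["FD"] <- out["FD"] + 1L
  }
  out["F1"] <- out[["P2"]]
  out["F2"] <- out[["P1"]]
  out
}

#' Segregating sites and Watterson's theta for a group
#'
#' `S` counts complete columns (within the group) holding at least two
#' distinct residues. Watterson's estimator is `S / a_n` with
#' `a_n = sum(1/i, i = 1..n-1)` for `n` sampled rows; with
#' `per_site = TRUE` it is further divided by the number of complete
#' columns, giving a per-site rate.
#'
#' @param block a `maf_block`.
#' @param group species labels of the sample (default: all rows).
#' @param per_site report theta per complete site.
#' @return list with `S`, `theta_w`, `n`, `complete_sites`.
#' @export
diversity_statistics <- function(block, group = NULL, per_site = FALSE) {
  m <- group_matrix(block, group)
  n <- nrow(m)
  if (n < 2L) stop("diversity_statistics: need at least 2 rows")
  complete <- colSums(!is_acgt(m)) == 0L
  S <- sum(vapply(which(complete), function(col)
    length(unique(m[, col])) > 1L, logical(1)))
  a_n <- sum(1 / seq_len(n - 1L))
  theta <- S / a_n
  if (per_site) {
    nc <- sum(complete)
    theta <- if (nc > 0L) theta / nc else NA_real_
  }
  list(S = as.integer(S), theta_w = theta, n = n,
       complete_sites = sum(complete))
}

#' Unfolded site-frequency spectrum
#'
#' For each complete column that is biallelic within the ingroup and where
#' the outgroup carries one of the two alleles, the derived allele is the
#' non-outgroup allele and its ingroup count (between 1 and n-1) falls in
#' the matching bin. Columns where the outgroup shows a third allele are
#' unpolarizable; monomorphic or multi-allelic ingroup columns are ignored.
#' The histogram totals the polarizable columns.
#'
#' @param block a `maf_block`.
#' @param ingroup species labels of the ingroup sample.
#' @param outgroup single outgroup species (present exactly once).
#' @param bounds numeric bin edges over derived-allele counts; default one
#'   bin per count `1..n-1`.
#' @return list with `histogram` (named by bin), `polarizable`,
#'   `unpolarizable`, `ignored`.
#' @export
site_frequency_spectrum <- function(block, ingroup, outgroup, bounds = NULL) {
  m <- group_matrix(block, ingroup)
  sp <- block_species(block)
  oi <- which(sp == outgroup)
  if (length(oi) != 1L)
    stop("site_frequency_spectrum: outgroup must be present exactly once")
  o <- fold_raw(charToRaw(block$sequences[[oi]]$text))
  n <- nrow(m)
  if (n < 2L) stop("site_frequency_spectrum: need >= 2 ingroup rows")
  if (is.null(bounds)) bounds <- seq(0.5, n - 0.5, by = 1)
  counts <- integer(length(bounds) - 1L)
  unpol <- 0L; ignored <- 0L
  for (col in seq_len(ncol(m))) {
    a <- m[, col]
    if (!all(is_acgt(a)) || !is_acgt(o[col])) { ignored <- ignored + 1L; next }
    alleles <- unique(a)
    if (length(alleles) != 2L) { ignored <- ignored + 1L; next }
    if (!o[col] %in% alleles) { unpol <- unpol + 1L; next }
    derived <- alleles[alleles != o[col]]
    k <- sum(a == derived)
    bin <- findInterval(k, bounds)
    if (bin >= 1L && bin < length(bounds)) counts[bin] <- counts[bin] + 1L
  }
  names(counts) <- vapply(seq_len(length(bounds) - 1L), function(i)
    sprintf("[%g,%g)", bounds[i], bounds[i + 1L]), character(1))
  list(histogram = counts, polarizable = sum(counts),
       unpolarizable = unpol, ignored = ignored)
}

#' Number of haplotype clusters under a branch-length threshold
#'
#' Counts groups of leaves that remain connected after removing every
#' branch of the block's attached tree longer than `threshold`.
#'
#' @param block a `maf_block` with an attached tree (or a `phylo` object).
#' @param threshold maximum branch length kept.
#' @return integer cluster count.
#' @export
count_clusters <- function(block, threshold) {
  tree <- if (inherits(block, "phylo")) block else block$tree
  if (is.null(tree)) stop("count_clusters: no tree attached to block")
  nnode <- max(tree$edge)
  parent <- seq_len(nnode)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- tree$edge.length <= threshold
  for (e in which(keep)) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent[a] <- b
  }
  ntip <- length(tree$tip.label)
  length(unique(vapply(seq_len(ntip), find, integer(1))))
}

#' Number of residues a species contributes to a block
#' @param block a `maf_block`.
#' @param species species label (first matching row).
#' @return integer residue count (0 when absent).
#' @export
sequence_length <- function(block, species) {
  i <- which(block_species(block) == species)[1L]
  if (is.na(i)) return(0L)
  block$sequences[[i]]$size
}

#' Alignment score of a block
#' @param block a `maf_block`.
#' @return numeric score or `NA` when absent.
#' @export
aln_score <- function(block) {
  if (is.null(block$score)) NA_real_ else block$score
}

# ---- streaming CSV statistics sink ---------------------------------------

# Registry mapping statistic names (as used in the option language) to
# closures block -> named list of values.
stat_compute <- function(name, args, block, ref_species) {
  switch(name,
    BlockLength = list(BlockLength = block_length(block)),
    BlockSize = list(BlockSize = block_size(block)),
    AlnScore = list(AlnScore = aln_score(block)),
    SequenceLength = list(SequenceLength =
      sequence_length(block, args$species)),
    BlockCounts = as.list(block_counts(block)),
    SiteStatistics = as.list(site_statistics(block)),
    PairwiseDivergence = list(Divergence = tryCatch(
      pairwise_divergence(block, args$species1, args$species2),
      error = function(e) NA_real_)),
    DiversityStatistics = {
      d <- tryCatch(diversity_statistics(block, args$group),
                    error = function(e) list(S = NA, theta_w = NA))
      list(S = d$S, ThetaW = d$theta_w)
    },
    PolymorphismStatistics = as.list(tryCatch(
      polymorphism_statistics(block, args$group1, args$group2),
      error = function(e) c(P1 = NA, P2 = NA, F1 = NA, F2 = NA,
                            FD = NA, PS = NA))),
    SiteFrequencySpectrum = {
      s <- site_frequency_spectrum(block, args$ingroup, args$outgroup)
      out <- as.list(s$histogram)
      names(out) <- paste0("SFS", seq_along(out))
      c(out, list(Unpolarizable = s$unpolarizable))
    },
    CountClusters = list(Clusters = tryCatch(
      count_clusters(block, args$threshold), error = function(e) NA)),
    stop("unknown statistic: ", name))
}

#' Streaming per-block statistics written to CSV
#'
#' A pass-through filter: each block flows on unchanged while one CSV row
#' per block is appended to `path`, keyed by the block ordinal and the
#' reference row's forward-strand coordinates (1-based inclusive, matching
#' the exported alignment headers). `stats` is a list of
#' `list(name = <statistic>, args = <named list>)` entries; see the option
#' language's `SequenceStatistics` filter.
#'
#' @param source a `maf_iterator`.
#' @param stats list of statistic requests.
#' @param ref_species species providing the coordinate columns.
#' @param path CSV output path.
#' @return a `maf_iterator` (pass-through).
#' @export
flt_sequence_statistics <- function(source, stats, ref_species, path) {
  con <- file(path, "w")
  ordinal <- 0L
  header_written <- FALSE
  fmt <- function(v) {
    if (is.null(v) || (length(v) == 1L && is.na(v))) "NA"
    else as.character(v)
  }
  it <- iter_flatmap(source, function(b) {
    ordinal <<- ordinal + 1L
    i <- which(block_species(b) == ref_species)[1L]
    coords <- if (is.na(i)) list(chromosome = NA, start = NA, end = NA)
              else to_plus_strand_interval(b$sequences[[i]])
    vals <- list(Block = ordinal, Chr = coords$chromosome,
                 Start = if (is.na(coords$start)) NA else coords$start + 1L,
                 Stop = coords$end)
    for (s in stats)
      vals <- c(vals, stat_compute(s$name, s$args, b, ref_species))
    if (!header_written) {
      writeLines(paste(names(vals), collapse = ","), con)
      header_written <<- TRUE
    }
    writeLines(paste(vapply(vals, fmt, character(1)), collapse = ","), con)
    list(b)
  })
  oldclose <- it$close
  it$close <- function() { close(con); if (!is.null(oldclose)) oldclose() }
  it
}
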