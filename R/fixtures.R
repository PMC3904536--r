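# Synthetic data generation: K80 sequence simulation on a tree, synteny
# fixtures with known coordinate ground truth, and topology mixtures.
# Everything is a deterministic function of its arguments and a seed.

# Internal: run code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' K80 transition probability matrix
#'
#' Nucleotide order A, C, G, T. Branch length `t` is in expected
#' substitutions per site; `kappa` is the transition/transversion *rate*
#' ratio (kappa = 4 gives the 2:1 expected transition:transversion count
#' ratio typical of mammalian nuclear DNA). Rows sum to one.
#'
#' @param t branch length (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @return 4x4 stochastic matrix.
#' @export
k80_transition_matrix <- function(t, kappa = 4) {
  alpha <- kappa / (kappa + 2)
  beta <- 1 / (kappa + 2)
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2        # transition
  tv <- 0.25 - 0.25 * e1                   # each transversion
  #          A     C     G     T
  m <- rbind(c(same, tv,   ts,   tv),
             c(tv,   same, tv,   ts),
             c(ts,   tv,   same, tv),
             c(tv,   ts,   tv,   same))
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  m
}

#' Simulate a synteny block under the K80 substitution model
#'
#' A uniform random root sequence is evolved down `tree` using the exact
#' K80 transition probabilities per branch (no Gillespie simulation: the
#' closed form is exact and faster). Each leaf becomes one row of a
#' [maf_block()] with coordinates `species.chr`, start 0, `+` strand.
#' Optional corruption stages inject gaps (`-`), soft-masking (lowercase)
#' and per-column quality scores, in that order.
#'
#' @param tree a `phylo` object or Newick string with branch lengths in
#'   expected substitutions per site.
#' @param length number of alignment columns.
#' @param kappa transition/transversion rate ratio (see
#'   [k80_transition_matrix()]).
#' @param seed integer seed; the block is a deterministic function of
#'   (arguments, seed).
#' @param gap_rate,mask_rate per-position probabilities in `[0, 1]`.
#' @param quality attach random per-column quality scores (integers 0-9,
#'   -1 at gaps).
#' @return a `maf_block` with one row per tree leaf.
#' @export
simulate_k80_block <- function(tree, length = 1000L, kappa = 4, seed = 1L,
                               gap_rate = 0, mask_rate = 0, quality = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), gap_rate >= 0, gap_rate <= 1,
            mask_rate >= 0, mask_rate <= 1, all(tree$edge.length >= 0))
  with_seed(seed, {
    ntip <- base::length(tree$tip.label)
    nnode <- max(tree$edge)
    root <- ntip + 1L
    states <- matrix(NA_integer_, nrow = nnode, ncol = length)
    states[root, ] <- sample.int(4L, length, replace = TRUE)
    tr <- stats::reorder(tree, "cladewise")     # parents before children
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      P <- k80_transition_matrix(tr$edge.length[e], kappa)
      ps <- states[parent, ]
      cs <- integer(length)
      for (s in 1:4) {
        idx <- which(ps == s)
        if (base::length(idx) > 0L)
          cs[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                                prob = P[s, ])
      }
      states[child, ] <- cs
    }
    nucs <- c("A", "C", "G", "T")
    seqs <- lapply(seq_len(ntip), function(i) {
      ch <- nucs[states[i, ]]
      if (gap_rate > 0) {
        g <- stats::runif(length) < gap_rate
        ch[g] <- "-"
      }
      if (mask_rate > 0) {
        lw <- stats::runif(length) < mask_rate & ch != "-"
        ch[lw] <- tolower(ch[lw])
      }
      text <- paste(ch, collapse = "")
      scores <- NULL
      if (quality) {
        scores <- sample.int(10L, length, replace = TRUE) - 1L
        scores[ch == "-"] <- -1L
      }
      maf_sequence(tree$tip.label[i], "chr", 0L, strand = "+",
                   src_size = length, text = text, scores = scores)
    })
    maf_block(seqs)
  })
}

#' Generate a synteny fixture with known ground truth
#'
#' Emits `n_blocks` gap-free blocks over a set of species on one
#' chromosome each, with programmed inter-block genomic distances (0 means
#' contiguous and therefore mergeable at `max_dist = 0`), plus an optional
#' GFF3 annotation at known offsets on the first species. The returned
#' ledger records what downstream filters must produce, so tests assert
#' against the generator's own bookkeeping rather than re-deriving it.
#'
#' @param n_blocks number of blocks.
#' @param species species labels (first one is the coordinate reference).
#' @param block_cols columns per block (recycled to `n_blocks`).
#' @param gaps_between genomic distance before block i+1 (length
#'   `n_blocks - 1`, default all 0).
#' @param features list of `c(start, end)` 0-based half-open intervals on
#'   the reference species, turned into GFF3 gene records.
#' @param chromosome chromosome label used for every species.
#' @param divergence per-site substitution probability applied to each
#'   species' copy of the block's ancestral sequence (rows are homologous,
#'   as in real synteny blocks, so pairwise distances are estimable).
#' @param seed integer seed.
#' @return list with `maf_lines`, `gff3_lines`, `blocks`, and `ledger`
#'   (fields `mergeable`, `n_after_merge`, `block_starts`, `total_cols`).
#' @export
make_synteny_fixture <- function(n_blocks, species = c("spA", "spB", "spC"),
                                 block_cols = 200L, gaps_between = NULL,
                                 features = list(), chromosome = "chr1",
                                 divergence = 0.05, seed = 1L) {
  if (is.null(gaps_between)) gaps_between <- rep(0L, max(n_blocks - 1L, 0L))
  stopifnot(length(gaps_between) == max(n_blocks - 1L, 0L))
  block_cols <- rep_len(as.integer(block_cols), n_blocks)
  total <- sum(block_cols) + sum(gaps_between)
  src_size <- total + 10L
  with_seed(seed, {
    nucs <- c("A", "C", "G", "T")
    starts <- integer(n_blocks)
    pos <- 0L
    blocks <- vector("list", n_blocks)
    for (i in seq_len(n_blocks)) {
      starts[i] <- pos
      ancestor <- sample(nucs, block_cols[i], replace = TRUE)
      seqs <- lapply(species, function(s) {
        ch <- ancestor
        mut <- stats::runif(block_cols[i]) < divergence
        if (any(mut))
          ch[mut] <- vapply(ch[mut], function(x)
            sample(setdiff(nucs, x), 1L), character(1))
        maf_sequence(s, chromosome, pos, strand = "+", src_size = src_size,
                     text = paste(ch, collapse = ""))
      })
      blocks[[i]] <- maf_block(seqs, score = i * 10)
      pos <- pos + block_cols[i] +
        if (i < n_blocks) gaps_between[i] else 0L
    }
    maf_lines <- c("##maf version=1", "",
                   unlist(lapply(blocks, format_maf_block)))
    gff3_lines <- c("##gff-version 3",
                    vapply(seq_along(features), function(k) {
                      f <- features[[k]]
                      sprintf("%s.%s\tfixture\tgene\t%d\t%d\t.\t+\t.\tID=gene%d",
                              species[1], chromosome, f[1] + 1L, f[2], k)
                    }, character(1)))
    mergeable <- gaps_between == 0L
    ledger <- list(
      mergeable = mergeable,
      n_after_merge = 1L + sum(!mergeable),
      block_starts = starts,
      total_cols = sum(block_cols),
      src_size = src_size)
    list(maf_lines = maf_lines, gff3_lines = gff3_lines, blocks = blocks,
         ledger = ledger)
  })
}

#' Generate a shuffled mixture of rooted quartet topologies
#'
#' Produces Newick strings for the three resolutions of the triplet
#' `(a, b, c)` rooted by an outgroup, in the exact counts implied by
#' `proportions` (largest-remainder apportionment), shuffled by `seed`.
#'
#' @param n_trees total number of trees.
#' @param proportions numeric vector of length 3 (`ab`, `ac`, `bc`
#'   resolutions), summing to 1.
#' @param labels four labels: the triplet followed by the outgroup.
#' @param seed integer seed.
#' @return list with `newick` (character vector) and `counts` (named
#'   integer vector `ab`, `ac`, `bc`).
#' @export
make_topology_mixture <- function(n_trees, proportions,
                                  labels = c("a", "b", "c", "outgroup"),
                                  seed = 1L) {
  stopifnot(length(proportions) == 3L, abs(sum(proportions) - 1) < 1e-9,
            length(labels) == 4L)
  raw <- proportions * n_trees
  counts <- floor(raw)
  rem <- n_trees - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  counts <- as.integer(counts)
  names(counts) <- c("ab", "ac", "bc")
  a <- labels[1]; b <- labels[2]; c_ <- labels[3]; og <- labels[4]
  templates <- c(
    ab = sprintf("(((%s:0.1,%s:0.1):0.1,%s:0.2):0.1,%s:0.3);", a, b, c_, og),
    ac = sprintf("(((%s:0.1,%s:0.1):0.1,%s:0.2):0.1,%s:0.3);", a, c_, b, og),
    bc = sprintf("(((%s:0.1,%s:0.1):0.1,%s:0.2):0.1,%s:0.3);", b, c_, a, og))
  newick <- rep(templates, counts)
  newick <- with_seed(seed, sample(newick))
  list(newick = unname(newick), counts = counts)
}
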