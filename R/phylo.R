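# Block-wise distance phylogenetics. Trees are ape "phylo" objects; the
# agglomeration algorithms (NJ, BioNJ, UPGMA, WPGMA) are implemented here
# with deterministic tie-breaking so block-wise genealogies are reproducible.

#' Kimura two-parameter distance between two aligned texts
#'
#' Over columns where both rows hold unambiguous residues, let `P` be the
#' proportion of transitions (A<->G, C<->T) and `Q` the proportion of
#' transversions. The K80 distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`;
#' when either logarithm's argument is non-positive (saturation) or no
#' column can be compared, `NA` is returned.
#'
#' @param text1,text2 gapped texts of equal length (or `maf_sequence`s).
#' @return distance in expected substitutions per site, or `NA`.
#' @export
kimura_distance <- function(text1, text2) {
  if (inherits(text1, "maf_sequence")) text1 <- text1$text
  if (inherits(text2, "maf_sequence")) text2 <- text2$text
  if (nchar(text1) != nchar(text2))
    stop("kimura_distance: texts differ in length")
  a <- fold_raw(charToRaw(text1))
  b <- fold_raw(charToRaw(text2))
  ok <- is_acgt(a) & is_acgt(b)
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine_a <- a == RAW_A | a == RAW_G
  purine_b <- b == RAW_A | b == RAW_G
  transitions <- diff & (purine_a == purine_b)
  P <- sum(transitions) / n
  Q <- sum(diff & !transitions) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Observed (p) distance between two aligned texts
#' @inheritParams kimura_distance
#' @return mismatch proportion over comparable columns, or `NA`.
#' @export
observed_distance <- function(text1, text2) {
  if (inherits(text1, "maf_sequence")) text1 <- text1$text
  if (inherits(text2, "maf_sequence")) text2 <- text2$text
  if (nchar(text1) != nchar(text2))
    stop("observed_distance: texts differ in length")
  a <- fold_raw(charToRaw(text1)); b <- fold_raw(charToRaw(text2))
  ok <- is_acgt(a) & is_acgt(b)
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise distance matrix of a block
#'
#' @param block a `maf_block` with unique species labels and >= 2 rows.
#' @param method `"kimura"` or `"observed"`.
#' @return symmetric labelled matrix (class `dist_matrix`); `NA` marks
#'   saturated pairs.
#' @export
distance_matrix <- function(block, method = c("kimura", "observed")) {
  method <- match.arg(method)
  sp <- block_species(block)
  if (anyDuplicated(sp)) stop("distance_matrix: duplicated species labels")
  n <- length(sp)
  if (n < 2L) stop("distance_matrix: need >= 2 rows")
  f <- if (method == "kimura") kimura_distance else observed_distance
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      v <- f(block$sequences[[i]]$text, block$sequences[[j]]$text)
      d[i, j] <- v; d[j, i] <- v
    }
  structure(d, class = c("dist_matrix", "matrix"))
}

# Internal: deterministic argmin over the upper triangle of a criterion
# matrix; ties broken by lowest (i, j) pair in row-major order.
pick_pair <- function(crit) {
  n <- nrow(crit)
  best <- c(NA_integer_, NA_integer_); bestv <- Inf
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (crit[i, j] < bestv - 1e-12) {
        bestv <- crit[i, j]; best <- c(i, j)
      }
  best
}

# Internal: Newick label quoting not needed for our species labels; assemble
# trees as Newick strings and parse with ape.
nw <- function(label, len) sprintf("%s:%.17g", label, len)

#' Build a tree from a distance matrix
#'
#' Neighbor joining follows the Saitou-Nei Q criterion with the standard
#' branch-length formulas; BioNJ adds the variance-weighted reduction;
#' UPGMA and WPGMA are average- and simple-linkage agglomeration producing
#' rooted ultrametric trees. Tie-breaking is deterministic (lowest index
#' pair), and negative branch length estimates are clamped to zero. `NA`
#' entries (saturated pairs) abort with an error instructing upstream
#' filtering rather than being silently imputed.
#'
#' @param d symmetric labelled distance matrix.
#' @param method `"nj"`, `"bionj"`, `"upgma"` or `"wpgma"`.
#' @return an [ape] `phylo` object (unrooted for nj/bionj).
#' @export
build_tree <- function(d, method = c("nj", "bionj", "upgma", "wpgma")) {
  method <- match.arg(method)
  d <- unclass(d)
  if (anyNA(d))
    stop("build_tree: distance matrix contains NA (saturated pair); ",
         "filter such blocks upstream")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2L) stop("build_tree: need >= 2 taxa")
  if (n == 2L)
    return(ape::read.tree(text = sprintf("(%s,%s);",
      nw(labels[1], d[1, 2] / 2), nw(labels[2], d[1, 2] / 2))))
  if (method %in% c("nj", "bionj")) nj_like(d, labels, variance = method == "bionj")
  else upgma_like(d, labels, weighted = method == "wpgma")
}

# Internal: NJ / BioNJ agglomeration on a working copy of d.
nj_like <- function(d, labels, variance = FALSE) {
  sub <- labels                       # Newick substring per live cluster
  v <- d                              # variance matrix (BioNJ)
  repeat {
    n <- nrow(d)
    if (n == 3L) break
    r <- rowSums(d)
    crit <- matrix(Inf, n, n)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        crit[i, j] <- (n - 2) * d[i, j] - r[i] - r[j]
    p <- pick_pair(crit); i <- p[1]; j <- p[2]
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    newsub <- sprintf("(%s,%s)", nw(sub[i], bi), nw(sub[j], bj))
    others <- setdiff(seq_len(n), c(i, j))
    if (variance && v[i, j] > 0) {
      lambda <- 0.5 + sum(v[j, others] - v[i, others]) /
        (2 * (n - 2) * v[i, j])
      lambda <- min(max(lambda, 0), 1)
    } else lambda <- 0.5
    dnew <- lambda * d[i, others] + (1 - lambda) * d[j, others] -
      lambda * bi - (1 - lambda) * bj
    vnew <- lambda * v[i, others] + (1 - lambda) * v[j, others] -
      lambda * (1 - lambda) * v[i, j]
    keep <- others
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew),
                c(dnew, 0))
    v2 <- rbind(cbind(v[keep, keep, drop = FALSE], vnew),
                c(vnew, 0))
    d <- d2; v <- v2
    sub <- c(sub[keep], newsub)
  }
  # resolve the last three clusters onto one internal node
  ba <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  bb <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  bc <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  txt <- sprintf("(%s,%s,%s);", nw(sub[1], max(ba, 0)),
                 nw(sub[2], max(bb, 0)), nw(sub[3], max(bc, 0)))
  ape::read.tree(text = txt)
}

# Internal: UPGMA / WPGMA with cluster heights.
upgma_like <- function(d, labels, weighted = FALSE) {
  sub <- labels
  size <- rep(1L, length(labels))
  height <- rep(0, length(labels))
  repeat {
    n <- nrow(d)
    crit <- d
    crit[lower.tri(crit, diag = TRUE)] <- Inf
    p <- pick_pair(crit); i <- p[1]; j <- p[2]
    h <- d[i, j] / 2
    newsub <- sprintf("(%s,%s)", nw(sub[i], h - height[i]),
                      nw(sub[j], h - height[j]))
    others <- setdiff(seq_len(n), c(i, j))
    wi <- if (weighted) 0.5 else size[i] / (size[i] + size[j])
    dnew <- wi * d[i, others] + (1 - wi) * d[j, others]
    if (length(others) == 0L) {
      return(ape::read.tree(text = paste0(newsub, ";")))
    }
    d <- rbind(cbind(d[others, others, drop = FALSE], dnew), c(dnew, 0))
    sub <- c(sub[others], newsub)
    size <- c(size[others], size[i] + size[j])
    height <- c(height[others], h)
  }
}

#' Reroot a tree on the branch leading to an outgroup leaf
#'
#' The new root is placed at the midpoint of the outgroup's terminal
#' branch; topology and all leaf-to-leaf path lengths are preserved. When
#' the species is absent the tree is returned untouched with a warning.
#'
#' @param tree a `phylo` object.
#' @param species outgroup leaf label.
#' @return a rooted `phylo` object.
#' @export
reroot_with_outgroup <- function(tree, species) {
  if (!species %in% tree$tip.label) {
    warning("reroot_with_outgroup: species '", species,
            "' not in tree; left untouched")
    return(tree)
  }
  tr <- ape::unroot(tree)
  tip <- which(tr$tip.label == species)
  edge <- which(tr$edge[, 2] == tip)
  len <- tr$edge.length[edge]
  rooted <- ape::root(tr, outgroup = species, resolve.root = TRUE)
  # split the outgroup edge evenly across the new root
  tip2 <- which(rooted$tip.label == species)
  root_node <- length(rooted$tip.label) + 1L
  e_out <- which(rooted$edge[, 1] == root_node & rooted$edge[, 2] == tip2)
  e_rest <- which(rooted$edge[, 1] == root_node & rooted$edge[, 2] != tip2)
  if (length(e_out) == 1L && length(e_rest) == 1L) {
    total <- rooted$edge.length[e_out] + rooted$edge.length[e_rest]
    rooted$edge.length[e_out] <- total / 2
    rooted$edge.length[e_rest] <- total / 2
  }
  rooted
}

#' Drop a leaf from a tree
#'
#' Removes the leaf and fuses the resulting degree-two node, summing the
#' two incident branch lengths, so remaining pairwise path lengths are
#' unchanged. Dropping an absent species is the identity plus a warning.
#'
#' @param tree a `phylo` object.
#' @param species leaf label(s) to remove.
#' @return a `phylo` object.
#' @export
drop_species <- function(tree, species) {
  present <- species %in% tree$tip.label
  if (!any(present)) {
    warning("drop_species: species not in tree; left untouched")
    return(tree)
  }
  if (!all(present))
    warning("drop_species: ignoring absent species ",
            paste(species[!present], collapse = ", "))
  ape::drop.tip(tree, species[present])
}

#' Tally rooted triplet topologies over a list of trees
#'
#' Each tree is restricted to the three focal species plus a declared
#' outgroup; the pair of focal species forming a cherry after rooting on
#' the outgroup determines the resolution. Resolutions are counted as
#' `ab`, `ac`, `bc` (pair indices into `triplet`) plus `unresolved` for
#' polytomies. Counts sum to the number of trees.
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`).
#' @param triplet character vector of the three focal species `(a, b, c)`.
#' @param outgroup species used to root each restricted tree.
#' @return named integer vector `ab`, `ac`, `bc`, `unresolved`.
#' @export
topology_tally <- function(trees, triplet, outgroup) {
  stopifnot(length(triplet) == 3L)
  a <- triplet[1]; b <- triplet[2]; c_ <- triplet[3]
  out <- c(ab = 0L, ac = 0L, bc = 0L, unresolved = 0L)
  for (tr in trees) {
    need <- c(triplet, outgroup)
    if (!all(need %in% tr$tip.label))
      stop("topology_tally: tree lacks required leaves")
    t4 <- ape::keep.tip(tr, need)
    t4$edge.length <- rep(1, nrow(t4$edge))     # topological distances
    dd <- ape::cophenetic.phylo(t4)
    s_ab <- dd[a, b] + dd[c_, outgroup]
    s_ac <- dd[a, c_] + dd[b, outgroup]
    s_bc <- dd[b, c_] + dd[a, outgroup]
    sums <- c(ab = s_ab, ac = s_ac, bc = s_bc)
    mn <- min(sums)
    winners <- names(sums)[sums <= mn + 1e-9]
    if (length(winners) == 1L) out[winners] <- out[winners] + 1L
    else out["unresolved"] <- out["unresolved"] + 1L
  }
  out
}

# ---- stream filters attaching distance matrices and trees ----------------

#' Attach a distance matrix to each block
#'
#' Pass-through filter storing the matrix in attribute `dist_matrix`.
#' Blocks with duplicated species or fewer than two rows pass unmodified
#' with a warning.
#'
#' @param source a `maf_iterator`.
#' @param method see [distance_matrix()].
#' @return a `maf_iterator`.
#' @export
flt_distance_estimation <- function(source, method = "kimura") {
  iter_flatmap(source, function(b) {
    dm <- tryCatch(distance_matrix(b, method), error = function(e) {
      warning("distance estimation skipped: ", conditionMessage(e))
      NULL
    })
    attr(b, "dist_matrix") <- dm
    list(b)
  })
}

#' Build a tree for each block from its attached distance matrix
#'
#' Requires [flt_distance_estimation()] upstream. Blocks whose matrix is
#' missing or contains NA are passed on without a tree, with a warning.
#'
#' @param source a `maf_iterator`.
#' @param method see [build_tree()].
#' @return a `maf_iterator`.
#' @export
flt_distance_based_phylogeny <- function(source, method = "nj") {
  iter_flatmap(source, function(b) {
    dm <- attr(b, "dist_matrix")
    if (is.null(dm)) {
      warning("phylogeny: no distance matrix attached; block passed without tree")
      return(list(b))
    }
    b$tree <- tryCatch(build_tree(dm, method), error = function(e) {
      warning("phylogeny skipped: ", conditionMessage(e))
      NULL
    })
    attr(b, "dist_matrix") <- dm
    list(b)
  })
}

#' Reroot each block's tree with an outgroup
#' @param source a `maf_iterator`.
#' @param outgroup species label.
#' @return a `maf_iterator`.
#' @export
flt_new_outgroup <- function(source, outgroup) {
  iter_flatmap(source, function(b) {
    if (!is.null(b$tree)) b$tree <- reroot_with_outgroup(b$tree, outgroup)
    list(b)
  })
}

#' Drop species from each block's tree
#' @param source a `maf_iterator`.
#' @param species leaf label(s).
#' @return a `maf_iterator`.
#' @export
flt_drop_species <- function(source, species) {
  iter_flatmap(source, function(b) {
    if (!is.null(b$tree)) b$tree <- drop_species(b$tree, species)
    list(b)
  })
}
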