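#' Pairwise distance matrix from a protein alignment
#'
#' For every pair of rows the proportion of differing sites is computed
#' over the columns where both rows are non-gap (pairwise deletion);
#' `mode = "poisson"` applies the Poisson correction `-ln(1 - p)`.
#'
#' @param msa a `protein_msa` with at least three rows.
#' @param mode `"p"` (proportion) or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal and the row ids
#'   as dimnames.
#' @export
pdistance_matrix <- function(msa, mode = c("p", "poisson")) {
  mode <- match.arg(mode)
  n <- length(msa$aln)
  if (n < 3)
    stop_lpmo("lpmominer_validation", "distance matrix needs at least 3 rows")
  mat <- msa_matrix(msa)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok))
        stop_lpmo("lpmominer_undefined_distance",
                  "no comparable columns between '%s' and '%s'",
                  msa$ids[i], msa$ids[j])
      p <- mean(mat[i, ok] != mat[j, ok])
      if (mode == "poisson") {
        if (p >= 1)
          stop_lpmo("lpmominer_undefined_distance",
                    "Poisson correction undefined at p = 1 ('%s' vs '%s')",
                    msa$ids[i], msa$ids[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Iteratively joins the pair minimising the Q criterion
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`. Ties (within 1e-12) are broken by
#' the lexicographically smallest `(i, j)` index pair, where indices refer
#' to the current matrix order (joined nodes are removed and the new node
#' appended at the end). Branch lengths use the standard formulas; a
#' negative estimate is clamped to zero with the deficit transferred to
#' its sister edge (so the pair's total is preserved), and re-clamped at
#' zero if the sister in turn goes negative.
#'
#' @param d symmetric distance matrix with labeled dimnames.
#' @return An unrooted [ape::read.tree()] `phylo` object (basal
#'   trifurcation; all internal nodes degree 3). The attribute
#'   `join_sequence` records the ordered label pairs joined at each
#'   agglomeration step (internal nodes named `u1`, `u2`, ...).
#' @export
nj_tree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop_lpmo("lpmominer_validation", "distance matrix is not symmetric")
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3) stop_lpmo("lpmominer_validation", "need at least 3 taxa")
  nwk <- labels  # newick fragment per active node
  nm <- labels   # display name per active node (internal nodes u1, u2, ...)
  joins <- list()
  u_count <- 0L
  dm <- d
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(dm) > 3) {
    m <- nrow(dm)
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    l <- clamp_pair(li, lj)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], l[1], nwk[j], l[2])
    u_count <- u_count + 1L
    joins[[u_count]] <- c(nm[i], nm[j])
    du <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    rownames(dm2) <- colnames(dm2) <- c(rownames(dm)[keep], "u")
    dm <- dm2
    nwk <- c(nwk[keep], new_nwk)
    nm <- c(nm[keep], sprintf("u%d", u_count))
  }
  d12 <- dm[1, 2]; d13 <- dm[1, 3]; d23 <- dm[2, 3]
  x <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  x <- pmax(x, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1], x[1], nwk[2], x[2], nwk[3], x[3])
  tree <- ape::read.tree(text = txt)
  attr(tree, "join_sequence") <- joins
  tree
}

# Canonical bipartition keys of all internal edges of an unrooted phylo.
# Each key is the sorted tip-label set on the side NOT containing the
# alphabetically first label, joined with "|".
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  tips <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    tips[[p]] <- c(tips[[p]], tips[[ch]])
  }
  all_labels <- sort(tree$tip.label)
  anchor <- all_labels[1]
  internal_children <- tr$edge[tr$edge[, 2] > ntip, 2]
  keys <- vapply(internal_children, function(nd) {
    side <- sort(tree$tip.label[tips[[nd]]])
    if (anchor %in% side) side <- setdiff(all_labels, side)
    paste(side, collapse = "|")
  }, "")
  names(keys) <- as.character(internal_children)
  # trivial bipartitions (single tip / all-but-one) carry no grouping signal
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, 0L)
  keys[sizes >= 2 & sizes <= ntip - 2]
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for each internal edge of the original tree, the
#' percentage of replicates whose tree contains the same tip bipartition.
#' Deterministic for a fixed seed. Replicates in which a resampled
#' alignment leaves some pair with no comparable columns are kept in the
#' denominator and support nothing.
#'
#' @param msa a `protein_msa`.
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @param mode distance mode, see [pdistance_matrix()].
#' @return List `tree` (the original-alignment NJ tree with `node.label`
#'   holding supports) and `support` (data.frame `bipartition`,
#'   `support`).
#' @export
bootstrap_support <- function(msa, n_replicates = 100L, seed = 1L,
                              mode = "p") {
  if (n_replicates < 1)
    stop_lpmo("lpmominer_validation", "need at least one replicate")
  # canonicalise row order so supports do not depend on input leaf order
  # (NJ tie-breaking is defined on matrix order)
  ord <- order(msa$ids)
  msa <- structure(list(ids = msa$ids[ord], aln = msa$aln[ord],
                        center_id = msa$center_id),
                   class = "protein_msa")
  tree <- nj_tree(pdistance_matrix(msa, mode))
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), keys)
  mat <- msa_matrix(msa)
  nc <- ncol(mat)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      rmsa <- structure(list(ids = msa$ids,
                             aln = setNames(apply(mat[, cols, drop = FALSE], 1,
                                                  paste, collapse = ""), msa$ids),
                             center_id = msa$center_id),
                        class = "protein_msa")
      rtree <- tryCatch(nj_tree(pdistance_matrix(rmsa, mode)),
                        lpmominer_undefined_distance = function(e) NULL)
      if (is.null(rtree)) next
      rkeys <- tree_bipartitions(rtree)
      hit <- keys %in% rkeys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_replicates
  # attach supports as node labels on the internal nodes they belong to
  ntip <- length(tree$tip.label)
  node.label <- rep("", tree$Nnode)
  node.label[as.integer(names(keys)) - ntip] <-
    formatC(support, format = "f", digits = 0)
  tree$node.label <- node.label
  list(tree = tree,
       support = data.frame(bipartition = names(support),
                            support = unname(support),
                            stringsAsFactors = FALSE))
}

#' Assign phylogenetic groups / substrates to query leaves
#'
#' Each query leaf inherits the substrate label of its nearest reference
#' leaf by path length. Queries equidistant (within 1e-10) from references
#' with different labels are `"ambiguous"`; queries whose nearest
#' reference lies beyond `max_ref_dist` are `"unassigned"` (distinct
#' groups into which no reference falls).
#'
#' @param tree a `phylo` containing query and reference leaves.
#' @param reference_labels named character vector: names are reference
#'   leaf labels, values their substrate.
#' @param max_ref_dist distance beyond which a query is unassigned.
#' @return `data.frame` with `query`, `substrate`, `nearest_reference`,
#'   `distance`.
#' @export
assign_groups <- function(tree, reference_labels, max_ref_dist = Inf) {
  refs <- names(reference_labels)
  missing <- setdiff(refs, tree$tip.label)
  if (length(missing))
    stop_lpmo("lpmominer_validation", "reference leaves not in tree: %s",
              paste(missing, collapse = ", "))
  queries <- setdiff(tree$tip.label, refs)
  dmat <- ape::cophenetic.phylo(tree)
  out <- lapply(queries, function(q) {
    dq <- dmat[q, refs]
    dmin <- min(dq)
    nearest <- refs[dq <= dmin + 1e-10]
    labs <- unique(unname(reference_labels[nearest]))
    substrate <- if (dmin > max_ref_dist) "unassigned"
                 else if (length(labs) > 1)
                   paste(c("ambiguous", sort(labs)), collapse = ":")
                 else labs
    data.frame(query = q, substrate = substrate,
               nearest_reference = paste(nearest, collapse = ","),
               distance = dmin, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
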