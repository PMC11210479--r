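# Independent oracles and small generators used across the test files.
# These deliberately re-derive results by brute force or via an unrelated
# library path; they never call the package function they are checking.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_records <- function(n, len_range = c(30, 60), pool = AA20,
                           prefix = "R") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  protein_records(sprintf("%s%02d", prefix, seq_len(n)),
                  vapply(lens, function(L)
                    paste(sample(pool, L, replace = TRUE), collapse = ""), ""))
}

# Exhaustive enumeration of all global alignments (column sequences over
# diagonal / up / left) with affine run scoring: a maximal gap run of
# length k costs open + k * ext. Only feasible for short sequences.
enumerate_best_alignment <- function(a, b, sub, open = 11, ext = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  best <- -Inf
  recurse <- function(i, j, path) {
    if (i == n && j == m) {
      best <<- max(best, score_path(path))
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, c(path, "D"))
    if (i < n) recurse(i + 1, j, c(path, "U"))
    if (j < m) recurse(i, j + 1, c(path, "L"))
  }
  score_path <- function(path) {
    s <- 0; ia <- 0; ib <- 0
    runs <- rle(path)
    for (k in seq_along(runs$values)) {
      v <- runs$values[k]; L <- runs$lengths[k]
      if (v == "D") {
        for (q in seq_len(L)) s <- s + sub[ac[ia + q], bc[ib + q]]
        ia <- ia + L; ib <- ib + L
      } else if (v == "U") {
        s <- s - (open + L * ext); ia <- ia + L
      } else {
        s <- s - (open + L * ext); ib <- ib + L
      }
    }
    s
  }
  recurse(0, 0, character())
  best
}

# Brute-force Saitou-Nei join sequence: explicit loops, explicit argmin
# with the smallest-(i,j) tie rule, internal nodes named u1, u2, ...
bruteforce_nj_joins <- function(d) {
  nm <- rownames(d)
  joins <- list(); u <- 0L
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- sapply(seq_len(m), function(i) sum(d[i, ]))
    besti <- 0L; bestj <- 0L; bestq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * d[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; besti <- i; bestj <- j }
    }
    u <- u + 1L
    joins[[u]] <- c(nm[besti], nm[bestj])
    du <- sapply(seq_len(m), function(k)
      (d[besti, k] + d[bestj, k] - d[besti, bestj]) / 2)
    keep <- setdiff(seq_len(m), c(besti, bestj))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    lab <- sprintf("u%d", u)
    rownames(d2) <- colnames(d2) <- c(nm[keep], lab)
    d <- d2; nm <- c(nm[keep], lab)
  }
  joins
}

# Path-length distance matrix of a tree with known topology/lengths,
# used to build additive matrices for NJ recovery tests.
additive_matrix_from_tree <- function(newick) {
  tr <- ape::read.tree(text = newick)
  m <- ape::cophenetic.phylo(tr)
  m[sort(rownames(m)), sort(colnames(m))]
}

# Greedy overlap resolution oracle: same precedence contract as
# assemble_architecture (score desc, span desc, start asc, label), but
# implemented over explicit interval sets instead of a position mask.
resolve_overlaps_oracle <- function(hits, mature_length) {
  span <- hits$query_to - hits$query_from + 1L
  ord <- order(-hits$domain_bitscore, -span, hits$query_from, hits$profile_id)
  occupied <- integer(0)
  segs <- NULL
  for (i in ord) {
    pos <- setdiff(hits$query_from[i]:hits$query_to[i], occupied)
    if (!length(pos)) next
    brk <- c(0, which(diff(pos) != 1), length(pos))
    runs <- lapply(seq_len(length(brk) - 1),
                   function(k) pos[(brk[k] + 1):brk[k + 1]])
    run <- runs[[which.max(sapply(runs, length))]]
    occupied <- c(occupied, run)
    segs <- rbind(segs, data.frame(label = hits$profile_id[i],
                                   start = min(run), end = max(run),
                                   stringsAsFactors = FALSE))
  }
  segs[order(segs$start), , drop = FALSE]
}

toy_submatrix <- function() {
  ab <- c("A", "B", "C", "D")
  m <- matrix(-2, 4, 4, dimnames = list(ab, ab))
  diag(m) <- 3
  m
}

cohort_cache <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- make_table1_cohort()
    co
  }
})

pipeline_cache <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      co <- cohort_cache()
      res <<- run_pipeline(list(records = co$records, hits = co$hits,
                                references = co$references))
    }
    res
  }
})

# mature sequences as annotated by the pipeline, in cohort order
cohort_matures <- function() {
  co <- cohort_cache()
  ann <- pipeline_cache()$annotations
  ann <- ann[match(co$records$id, ann$id), ]
  protein_records(ann$id, vapply(seq_len(nrow(ann)), function(i) {
    r <- co$records$residues[co$records$id == ann$id[i]]
    substr(r, ann$signal_length[i] + 1L, nchar(r))
  }, ""))
}
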