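mk_msa <- function(rows) {
  structure(list(ids = names(rows), aln = rows, center_id = names(rows)[1]),
            class = "protein_msa")
}

test_that("p-distances equal per-pair recounts", {
  rows <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  expect_true(all(pdistance_matrix(mk_msa(rows)) == 0))

  rows2 <- c(a = "AACC", b = "AAGG", c = "AAAA")
  d <- pdistance_matrix(mk_msa(rows2))
  expect_equal(d["a", "b"], 0.5)

  set.seed(81)
  for (k in 1:6) {
    nr <- sample(3:5, 1); nc <- sample(10:20, 1)
    m <- matrix(sample(c("A", "C", "G", "-"), nr * nc, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), nr, nc)
    ok_rows <- apply(m, 1, function(r) any(r != "-"))
    m <- m[ok_rows, , drop = FALSE]
    if (nrow(m) < 3) next
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- sprintf("t%d", seq_along(rows))
    got <- try(pdistance_matrix(mk_msa(rows)), silent = TRUE)
    if (inherits(got, "try-error")) next
    for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      comp <- m[i, ] != "-" & m[j, ] != "-"
      expect_equal(got[i, j], mean(m[i, comp] != m[j, comp]))
    }
  }

  # poisson mode applies -ln(1 - p)
  d2 <- pdistance_matrix(mk_msa(rows2), mode = "poisson")
  expect_equal(d2["a", "b"], -log(1 - 0.5))

  nocomp <- c(a = "AA--", b = "--CC", c = "AACC")
  expect_error(pdistance_matrix(mk_msa(nocomp)),
               class = "lpmominer_undefined_distance")
})

test_that("three taxa give the closed-form star tree", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["a"]], (5 + 9 - 10) / 2)
  expect_equal(el[["b"]], (5 + 10 - 9) / 2)
  expect_equal(el[["c"]], (9 + 10 - 5) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "lpmominer_validation")
  dns <- d; dns[1, 2] <- 99
  expect_error(nj_tree(dns), class = "lpmominer_validation")
})

test_that("NJ exactly recovers additive trees", {
  newicks <- c(
    "((a:2,b:3):1.5,(c:1,d:4):2,e:2.5);",
    "(((a:1,b:1):1,c:3):1,(d:2,e:2):1,f:4);",
    "((a:0.5,(b:1.2,c:0.7):0.4):0.9,d:1.1,(e:2,f:0.3):0.6);")
  for (nw in newicks) {
    d <- additive_matrix_from_tree(nw)
    tr <- nj_tree(d)
    got <- ape::cophenetic.phylo(tr)
    got <- got[rownames(d), colnames(d)]
    expect_equal(got, d, tolerance = 1e-8)
    ref <- ape::read.tree(text = nw)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ join order equals brute-force Q minimisation on random matrices", {
  set.seed(82)
  for (k in 1:60) {
    n <- 6
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- round(runif(n * (n - 1) / 2, 0.05, 1), 3)
    m <- m + t(m)
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tr <- nj_tree(m)
    expect_equal(attr(tr, "join_sequence"), bruteforce_nj_joins(m))
    # and the topology agrees with the reference implementation
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(m))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic and detect strong clades", {
  set.seed(83)
  # two well-separated clades: within-clade columns nearly identical
  base1 <- sample(AA20, 40, replace = TRUE)
  base2 <- sample(AA20, 40, replace = TRUE)
  mut <- function(x, k) { x[sample(40, k)] <- sample(AA20, k, replace = TRUE); x }
  rows <- c(a1 = paste(base1, collapse = ""),
            a2 = paste(mut(base1, 2), collapse = ""),
            a3 = paste(mut(base1, 3), collapse = ""),
            b1 = paste(base2, collapse = ""),
            b2 = paste(mut(base2, 2), collapse = ""),
            b3 = paste(mut(base2, 3), collapse = ""))
  msa <- mk_msa(rows)
  bs <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  clade <- bs$support[grepl("^b1\\|b2\\|b3$|^a1\\|a2\\|a3$",
                            bs$support$bipartition), ]
  expect_true(all(clade$support >= 95))
  bs2 <- bootstrap_support(msa, n_replicates = 100, seed = 7)
  expect_equal(bs$support, bs2$support)

  # leaf-order permutation leaves supports unchanged
  perm <- sample(names(rows))
  bs3 <- bootstrap_support(mk_msa(rows[perm]), n_replicates = 100, seed = 7)
  expect_equal(sort(bs3$support$support), sort(bs$support$support))

  # degenerate identical-row alignment still reports all supports
  same <- mk_msa(c(x = "AAAA", y = "AAAA", z = "AAAA", w = "AAAA"))
  bs4 <- bootstrap_support(same, n_replicates = 5, seed = 1)
  expect_true(all(bs4$support$support >= 0 & bs4$support$support <= 100))
})

test_that("newick output reparses to an isomorphic tree", {
  set.seed(84)
  n <- 8
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 1)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
  tr <- nj_tree(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
})

test_that("group assignment inherits the nearest reference substrate", {
  nw <- "((q1:0.1,ref_chi:0.1):0.5,(q2:0.1,ref_cel:0.1):0.5,qfar:3);"
  tr <- ape::read.tree(text = nw)
  labs <- c(ref_chi = "chitin", ref_cel = "cellulose")
  g <- assign_groups(tr, labs)
  expect_equal(g$substrate[g$query == "q1"], "chitin")
  expect_equal(g$substrate[g$query == "q2"], "cellulose")
  g2 <- assign_groups(tr, labs, max_ref_dist = 2)
  expect_equal(g2$substrate[g2$query == "qfar"], "unassigned")

  # exact tie between differently labeled references
  nw2 <- "(q:1,(ref_chi:1,ref_cel:1):0.5);"
  tr2 <- ape::read.tree(text = nw2)
  g3 <- assign_groups(tr2, labs)
  expect_match(g3$substrate[g3$query == "q"], "^ambiguous")
  expect_error(assign_groups(tr2, c(zz = "chitin")),
               class = "lpmominer_validation")
})
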