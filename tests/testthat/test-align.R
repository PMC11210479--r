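test_that("identical sequences align gap-free with the diagonal score", {
  sub <- blosum62()
  s <- "HGAMESPTDRNA"
  al <- global_align(s, s)
  expect_equal(al$a_aln, s)
  expect_equal(al$b_aln, s)
  expect_equal(al$score,
               sum(diag(sub[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
  al2 <- global_align("HG", "HG")
  expect_equal(al2$score, sub["H", "H"] + sub["G", "G"])
  expect_error(global_align("", "HG"), class = "lpmominer_validation")
})

test_that("alignment scores equal exhaustive enumeration on short sequences", {
  sub <- toy_submatrix()
  set.seed(41)
  for (k in 1:12) {
    la <- sample(1:5, 1); lb <- sample(1:5, 1)
    a <- paste(sample(rownames(sub), la, replace = TRUE), collapse = "")
    b <- paste(sample(rownames(sub), lb, replace = TRUE), collapse = "")
    got <- global_align(a, b, substitution_table = sub)$score
    want <- enumerate_best_alignment(a, b, sub)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent aligner", {
  set.seed(42)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (k in 1:6) {
    rec <- random_records(2, c(25, 45))
    got <- global_align(rec$residues[1], rec$residues[2])$score
    want <- Biostrings::pairwiseAlignment(rec$residues[1], rec$residues[2],
                                          substitutionMatrix = BLOSUM62,
                                          gapOpening = 11, gapExtension = 1,
                                          type = "global", scoreOnly = TRUE)
    expect_equal(got, want)
  }
})

test_that("alignment score is symmetric", {
  set.seed(43)
  for (k in 1:8) {
    rec <- random_records(2, c(15, 40))
    expect_equal(global_align(rec$residues[1], rec$residues[2])$score,
                 global_align(rec$residues[2], rec$residues[1])$score)
  }
})

test_that("position transfer does exact coordinate bookkeeping", {
  s <- "HGAMESPTDRNA"
  al <- global_align(s, s)
  expect_equal(transfer_positions(al, 1:nchar(s)), 1:nchar(s))

  # b = a with one residue deleted before position i: i maps to i - 1
  b <- paste0(substr(s, 1, 3), substr(s, 5, nchar(s)))
  al2 <- global_align(s, b)
  expect_equal(transfer_positions(al2, 8L), 7L)
  expect_equal(transfer_positions(al2, nchar(s)), nchar(b))
  expect_error(transfer_positions(al2, 0L), class = "lpmominer_validation")
  expect_error(transfer_positions(al2, nchar(s) + 1L),
               class = "lpmominer_validation")

  # random indel battery against cumulative-count bookkeeping
  set.seed(44)
  for (k in 1:10) {
    rec <- random_records(1, c(30, 50))
    a <- rec$residues
    drop <- sort(sample(nchar(a), 3))
    bchars <- strsplit(a, "")[[1]][-drop]
    b <- paste(bchars, collapse = "")
    al3 <- global_align(a, b)
    mapped <- transfer_positions(al3, seq_len(nchar(a)))
    # independent bookkeeping oracle: walk the alignment columns once
    acol <- strsplit(al3$a_aln, "")[[1]]
    bcol <- strsplit(al3$b_aln, "")[[1]]
    want <- rep(NA_integer_, nchar(a))
    ia <- 0L; ib <- 0L
    for (col in seq_along(acol)) {
      if (bcol[col] != "-") ib <- ib + 1L
      if (acol[col] != "-") {
        ia <- ia + 1L
        if (bcol[col] != "-") want[ia] <- ib
      }
    }
    expect_identical(mapped, want)
    ok <- !is.na(mapped)
    expect_true(all(diff(mapped[ok]) >= 1))   # monotone
    expect_true(all(mapped[ok] <= which(ok))) # b is a subsequence of a
  }
})

test_that("star MSA embeds sequences losslessly in common columns", {
  rec <- protein_records(c("a", "b", "c"),
                         c("HGAMESPTDRNA", "HGAMESPTDRNA", "HGAMESPTDRNA"))
  msa <- star_msa(rec)
  expect_true(all(!grepl("-", msa$aln)))

  set.seed(45)
  rec2 <- random_records(5, c(20, 45))
  msa2 <- star_msa(rec2)
  expect_equal(length(unique(nchar(msa2$aln))), 1L)
  for (id in rec2$id)
    expect_equal(gsub("-", "", msa2$aln[[id]]),
                 rec2$residues[rec2$id == id])
  # no column may be gap in every row
  m <- do.call(rbind, strsplit(unname(msa2$aln), ""))
  expect_true(all(apply(m, 2, function(col) any(col != "-"))))

  # center plus one sequence reduces to the pairwise alignment
  rec3 <- rec2[1:2, ]
  al <- global_align(rec3$residues[1], rec3$residues[2])
  msa3 <- star_msa(rec3, center_id = rec3$id[1])
  expect_equal(unname(msa3$aln[rec3$id[1]]), al$a_aln)
  expect_equal(unname(msa3$aln[rec3$id[2]]), al$b_aln)

  expect_error(star_msa(rec3, center_id = "nope"),
               class = "lpmominer_validation")
})

test_that("conserved columns match per-column intersection by brute force", {
  rows <- c(a = "HG-AMES", b = "HGKAMES", c = "HGRAMES")
  msa <- structure(list(ids = names(rows), aln = rows, center_id = "a"),
                   class = "protein_msa")
  cc <- conserved_columns(msa, 1)
  m <- do.call(rbind, strsplit(unname(rows), ""))
  oracle <- which(apply(m, 2, function(col)
    all(col != "-") && length(unique(col)) == 1))
  expect_equal(cc$column, oracle)

  set.seed(46)
  for (k in 1:6) {
    nr <- sample(3:6, 1); nc <- sample(8:15, 1)
    m <- matrix(sample(c(AA20[1:4], "-"), nr * nc, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), nr, nc)
    keep <- apply(m, 2, function(col) any(col != "-"))
    m <- m[, keep, drop = FALSE]
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- sprintf("r%d", seq_len(nr))
    msa <- structure(list(ids = names(rows), aln = rows,
                          center_id = names(rows)[1]), class = "protein_msa")
    got <- conserved_columns(msa, 1)$column
    want <- which(apply(m, 2, function(col)
      all(col != "-") && length(unique(col)) == 1))
    expect_equal(got, want)
  }

  # a single differing row removes the column at min_fraction 1
  rows2 <- c(a = "HGA", b = "HGA", c = "HTA")
  msa2 <- structure(list(ids = names(rows2), aln = rows2, center_id = "a"),
                    class = "protein_msa")
  expect_equal(conserved_columns(msa2, 1)$column, c(1L, 3L))
  expect_equal(conserved_columns(msa2, 2 / 3)$column, 1:3)
})

test_that("percent identity is the fully conserved column fraction", {
  rows <- c(a = "HGAMES", b = "HGAMES")
  msa <- structure(list(ids = names(rows), aln = rows, center_id = "a"),
                   class = "protein_msa")
  expect_equal(percent_identity(msa), 100)
  rows2 <- c(a = "AAAA", b = "CCCC")
  msa2 <- structure(list(ids = names(rows2), aln = rows2, center_id = "a"),
                    class = "protein_msa")
  expect_equal(percent_identity(msa2), 0)
  msa3 <- structure(list(ids = "a", aln = rows["a"], center_id = "a"),
                    class = "protein_msa")
  expect_error(percent_identity(msa3), class = "lpmominer_validation")
})

test_that("aligned FASTA round trips through write_msa / read_msa", {
  set.seed(47)
  msa <- star_msa(random_records(4, c(20, 35)))
  path <- withr::local_tempfile(fileext = ".afa")
  write_msa(msa, path)
  back <- read_msa(path)
  expect_equal(unname(back$aln[msa$ids]), unname(msa$aln))
})
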