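test_that("mature derivation recovers the planted signal cleavage", {
  co <- cohort_cache()
  rec <- co$records[co$records$id == "GL0247266", ]
  md <- derive_mature(rec, co$references)
  expect_equal(md$signal_length, 27L)
  expect_equal(nchar(md$mature), 604L)
  expect_equal(substr(md$mature, 1, 5), "HGAME")  # Edman-confirmed N-terminus

  rec2 <- co$records[co$records$id == "GL0183513", ]
  md2 <- derive_mature(rec2, co$references)
  expect_equal(md2$signal_length, 30L)
  expect_equal(substr(md2$mature, 1, 5), "HGYIQ")

  syn <- make_lpmo(list(id = "S", specificity = "chitin",
                        architecture = character(), mutation_rate = 0,
                        signal_length = 20L), seed = 8)
  md3 <- derive_mature(syn$record, co$references)
  expect_equal(md3$signal_length, 20L)

  noh <- protein_records("NOH", paste(rep("MKLAVST", 30), collapse = ""))
  expect_error(derive_mature(noh, co$references),
               class = "lpmominer_no_mature")
})

test_that("active-site mapping hits the published Hx/Fy positions", {
  co <- cohort_cache()
  ann <- pipeline_cache()$annotations
  t1 <- lpmo_table1()
  ann <- ann[match(t1$id, ann$id), ]
  expect_equal(ann$hx, t1$hx)
  expect_equal(ann$fy, t1$fy)
  expect_equal(ann$mature_length, t1$mature_length)
  expect_equal(ann$full_length, t1$full_length)

  # a reference mapped onto itself returns its own annotations
  refs <- co$references
  site <- map_active_site(refs$sequence[1], refs)
  expect_equal(site$hx, refs$hx[1])
  expect_equal(site$fy, refs$fy[1])

  expect_error(map_active_site("AGAMES", refs), class = "lpmominer_validation")
})

test_that("diagnostic residue drives the substrate call", {
  co <- cohort_cache()
  refs <- co$references
  site <- map_active_site(refs$sequence[1], refs)
  d <- diagnose_specificity(refs$sequence[1], site, refs)
  expect_equal(d$residue, "I")
  expect_equal(d$call, "chitin")

  syn <- make_lpmo(list(id = "CEL", specificity = "cellulose",
                        architecture = character(), mutation_rate = 0),
                   seed = 17)
  md <- derive_mature(syn$record, refs)
  site2 <- map_active_site(md$mature, refs)
  d2 <- diagnose_specificity(md$mature, site2, refs)
  expect_equal(d2$residue, "R")
  expect_equal(d2$call, "cellulose")

  # the Ile-next-to-Arg case: chitin call despite the nearby arginine
  ann <- pipeline_cache()$annotations
  g <- ann[ann$id == "GL0247266", ]
  expect_equal(g$diagnostic_residue, "I")
  expect_equal(g$specificity, "chitin")
  expect_equal(sum(ann$specificity == "cellulose"), 4L)
})

test_that("tryptophan triad completeness matches the plants", {
  co <- cohort_cache()
  refs <- co$references
  site <- map_active_site(refs$sequence[1], refs)
  expect_true(detect_triad(refs$sequence[1], site, refs)$complete)

  syn <- make_lpmo(list(id = "T", specificity = "chitin",
                        architecture = character(), mutation_rate = 0,
                        triad_class = "minus_a"), seed = 23)
  md <- derive_mature(syn$record, refs)
  site2 <- map_active_site(md$mature, refs)
  tri <- detect_triad(md$mature, site2, refs)
  expect_false(tri$complete)
  expect_length(tri$found, 2L)

  ann <- pipeline_cache()$annotations
  expect_equal(sum(ann$triad_complete), 21L)
})

test_that("conserved alanine is found at its anchor column", {
  co <- cohort_cache()
  refs <- co$references
  rec <- co$records[co$records$id == "GL0247266", ]
  md <- derive_mature(rec, refs)
  site <- map_active_site(md$mature, refs, record_id = "GL0247266")
  expect_true(detect_conserved_alanine(md$mature, site, refs))
  # the anchor maps to mature position 137 (Hx 112 + 25)
  pos <- transfer_positions(site$alignment, refs$alanine_anchor[site$ref_index])
  expect_equal(pos, 137L)
  expect_equal(substr(md$mature, 137, 137), "A")

  ann <- pipeline_cache()$annotations
  expect_equal(sum(ann$alanine_conserved), 29L)
})

test_that("polar motif scanning honours the degenerate pattern", {
  hit <- scan_polar_motif("KKKYEPQSVEKKK")
  expect_equal(c(hit$start, hit$end), c(4L, 10L))
  hit2 <- scan_polar_motif("AAWNPQSLEAA")
  expect_equal(hit2$match, "WNPQSLE")
  # one mismatch at a fixed position is tolerated, two are not
  expect_false(is.null(scan_polar_motif("YETQSVE")))
  expect_null(scan_polar_motif("YETQAVE"))
  # bracket positions are exact
  expect_null(scan_polar_motif("AEPQSVE"))
  expect_null(scan_polar_motif("AAAA"))

  ann <- pipeline_cache()$annotations
  expect_equal(sum(ann$polar_motif), 20L)
})

test_that("gatekeeper scanning reports the best window above threshold", {
  g <- scan_gatekeeper("KKVADTGNAFYKK")
  expect_equal(g$similarity, 1)
  expect_equal(c(g$start, g$end), c(3L, 11L))
  expect_equal(scan_gatekeeper("kkvadtgnafykk")$similarity, 1)  # case folded
  # five of nine matches is below the default threshold
  expect_null(scan_gatekeeper("VADTGQQQQKKKKKKKK", min_matches = 6L))

  set.seed(61)
  gk <- strsplit("VADTGNAFY", "")[[1]]
  for (k in 1:10) {
    s <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
    got <- scan_gatekeeper(s, min_matches = 0L)
    chars <- strsplit(s, "")[[1]]
    scores <- sapply(1:(40 - 8), function(i) sum(chars[i:(i + 8)] == gk))
    expect_equal(got$similarity, max(scores) / 9)
    expect_equal(got$start, which.max(scores))
  }
})

test_that("cysteine reports count exactly", {
  co <- cohort_cache()
  refs <- co$references
  rec <- co$records[co$records$id == "GL0658692", ]
  md <- derive_mature(rec, refs)
  site <- map_active_site(md$mature, refs)
  cys <- cysteine_report(rec, md, catalytic_domain_span(site, nchar(md$mature)))
  expect_equal(cys$n_full, 8L)
  expect_equal(cys$n_catalytic, 6L)
  expect_equal(cys$max_bridges, 3L)

  nocys <- protein_records("NC", "HGAMESPTDRNA")
  md2 <- list(record_id = "NC", signal_length = 0L, mature = nocys$residues)
  cys2 <- cysteine_report(nocys, md2, c(1L, 12L))
  expect_equal(unlist(cys2[c("n_full", "n_catalytic", "max_bridges")]),
               c(n_full = 0L, n_catalytic = 0L, max_bridges = 0L))

  set.seed(62)
  for (k in 1:8) {
    rec3 <- random_records(1, c(40, 80))
    span <- sort(sample(nchar(rec3$residues), 2))
    md3 <- list(record_id = rec3$id, signal_length = 0L,
                mature = rec3$residues)
    got <- cysteine_report(rec3, md3, span)
    chars <- strsplit(rec3$residues, "")[[1]]
    expect_equal(got$n_full, sum(chars == "C"))
    expect_equal(got$n_catalytic, sum(chars[span[1]:span[2]] == "C"))
    expect_equal(got$max_bridges, got$n_catalytic %/% 2L)
  }
})

test_that("annotation invariants hold on a planted battery", {
  co <- cohort_cache()
  ann <- pipeline_cache()$annotations
  expect_true(all(ann$hx > 1))
  expect_true(all(ann$fy > ann$hx))
  expect_true(all(ann$fy <= ann$mature_length))
  tr <- co$truth[match(ann$id, co$truth$id), ]
  expect_equal(ann$hx, tr$hx)
  expect_equal(ann$fy, tr$fy)
  expect_equal(ann$triad_complete, tr$triad_complete)
  expect_equal(ann$alanine_conserved, tr$has_alanine)
  expect_equal(ann$polar_motif, tr$has_polar)
  expect_equal(ann$specificity, tr$specificity)
})
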