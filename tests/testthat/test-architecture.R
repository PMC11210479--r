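mk_arch_hits <- function(label, from, to, score = NULL) {
  if (!length(label))
    return(structure(data.frame(query_id = character(), profile_id = character(),
                                profile_length = integer(),
                                domain_bitscore = numeric(), bias = numeric(),
                                query_from = integer(), query_to = integer(),
                                hmm_from = integer(), hmm_to = integer(),
                                stringsAsFactors = FALSE),
                     class = c("domain_hits", "data.frame")))
  structure(data.frame(query_id = "q", profile_id = label,
                       profile_length = 200L,
                       domain_bitscore = score %||% seq(100, by = -1,
                                                        length.out = length(label)),
                       bias = 0, query_from = as.integer(from),
                       query_to = as.integer(to), hmm_from = 1L, hmm_to = 200L,
                       stringsAsFactors = FALSE),
            class = c("domain_hits", "data.frame"))
}

test_that("architectures assemble sorted, disjoint segments with SPACEs", {
  none <- mk_arch_hits(character(), integer(), integer(), numeric())
  a <- assemble_architecture(none, 120L)
  expect_equal(a$label, "SPACE")
  expect_equal(c(a$start, a$end), c(1L, 120L))
  expect_equal(nrow(assemble_architecture(none, 40L)), 0L)

  # tandem-CBM5 architecture with a C-terminal secretion tail
  h <- mk_arch_hits(c("LPMO10", "CBM5", "CBM5", "Secret_tail_C"),
                    c(1, 200, 245, 500), c(190, 239, 284, 574),
                    score = c(300, 80, 75, 60))
  a2 <- assemble_architecture(h, 580L)
  expect_equal(architecture_string(a2),
               "LPMO10|CBM5|CBM5|SPACE|Secret_tail_C")
  expect_true(all(diff(a2$start) > 0))
  expect_true(all(a2$start[-1] > a2$end[-nrow(a2)]))

  bad <- mk_arch_hits("CBM5", 10, 700, 50)
  expect_error(assemble_architecture(bad, 500L),
               class = "lpmominer_validation")
})

test_that("overlap resolution equals the precedence oracle and is order-invariant", {
  set.seed(71)
  for (k in 1:200) {
    n <- sample(2:6, 1)
    from <- sample(1:150, n, replace = TRUE)
    to <- pmin(from + sample(10:80, n, replace = TRUE), 200L)
    h <- mk_arch_hits(sample(c("CBM5", "Fn3", "GbpA_2"), n, replace = TRUE),
                      from, to, score = sample(seq(20, 120, by = 0.5), n))
    a <- assemble_architecture(h, 200L, min_space_len = 1000L)
    want <- resolve_overlaps_oracle(h, 200L)
    expect_equal(a$label, want$label)
    expect_equal(a$start, want$start)
    expect_equal(a$end, want$end)

    perm <- h[sample(n), ]
    a2 <- assemble_architecture(perm, 200L, min_space_len = 1000L)
    expect_equal(a2, a, ignore_attr = TRUE)
  }
})

test_that("GbpA-like classification needs the adjacent Domain-X", {
  h <- mk_arch_hits(c("LPMO10", "GbpA_2", "Ig_like", "CBM5_12"),
                    c(1, 216, 416, 510), c(191, 317, 504, 602),
                    score = c(300, 90, 80, 70))
  a <- assemble_architecture(h, 604L)
  expect_equal(architecture_string(a),
               "LPMO10|GbpA_2|SPACE|Ig_like|CBM5_12")
  g <- classify_gbpa_like(a)
  expect_true(g$gbpa_like)
  expect_equal(g$evidence$label, c("LPMO10", "GbpA_2", "SPACE"))
  expect_equal(count_functional_domains(a), 5L)

  lone <- assemble_architecture(mk_arch_hits("LPMO10", 1, 190, 300), 200L)
  expect_false(classify_gbpa_like(lone)$gbpa_like)
  expect_equal(count_functional_domains(lone), 1L)

  # SPACE far downstream of GbpA_2 violates adjacency
  h2 <- mk_arch_hits(c("LPMO10", "GbpA_2", "Fn3"),
                     c(1, 200, 310), c(190, 295, 400),
                     score = c(300, 90, 80))
  a2 <- assemble_architecture(h2, 600L)   # SPACE starts at 401
  expect_equal(architecture_string(a2), "LPMO10|GbpA_2|Fn3|SPACE")
  expect_false(classify_gbpa_like(a2)$gbpa_like)
  expect_equal(count_functional_domains(a2), 3L)
  # unless confirmed structurally
  expect_equal(count_functional_domains(a2, confirmed_domain_x = 401L), 4L)

  empty <- assemble_architecture(mk_arch_hits(character(), integer(),
                                              integer(), numeric()), 30L)
  expect_equal(count_functional_domains(empty), 0L)
})

test_that("cohort architectures equal the planted layouts", {
  co <- cohort_cache()
  res <- pipeline_cache()
  tr <- co$truth
  ann <- res$annotations[match(tr$id, res$annotations$id), ]
  expect_equal(ann$architecture, tr$architecture)
  expect_equal(sum(ann$gbpa_like), 13L)
  expect_equal(ann$n_functional_domains[ann$id == "GL0247266"], 5L)
  expect_equal(ann$n_functional_domains[ann$id == "GL0183513"], 4L)
})
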