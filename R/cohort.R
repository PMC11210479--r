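## Synthetic stand-in cohort for the 31-protein study table.
##
## The real supplementary sequences of the source study are not
## redistributable here; instead this builder constructs a synthetic
## cohort whose ground truth embodies the published per-protein table
## ([lpmo_table1()]): full/mature lengths, Hx/Fy positions and cysteine
## counts row for row, plus the published census features (nine
## family-conserved residues, 21 complete tryptophan triads, 20 polar
## motifs, 29 conserved alanines, and a three-member group of
## near-identical single-domain proteins with 83.3% catalytic identity).
## Files derived from it are labelled "synthetic" wherever they are
## stored.

# per-protein feature design (which proteins carry which sequence marks);
# group-level assignments follow the study's substrate and census logic,
# the exact membership of the triad/polar/alanine sets is a design choice.
cohort_design <- function() {
  t1 <- lpmo_table1()
  d <- data.frame(id = t1$id, group = t1$group, stringsAsFactors = FALSE)
  g1 <- t1$group == "1"
  d$diag <- ifelse(g1, "R", ifelse(t1$group == "3.6", "V", "I"))
  d$diag[d$id == "GL0247266"] <- "I"     # Ile at the diagnostic column,
  d$special_rel11 <- NA_character_       # Arg immediately upstream
  d$special_rel11[d$id == "GL0247266"] <- "R"
  incomplete_ab <- t1$id[g1]
  incomplete_a <- c("GL1004230", "GL0883009", "GL0656018", "GL0225724",
                    "GL0620585")
  d$triad <- ifelse(d$id %in% incomplete_ab, "minus_ab",
                    ifelse(d$id %in% incomplete_a, "minus_a", "complete"))
  d$alanine <- !(d$id %in% c("GL0522565", "GL0620585"))
  d$polar <- !(d$id %in% c(incomplete_ab, incomplete_a, "GL0522565"))
  d
}

# explicit accessory-domain placements (mature coordinates); SPACE
# regions are the uncovered gaps >= 60 residues between them
cohort_layouts <- function() {
  list(
    GL0247266 = "GbpA_2:216-317,Ig_like:416-504,CBM5_12:510-602",
    GL1034380 = "",
    GL0125011 = "Fn3:210-304,CBM73:320-379,CBM5:400-439",
    GL0658692 = "CBM5:200-239,CBM73:290-349",
    GL0213284 = "CBM5:200-239,CBM73:290-349",
    GL0393374 = "", GL0681738 = "", GL0089352 = "",
    GL0183513 = "GbpA_2:180-276,CBM73:395-445",
    GL0251010 = "GbpA_2:190-285,CBM73:396-450",
    GL0522565 = "GbpA_2:188-283,CBM73:394-448",
    GL0422153 = "GbpA_2:188-283,CBM73:394-448",
    GL1004230 = "",
    GL0883009 = "CBM73:240-299",
    GL0293304 = "Fn3:200-294,Ig_like:310-399",
    GL0656018 = "Fn3:180-274,CBM73:290-349,CBM5:360-399",
    GL0225724 = "",
    GL0391320 = "CBM5:200-239,CBM5:245-284,Fn3:300-394,CBM73:420-479,Secret_tail_C:500-569",
    GL0200824 = "CBM5:200-239,CBM5:245-284,Fn3:300-394,CBM73:420-479,Secret_tail_C:500-569",
    GL0338092 = "CBM5:200-239,CBM5:245-284,CBM73:500-559",
    GL0600730 = "",
    GL0066553 = "GbpA_2:180-275,CBM5:400-439",
    GL0555809 = "GbpA_2:178-273,CBM5:398-437",
    GL0999597 = "CBM5:190-229",
    GL0620585 = "Fn3:210-304,CBM73:320-379,CBM5:505-544",
    GL0297948 = "GbpA_2:178-273,CBM5:414-453",
    GL0875000 = "GbpA_2:178-273,CBM5:415-454",
    GL0489328 = "GbpA_2:178-273,CBM5:416-455",
    GL0507050 = "GbpA_2:178-273,CBM5:416-455",
    GL0417116 = "GbpA_2:178-273,CBM5:413-452",
    GL0772141 = "GbpA_2:178-273,CBM5:412-451")
}

parse_layout <- function(txt, cat_end, mature_length, min_space_len = 60L) {
  segs <- data.frame(label = "LPMO10", start = 1L, end = cat_end,
                     stringsAsFactors = FALSE)
  if (nzchar(txt)) {
    parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
    for (p in parts) {
      m <- regmatches(p, regexec("^([A-Za-z0-9_]+):(\\d+)-(\\d+)$", p))[[1]]
      segs <- rbind(segs, data.frame(label = m[2], start = as.integer(m[3]),
                                     end = as.integer(m[4])))
    }
  }
  # insert the implied SPACE regions
  out <- segs[order(segs$start), , drop = FALSE]
  spaces <- NULL
  for (k in seq_len(nrow(out))) {
    gs <- out$end[k] + 1L
    ge <- if (k < nrow(out)) out$start[k + 1L] - 1L else mature_length
    if (ge - gs + 1L >= min_space_len)
      spaces <- rbind(spaces, data.frame(label = "SPACE", start = gs, end = ge))
  }
  res <- rbind(out, spaces)
  res[order(res$start), , drop = FALSE]
}

# non-anchor block columns that must vary somewhere in the cohort, as
# (block, rel) pairs; anchor and feature-bearing columns are excluded
variable_block_columns <- function() {
  rbind(data.frame(block = "B1", rel = c(3:6, 8, 9, 11, 12)),
        data.frame(block = "B2", rel = c(1, 2, 4:7, 9:27)),
        data.frame(block = "B3", rel = c(2:4, 6:8, 10, 13:18, 20:24, 26:28)))
}

# mature position of a block column for a protein with given hx/fy
block_position <- function(block, rel, hx, fy) {
  switch(block,
         B1 = rel,
         B2 = hx + B2_OFFSET + rel,
         B3 = fy + B3_OFFSET + rel)
}

block_consensus_letter <- function(block, rel) {
  substr(switch(block, B1 = B1_CONS, B2 = B2_CONS, B3 = B3_CONS), rel, rel)
}

GROUP2_M2 <- c(25L, 31L, 37L, 43L, 49L, 55L, 61L, 67L, 73L, 79L, 85L, 91L, 97L)
GROUP2_M3 <- c(26L, 32L, 38L, 44L, 50L, 56L, 62L, 68L, 74L, 80L, 86L, 92L,
               98L, 104L, 145L, 151L, 157L, 163L)

#' Build the synthetic stand-in cohort for the published 31-protein table
#'
#' Constructs 31 full-length synthetic LPMO sequences whose planted truth
#' reproduces [lpmo_table1()] row for row, together with the emulated
#' profile-search hit table (mining plus accessory domains), the expected
#' architectures and the curated reference annotations. Deterministic for
#' a fixed seed; the bundled `inst/extdata` fixtures are this cohort at
#' the default seed.
#'
#' @param seed integer seed for the random spacer content.
#' @return List `records` (full-length `protein_records`), `truth`
#'   (per-protein plant table), `hits` (`domain_hits`), `layouts` (named
#'   list of expected architecture segment tables), `references`
#'   (a [reference_set]), `design` (the feature design table).
#' @export
make_table1_cohort <- function(seed = 20240624L) {
  t1 <- lpmo_table1()
  design <- cohort_design()
  layouts_txt <- cohort_layouts()
  n <- nrow(t1)

  # deterministic assignment of forced variation in block columns:
  # three carriers per column among the eligible proteins
  vb <- variable_block_columns()
  group2_clones <- c("GL0681738", "GL0089352")
  eligible <- setdiff(t1$id, group2_clones)
  eligible_b1 <- setdiff(eligible, c("GL0247266", "GL0183513"))
  overrides <- setNames(vector("list", n), t1$id)
  for (k in seq_len(nrow(vb))) {
    pool <- if (vb$block[k] == "B1") eligible_b1 else eligible
    carriers <- pool[1 + ((2L * k + c(0L, 9L, 19L)) %% length(pool))]
    cons <- block_consensus_letter(vb$block[k], vb$rel[k])
    for (id in carriers) {
      i <- match(id, t1$id)
      pos <- block_position(vb$block[k], vb$rel[k], t1$hx[i], t1$fy[i])
      # skip columns a protein does not carry (truncated B2 tail)
      if (vb$block[k] == "B2" && pos >= t1$fy[i] - 18L) next
      overrides[[id]] <- rbind(overrides[[id]],
                               data.frame(pos = pos,
                                          letter = VARIANT_MAP[[cons]],
                                          stringsAsFactors = FALSE))
    }
  }
  # the study's two experimentally sequenced N-termini
  overrides[["GL0183513"]] <- rbind(overrides[["GL0183513"]],
                                    data.frame(pos = 3:5,
                                               letter = c("Y", "I", "Q")))

  records <- NULL; truths <- NULL; layouts <- list()
  group2_mature <- NULL; group2_signal <- NULL
  with_seed(seed, {
    for (i in seq_len(n)) {
      id <- t1$id[i]
      L <- t1$mature_length[i]
      hx <- t1$hx[i]; fy <- t1$fy[i]
      cat_end <- fy + 6L
      sig_len <- t1$full_length[i] - L
      des <- design[design$id == id, ]
      n_cat <- t1$cys_catalytic[i]
      n_extra <- t1$cys_full[i] - n_cat
      cys_cat <- if (n_cat > 0)
        seq.int(16L + ((i - 1L) %% 5L), by = 5L, length.out = n_cat) else integer()
      tail_room <- L - cat_end
      cys_tail <- integer(); extra_in_signal <- n_extra
      if (n_extra > 0 && tail_room >= 30L + 7L * n_extra) {
        cys_tail <- seq.int(cat_end + 20L, by = 7L, length.out = n_extra)
        extra_in_signal <- 0L
      }

      if (id %in% group2_clones) {
        # near-clones of the first group-2 protein with designed mutations
        chars <- group2_mature
        muts <- if (id == "GL0681738") GROUP2_M2 else GROUP2_M3
        for (p in muts) chars[p] <- VARIANT_MAP[[chars[p]]]
        if (id == "GL0089352") {
          chars <- c(chars[1:99], chars[101:105], "T", chars[106:length(chars)])
        }
        sig <- group2_signal
      } else {
        built <- build_mature(L, hx, fy, des$diag, des$triad, des$alanine,
                              des$polar, POLAR_VARIANTS[1 + (i %% 4)],
                              cys_cat, cys_tail,
                              block_overrides = overrides[[id]],
                              special_rel11 = des$special_rel11)
        chars <- repair_polar(built$mature,
                              allowed_start = if (des$polar) hx + 26L else NA,
                              protected = built$protected)
        sig <- signal_chars(sig_len, extra_in_signal)
        if (id == "GL0393374") { group2_mature <- chars; group2_signal <- sig }
      }
      full <- paste(c(sig, chars), collapse = "")
      rec <- protein_records(id, full,
                             sprintf("synthetic stand-in, group %s", des$group),
                             source = "synthetic_table1")
      records <- rbind(records, rec)
      layouts[[id]] <- parse_layout(layouts_txt[[id]], cat_end, L)
      truths <- rbind(truths, data.frame(
        id = id, group = des$group, is_lpmo = TRUE, signal_length = sig_len,
        full_length = nchar(full), mature_length = L, hx = hx, fy = fy,
        specificity = if (des$diag == "R") "cellulose" else "chitin",
        triad_complete = des$triad == "complete",
        has_alanine = des$alanine, has_polar = des$polar,
        n_cys_catalytic = n_cat, n_cys_full = t1$cys_full[i],
        architecture = arch_string_of(layouts[[id]]),
        stringsAsFactors = FALSE))
    }
  })
  class(records) <- c("protein_records", "data.frame")
  hits <- make_hit_table(records, truths, layouts, seed = seed)
  list(records = records, truth = truths, hits = hits, layouts = layouts,
       references = make_reference_set(), design = design)
}

#' Write the cohort fixtures as plain-text files
#'
#' Writes the synthetic stand-in cohort to `dir` as
#' `synthetic_table1_lpmos.fasta`, `synthetic_table1_domtbl.txt`,
#' `synthetic_reference_annotations.tsv` and `synthetic_table1_truth.tsv`.
#'
#' @param dir output directory (created if missing).
#' @param cohort a [make_table1_cohort()] result (default cohort if NULL).
#' @return `dir`, invisibly.
#' @export
write_table1_fixtures <- function(dir, cohort = NULL) {
  cohort <- cohort %||% make_table1_cohort()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(cohort$records, file.path(dir, "synthetic_table1_lpmos.fasta"))
  write_domain_hits(cohort$hits, file.path(dir, "synthetic_table1_domtbl.txt"))
  write_reference_set(cohort$references,
                      file.path(dir, "synthetic_reference_annotations.tsv"))
  utils::write.table(cohort$truth,
                     file.path(dir, "synthetic_table1_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Path to a bundled synthetic fixture file
#' @param file file name under the package's `extdata`.
#' @return Absolute path.
#' @export
lpmo_fixture <- function(file) {
  p <- system.file("extdata", file, package = "lpmominer")
  if (!nzchar(p)) stop_lpmo("lpmominer_io", "no bundled fixture '%s'", file)
  p
}
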