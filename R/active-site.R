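#' Reference annotation tables
#'
#' Alignment-based active-site mapping needs a small curated set of mature
#' reference LPMOs with known anchor positions: the second histidine of
#' the histidine brace (`hx`), the conserved aromatic (`fy`, Phe or Tyr),
#' the substrate-specificity diagnostic position (the homolog of CBP21
#' Ile180: Ile/Val in chitin-active, Arg in cellulose-active AA10s), the
#' three tryptophans of the triad below the copper site, and the conserved
#' alanine packed against the active site. Every reference sequence starts
#' with the catalytic His1.
#'
#' @param ref_id identifiers.
#' @param sequence mature sequences (His at position 1).
#' @param hx,fy,diagnostic_pos,alanine_anchor 1-based mature positions.
#' @param triad list (or comma-joined string) of three positions.
#' @param substrate `"chitin"` or `"cellulose"`.
#' @return A `data.frame` of class `reference_set`.
#' @export
reference_set <- function(ref_id, sequence, hx, fy, diagnostic_pos,
                          triad, alanine_anchor, substrate) {
  if (is.list(triad)) triad <- vapply(triad, paste, "", collapse = ",")
  rs <- data.frame(ref_id = ref_id, sequence = toupper(sequence),
                   hx = as.integer(hx), fy = as.integer(fy),
                   diagnostic_pos = as.integer(diagnostic_pos),
                   triad = as.character(triad),
                   alanine_anchor = as.integer(alanine_anchor),
                   substrate = substrate, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rs))) {
    s <- rs$sequence[i]
    if (substr(s, 1, 1) != "H" || substr(s, rs$hx[i], rs$hx[i]) != "H")
      stop_lpmo("lpmominer_validation",
                "reference '%s': H1/Hx positions must hold histidine", rs$ref_id[i])
    if (!substr(s, rs$fy[i], rs$fy[i]) %in% c("F", "Y"))
      stop_lpmo("lpmominer_validation",
                "reference '%s': Fy position must hold Phe or Tyr", rs$ref_id[i])
    if (max(ref_triad(rs, i), rs$fy[i], rs$diagnostic_pos[i],
            rs$alanine_anchor[i]) > nchar(s))
      stop_lpmo("lpmominer_validation",
                "reference '%s': anchor position outside sequence", rs$ref_id[i])
  }
  class(rs) <- c("reference_set", "data.frame")
  rs
}

ref_triad <- function(refs, i) as.integer(strsplit(refs$triad[i], ",")[[1]])

#' Read / write a reference annotation table (TSV)
#' @param path TSV with columns ref_id, sequence, hx, fy, diagnostic_pos,
#'   triad (comma-joined), alanine_anchor, substrate.
#' @return A `reference_set`; `write_reference_set` returns `path`.
#' @export
read_reference_set <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  reference_set(tab$ref_id, tab$sequence, tab$hx, tab$fy,
                tab$diagnostic_pos, tab$triad, tab$alanine_anchor,
                tab$substrate)
}

#' @rdname read_reference_set
#' @param refs a `reference_set`.
#' @export
write_reference_set <- function(refs, path) {
  utils::write.table(as.data.frame(refs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Motif mapping concerns only the catalytic region: alignments against a
# reference are computed on the mature prefix (reference length plus a
# margin) so that long accessory tails of multidomain proteins neither
# slow the DP down nor drag the score below the positivity gate.
catalytic_prefix <- function(mature, ref_seq, margin = 120L) {
  substr(mature, 1L, min(nchar(mature), nchar(ref_seq) + margin))
}

#' Derive the mature sequence (signal-peptide removal, His1 at N-terminus)
#'
#' Secreted AA10 LPMOs begin with the catalytic histidine once the signal
#' peptide is cleaved. Candidate cleavage points are the histidines at
#' full-sequence positions `sp_min + 1` to `sp_max + 1`; each candidate
#' mature sequence is aligned to every reference and a candidate is valid
#' when its first residue occupies the reference His1 column with a
#' positive alignment score. The best-scoring valid candidate wins.
#'
#' @param record one-row `protein_records` table.
#' @param reference_set a [reference_set].
#' @param sp_min,sp_max signal-peptide length bounds (residues removed).
#' @param ... passed to [global_align()].
#' @return List of class `mature_derivation`: `record_id`, `signal_length`,
#'   `mature`, `ref_id`, `score`.
#' @export
derive_mature <- function(record, reference_set, sp_min = 10L, sp_max = 68L, ...) {
  if (sp_min >= sp_max)
    stop_lpmo("lpmominer_validation", "sp_min must be below sp_max")
  full <- record$residues
  window <- seq.int(sp_min + 1L, min(sp_max + 1L, nchar(full)))
  cand <- window[seq_chars(full)[window] == "H"]
  if (!length(cand))
    stop_lpmo("lpmominer_no_mature",
              "record '%s': no histidine in the signal-cleavage window [%d,%d]",
              record$id, sp_min + 1L, sp_max + 1L)
  best <- NULL
  for (cp in cand) {
    mature <- substr(full, cp, nchar(full))
    for (i in seq_len(nrow(reference_set))) {
      al <- global_align(reference_set$sequence[i],
                         catalytic_prefix(mature, reference_set$sequence[i]),
                         a_id = reference_set$ref_id[i], b_id = record$id, ...)
      if (al$score <= 0) next
      h1 <- transfer_positions(al, 1L)
      if (!is.na(h1) && h1 == 1L &&
          (is.null(best) || al$score > best$score)) {
        best <- list(record_id = record$id, signal_length = cp - 1L,
                     mature = mature, ref_id = reference_set$ref_id[i],
                     score = al$score)
      }
    }
  }
  if (is.null(best))
    stop_lpmo("lpmominer_no_mature",
              "record '%s': no cleavage candidate aligns to the reference His1",
              record$id)
  structure(best, class = "mature_derivation")
}

#' Map the H1-Hx-Fy active-site motif onto a mature sequence
#'
#' Aligns the mature sequence (His1 at position 1) to the highest-scoring
#' reference and transfers the reference `hx` and `fy` columns. The mapped
#' Hx must be histidine and the mapped Fy must be phenylalanine or
#' tyrosine (some AA10s carry Tyr at the aromatic position; the feature is
#' still reported as Fy).
#'
#' @param mature mature sequence string (must start with H).
#' @param reference_set a [reference_set].
#' @param record_id label carried on the report.
#' @param ... passed to [global_align()].
#' @return List of class `active_site`: `record_id`, `hx`, `fy`,
#'   `ref_id`, `alignment` (reference as `a`, mature as `b`).
#' @export
map_active_site <- function(mature, reference_set, record_id = "query", ...) {
  if (substr(mature, 1, 1) != "H")
    stop_lpmo("lpmominer_validation", "mature sequence must start with His1")
  alns <- lapply(seq_len(nrow(reference_set)), function(i)
    global_align(reference_set$sequence[i],
                 catalytic_prefix(mature, reference_set$sequence[i]),
                 a_id = reference_set$ref_id[i], b_id = record_id, ...))
  scores <- vapply(alns, `[[`, 0, "score")
  i <- which.max(scores)
  al <- alns[[i]]
  if (al$score <= 0)
    stop_lpmo("lpmominer_motif",
              "'%s': no reference aligns with positive score", record_id)
  hx <- transfer_positions(al, reference_set$hx[i])
  fy <- transfer_positions(al, reference_set$fy[i])
  mchars <- seq_chars(mature)
  if (is.na(hx) || mchars[hx] != "H")
    stop_lpmo("lpmominer_motif",
              "'%s': reference Hx column maps to %s, not histidine", record_id,
              if (is.na(hx)) "a gap" else sprintf("'%s'", mchars[hx]))
  if (is.na(fy) || !mchars[fy] %in% c("F", "Y"))
    stop_lpmo("lpmominer_motif",
              "'%s': reference Fy column maps to %s, not Phe/Tyr", record_id,
              if (is.na(fy)) "a gap" else sprintf("'%s'", mchars[fy]))
  structure(list(record_id = record_id, hx = hx, fy = fy,
                 ref_id = al$a_id, ref_index = i, alignment = al),
            class = "active_site")
}

# Map an arbitrary reference position through the stored alignment.
map_ref_position <- function(active_site, ref_pos) {
  transfer_positions(active_site$alignment, as.integer(ref_pos))
}

#' Substrate-specificity call from the diagnostic residue
#'
#' Reads the mature residue homologous to the reference diagnostic
#' position (CBP21 Ile180): Ile or Val calls chitin, Arg calls cellulose,
#' anything else (or a gap) is ambiguous.
#'
#' @param mature mature sequence.
#' @param active_site result of [map_active_site()].
#' @param reference_set the [reference_set] used for mapping.
#' @return List `position`, `residue`, `call`.
#' @export
diagnose_specificity <- function(mature, active_site, reference_set) {
  pos <- map_ref_position(active_site,
                          reference_set$diagnostic_pos[active_site$ref_index])
  residue <- if (is.na(pos)) NA_character_ else substr(mature, pos, pos)
  call <- if (is.na(residue)) "ambiguous"
          else if (residue %in% c("I", "V")) "chitin"
          else if (residue == "R") "cellulose"
          else "ambiguous"
  list(position = pos, residue = residue, call = call)
}

#' Detect the tryptophan triad below the copper site
#'
#' @inheritParams diagnose_specificity
#' @return List `positions` (mapped, NA where gapped), `found` (positions
#'   that hold Trp), `complete` (all three are Trp).
#' @export
detect_triad <- function(mature, active_site, reference_set) {
  pos <- map_ref_position(active_site,
                          ref_triad(reference_set, active_site$ref_index))
  res <- ifelse(is.na(pos), NA, substr(rep(mature, 3), pos, pos))
  found <- pos[!is.na(res) & res == "W"]
  list(positions = pos, found = found,
       complete = length(found) == 3L)
}

#' Detect the conserved active-site alanine
#'
#' @inheritParams diagnose_specificity
#' @return `TRUE` iff the mature position homologous to the reference
#'   alanine anchor holds Ala; gaps give `FALSE`.
#' @export
detect_conserved_alanine <- function(mature, active_site, reference_set) {
  pos <- map_ref_position(active_site,
                          reference_set$alanine_anchor[active_site$ref_index])
  !is.na(pos) && substr(mature, pos, pos) == "A"
}

#' Scan for the polar motif of chitin-active bacterial LPMOs
#'
#' Degenerate 7-position pattern `[YW][EN]PQS[VL]E`. Bracket positions
#' (1, 2, 6) must match one of their alternatives exactly; up to
#' `max_mismatch` mismatches are tolerated across the fixed positions
#' (3, 4, 5, 7). The first (leftmost) match wins.
#'
#' @param mature mature sequence.
#' @param max_mismatch tolerated mismatches at fixed positions.
#' @return List `start`, `end`, `match` or `NULL` when absent.
#' @export
scan_polar_motif <- function(mature, max_mismatch = 1L) {
  chars <- seq_chars(mature)
  n <- length(chars)
  if (n < 7) return(NULL)
  alts <- list(c("Y", "W"), c("E", "N"), "P", "Q", "S", c("V", "L"), "E")
  fixed <- c(3L, 4L, 5L, 7L)
  for (s in seq_len(n - 6L)) {
    w <- chars[s:(s + 6L)]
    if (!w[1] %in% alts[[1]] || !w[2] %in% alts[[2]] || !w[6] %in% alts[[6]])
      next
    mm <- sum(vapply(fixed, function(k) !w[k] %in% alts[[k]], logical(1)))
    if (mm <= max_mismatch)
      return(list(start = s, end = s + 6L,
                  match = paste(w, collapse = "")))
  }
  NULL
}

GATEKEEPER <- "VADTGNAFY"

#' Scan for the gatekeeper sequence
#'
#' Slides a 9-residue window over the mature sequence and scores
#' case-insensitive identity against the gatekeeper consensus
#' `VADTGNAFY`; the best window (leftmost on ties) is reported when its
#' identity reaches `min_matches`/9.
#'
#' @param mature mature sequence.
#' @param min_matches required identities out of 9.
#' @return List `start`, `end`, `similarity` or `NULL`.
#' @export
scan_gatekeeper <- function(mature, min_matches = 6L) {
  gk <- seq_chars(GATEKEEPER)
  chars <- seq_chars(toupper(mature))
  n <- length(chars)
  if (n < 9) return(NULL)
  best_s <- 0L; best_m <- -1L
  for (s in seq_len(n - 8L)) {
    m <- sum(chars[s:(s + 8L)] == gk)
    if (m > best_m) { best_m <- m; best_s <- s }
  }
  if (best_m < min_matches) return(NULL)
  list(start = best_s, end = best_s + 8L, similarity = best_m / 9)
}

#' Cysteine and disulfide-capacity report
#'
#' Counts cysteines in the full-length protein and within the catalytic
#' domain of the mature sequence; the disulfide capacity is
#' `floor(n_catalytic / 2)`.
#'
#' @param record one-row `protein_records` table (full-length sequence).
#' @param mature_derivation result of [derive_mature()].
#' @param catalytic_span integer `c(from, to)` in mature coordinates.
#' @return List `record_id`, `n_full`, `n_catalytic`, `max_bridges`.
#' @export
cysteine_report <- function(record, mature_derivation, catalytic_span) {
  mat <- mature_derivation$mature
  if (catalytic_span[1] < 1 || catalytic_span[2] > nchar(mat))
    stop_lpmo("lpmominer_validation", "catalytic span outside mature sequence")
  n_full <- count_residue(record$residues, "C")
  n_cat <- count_residue(mat, "C", catalytic_span[1], catalytic_span[2])
  list(record_id = record$id, n_full = n_full, n_catalytic = n_cat,
       max_bridges = n_cat %/% 2L)
}

#' Catalytic-domain span implied by the active-site motif
#'
#' The catalytic domain is taken to run from His1 through the conserved
#' aspartate six residues beyond the Fy aromatic (clipped to the mature
#' length); this matches the 151-197 residue catalytic modules typical of
#' AA10 enzymes.
#'
#' @param active_site result of [map_active_site()].
#' @param mature_length length of the mature sequence.
#' @return Integer `c(1, end)`.
#' @export
catalytic_domain_span <- function(active_site, mature_length) {
  c(1L, min(active_site$fy + 6L, as.integer(mature_length)))
}
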