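#' BLOSUM62 substitution scores for the 21-letter alphabet
#'
#' The standard BLOSUM62 matrix (half-bit scores) restricted to the 20
#' amino-acid letters plus X, built in code so the package carries no
#' binary data. This is the default substitution table for all pairwise
#' and star alignments.
#'
#' @return A symmetric 21x21 integer matrix with dimnames [AA_LETTERS].
#' @export
blosum62 <- function() {
  vals <- c(
     4, 0,-2,-1,-2, 0,-2,-1,-1,-1,-1,-2,-1,-1,-1, 1, 0, 0,-3,-2,-1,
     0, 9,-3,-4,-2,-3,-3,-1,-3,-1,-1,-3,-3,-3,-3,-1,-1,-1,-2,-2,-1,
    -2,-3, 6, 2,-3,-1,-1,-3,-1,-4,-3, 1,-1, 0,-2, 0,-1,-3,-4,-3,-1,
    -1,-4, 2, 5,-3,-2, 0,-3, 1,-3,-2, 0,-1, 2, 0, 0,-1,-2,-3,-2,-1,
    -2,-2,-3,-3, 6,-3,-1, 0,-3, 0, 0,-3,-4,-3,-3,-2,-2,-1, 1, 3,-1,
     0,-3,-1,-2,-3, 6,-2,-4,-2,-4,-3, 0,-2,-2,-2, 0,-2,-3,-2,-3,-1,
    -2,-3,-1, 0,-1,-2, 8,-3,-1,-3,-2, 1,-2, 0, 0,-1,-2,-3,-2, 2,-1,
    -1,-1,-3,-3, 0,-4,-3, 4,-3, 2, 1,-3,-3,-3,-3,-2,-1, 3,-3,-1,-1,
    -1,-3,-1, 1,-3,-2,-1,-3, 5,-2,-1, 0,-1, 1, 2, 0,-1,-2,-3,-2,-1,
    -1,-1,-4,-3, 0,-4,-3, 2,-2, 4, 2,-3,-3,-2,-2,-2,-1, 1,-2,-1,-1,
    -1,-1,-3,-2, 0,-3,-2, 1,-1, 2, 5,-2,-2, 0,-1,-1,-1, 1,-1,-1,-1,
    -2,-3, 1, 0,-3, 0, 1,-3, 0,-3,-2, 6,-2, 0, 0, 1, 0,-3,-4,-2,-1,
    -1,-3,-1,-1,-4,-2,-2,-3,-1,-3,-2,-2, 7,-1,-2,-1,-1,-2,-4,-3,-1,
    -1,-3, 0, 2,-3,-2, 0,-3, 1,-2, 0, 0,-1, 5, 1, 0,-1,-2,-2,-1,-1,
    -1,-3,-2, 0,-3,-2, 0,-3, 2,-2,-1, 0,-2, 1, 5,-1,-1,-3,-3,-2,-1,
     1,-1, 0, 0,-2, 0,-1,-2, 0,-2,-1, 1,-1, 0,-1, 4, 1,-2,-3,-2,-1,
     0,-1,-1,-1,-2,-2,-2,-1,-1,-1,-1, 0,-1,-1,-1, 1, 5, 0,-2,-2,-1,
     0,-1,-3,-2,-1,-3,-3, 3,-2, 1, 1,-3,-2,-2,-3,-2, 0, 4,-3,-1,-1,
    -3,-2,-4,-3, 1,-2,-2,-3,-3,-2,-1,-4,-4,-2,-3,-3,-2,-3,11, 2,-1,
    -2,-2,-3,-2, 3,-3, 2,-1,-2,-1,-1,-2,-3,-1,-2,-2,-2,-1, 2, 7,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1)
  matrix(vals, 21, 21, byrow = TRUE, dimnames = list(AA_LETTERS, AA_LETTERS))
}

encode_seq <- function(s, alphabet) {
  idx <- match(seq_chars(s), alphabet)
  if (anyNA(idx))
    stop_lpmo("lpmominer_validation",
              "sequence contains a letter outside the substitution table alphabet")
  as.integer(idx)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch / Gotoh global alignment. A gap of length k is
#' penalised `gap_open + k * gap_extend`. The traceback is deterministic:
#' on score ties the move preference is diagonal > up (gap in `b`) > left
#' (gap in `a`), so identical inputs always give identical alignments.
#'
#' @param a,b sequences (single strings) over the table's alphabet.
#' @param substitution_table symmetric scoring matrix with dimnames;
#'   defaults to [blosum62()].
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @param a_id,b_id optional sequence labels carried on the result.
#' @return A list of class `pairwise_alignment` with elements `a_id`,
#'   `b_id`, `a_aln`, `b_aln` (equal-length gapped strings, `-` gaps) and
#'   `score`.
#' @export
global_align <- function(a, b, substitution_table = blosum62(),
                         gap_open = 11, gap_extend = 1,
                         a_id = "a", b_id = "b") {
  if (!nzchar(a) || !nzchar(b))
    stop_lpmo("lpmominer_validation", "cannot align an empty sequence")
  alphabet <- rownames(substitution_table)
  ai <- encode_seq(a, alphabet)
  bi <- encode_seq(b, alphabet)
  res <- nw_align_cpp(ai, bi, substitution_table, gap_open, gap_extend)
  path <- res$path
  ach <- seq_chars(a)
  bch <- seq_chars(b)
  na <- cumsum(path != 2L)   # a-consuming columns
  nb <- cumsum(path != 1L)   # b-consuming columns
  a_aln <- rep("-", length(path))
  b_aln <- a_aln
  a_aln[path != 2L] <- ach[na[path != 2L]]
  b_aln[path != 1L] <- bch[nb[path != 1L]]
  structure(list(a_id = a_id, b_id = b_id,
                 a_aln = paste(a_aln, collapse = ""),
                 b_aln = paste(b_aln, collapse = ""),
                 score = res$score),
            class = "pairwise_alignment")
}

#' Transfer residue positions across a pairwise alignment
#'
#' Maps 1-based positions in sequence `a` through their alignment columns
#' to positions in sequence `b`. Positions whose column holds a gap in `b`
#' map to `NA` (the gap marker).
#'
#' @param alignment a `pairwise_alignment`.
#' @param positions_in_a integer vector of positions in the ungapped `a`.
#' @return Integer vector of positions in `b`, `NA` where `b` is gapped.
#' @export
transfer_positions <- function(alignment, positions_in_a) {
  acols <- seq_chars(alignment$a_aln)
  bcols <- seq_chars(alignment$b_aln)
  apos <- cumsum(acols != "-")
  bpos <- cumsum(bcols != "-")
  n_a <- apos[length(apos)]
  if (any(positions_in_a < 1 | positions_in_a > n_a))
    stop_lpmo("lpmominer_validation", "position outside sequence a (length %d)", n_a)
  vapply(positions_in_a, function(p) {
    col <- match(p, apos)  # first column where a reaches position p = the residue column
    if (bcols[col] == "-") NA_integer_ else bpos[col]
  }, integer(1))
}

#' Center-star multiple sequence alignment
#'
#' Progressive star alignment: every sequence is aligned pairwise to a
#' center sequence and the pairwise alignments are merged into common
#' columns under the "once a gap, always a gap" rule. Deterministic and
#' adequate for homologous single-family protein sets; the center defaults
#' to the longest sequence (first on ties).
#'
#' @param records a `protein_records` table with at least two rows.
#' @param center_id id of the center sequence, or `NULL` for the default.
#' @param substitution_table,gap_open,gap_extend see [global_align()].
#' @return A list of class `protein_msa`: `ids`, `aln` (named character
#'   vector of equal-length gapped rows), `center_id`.
#' @export
star_msa <- function(records, center_id = NULL,
                     substitution_table = blosum62(),
                     gap_open = 11, gap_extend = 1) {
  if (nrow(records) < 2)
    stop_lpmo("lpmominer_validation", "star MSA needs at least two sequences")
  if (is.null(center_id))
    center_id <- records$id[which.max(nchar(records$residues))]
  if (!center_id %in% records$id)
    stop_lpmo("lpmominer_validation", "center sequence '%s' not found", center_id)
  center <- records$residues[records$id == center_id]
  others <- records[records$id != center_id, , drop = FALSE]
  Lc <- nchar(center)

  alns <- lapply(seq_len(nrow(others)), function(k)
    global_align(center, others$residues[k], substitution_table,
                 gap_open, gap_extend, a_id = center_id, b_id = others$id[k]))

  # ins[[k]][i+1] = gap columns inserted before center position i+1
  # (i = 0..Lc; the last slot counts trailing insertions).
  ins_counts <- lapply(alns, function(al) {
    acols <- seq_chars(al$a_aln)
    slot <- cumsum(acols != "-") + (acols == "-")  # gap belongs to the next residue slot
    counts <- integer(Lc + 1)
    gap_slots <- slot[acols == "-"]
    # gaps after the last center residue fall in slot Lc+1
    gap_slots[gap_slots > Lc + 1] <- Lc + 1
    for (s in gap_slots) counts[s] <- counts[s] + 1L
    counts
  })
  master <- Reduce(pmax, ins_counts, integer(Lc + 1))

  pad_row <- function(al, counts) {
    acols <- seq_chars(al$a_aln)
    bcols <- seq_chars(al$b_aln)
    # split b columns into Lc+1 insertion chunks + residue columns
    out <- character(0)
    idx <- 1L
    for (i in seq_len(Lc + 1)) {
      n_ins <- counts[i]
      chunk <- if (n_ins > 0) bcols[idx:(idx + n_ins - 1)] else character(0)
      idx <- idx + n_ins
      out <- c(out, chunk, rep("-", master[i] - n_ins))
      if (i <= Lc) {  # the column carrying center residue i
        out <- c(out, bcols[idx])
        idx <- idx + 1L
      }
    }
    paste(out, collapse = "")
  }

  center_row <- {
    out <- character(0)
    cch <- seq_chars(center)
    for (i in seq_len(Lc + 1)) {
      out <- c(out, rep("-", master[i]))
      if (i <= Lc) out <- c(out, cch[i])
    }
    paste(out, collapse = "")
  }

  rows <- c(setNames(list(center_row), center_id),
            setNames(lapply(seq_along(alns),
                            function(k) pad_row(alns[[k]], ins_counts[[k]])),
                     others$id))
  aln <- unlist(rows)[records$id]  # restore input order
  structure(list(ids = records$id, aln = aln, center_id = center_id),
            class = "protein_msa")
}

msa_matrix <- function(msa) {
  do.call(rbind, lapply(msa$aln, seq_chars))
}

#' Fully (or near-fully) conserved alignment columns
#'
#' Reports columns whose most frequent non-gap residue is shared by at
#' least `min_fraction` of the rows; at `min_fraction = 1` the residue
#' must be present and identical in every row (columns containing any gap
#' are excluded there).
#'
#' @param msa a `protein_msa`.
#' @param min_fraction required fraction of rows, in (0, 1].
#' @param anchor_id row whose (ungapped) residue numbering anchors the
#'   reported positions; defaults to the MSA center.
#' @return `data.frame` with `column`, `residue`, `anchor_pos` (NA when
#'   the anchor row is gapped in that column).
#' @export
conserved_columns <- function(msa, min_fraction = 1, anchor_id = NULL) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop_lpmo("lpmominer_validation", "min_fraction must lie in (0,1]")
  anchor_id <- anchor_id %||% msa$center_id
  mat <- msa_matrix(msa)
  nr <- nrow(mat)
  anchor_row <- mat[match(anchor_id, msa$ids), ]
  anchor_pos <- cumsum(anchor_row != "-")
  keep <- integer(0); res <- character(0); apos <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    if (!length(nongap)) next
    tab <- table(nongap)
    modal <- names(tab)[which.max(tab)]
    if (max(tab) >= min_fraction * nr) {
      keep <- c(keep, j)
      res <- c(res, modal)
      apos <- c(apos, if (anchor_row[j] == "-") NA_integer_ else anchor_pos[j])
    }
  }
  data.frame(column = keep, residue = res, anchor_pos = apos,
             stringsAsFactors = FALSE)
}

#' Percent identity of a multiple alignment
#'
#' Defined as the fully-conserved-column fraction: 100 x (columns whose
#' residue is identical and non-gap in all rows) / (columns with at least
#' one non-gap residue), rounded to one decimal.
#'
#' @param msa a `protein_msa` with at least two rows.
#' @return A single percentage.
#' @export
percent_identity <- function(msa) {
  if (length(msa$aln) < 2)
    stop_lpmo("lpmominer_validation", "identity needs at least two rows")
  mat <- msa_matrix(msa)
  some_res <- apply(mat, 2, function(col) any(col != "-"))
  full_cons <- apply(mat, 2, function(col)
    all(col != "-") && length(unique(col)) == 1)
  round(100 * sum(full_cons) / sum(some_res), 1)
}

#' Write / read an MSA in aligned-FASTA
#' @param msa a `protein_msa`.
#' @param path file path.
#' @return `path` invisibly; `read_msa` returns a `protein_msa`.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::AAStringSet(msa$aln)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  aln <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  if (length(unique(nchar(aln))) != 1)
    stop_lpmo("lpmominer_format", "aligned FASTA rows have unequal lengths")
  structure(list(ids = names(aln), aln = aln, center_id = names(aln)[1]),
            class = "protein_msa")
}

# Extract the ungapped sequence of one MSA row.
ungap_row <- function(msa, id) gsub("-", "", msa$aln[[id]], fixed = TRUE)
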