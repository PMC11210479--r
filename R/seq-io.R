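#' Protein record tables
#'
#' A protein record set is a plain `data.frame` with one row per protein and
#' columns `id` (unique token), `description` (free text), `residues`
#' (upper-case sequence over the 20 amino-acid letters plus `X`) and
#' `source` (free-text provenance tag). All coordinates used throughout the
#' package are 1-based and inclusive, matching the residue numbering used in
#' LPMO structure tables.
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of sequences.
#' @param description free-text descriptions (defaults to empty).
#' @param source provenance tag recorded on every record.
#' @return A validated `data.frame` of class `protein_records`.
#' @export
protein_records <- function(id, residues, description = "", source = "user") {
  rec <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(id)),
                    residues = toupper(as.character(residues)),
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  class(rec) <- c("protein_records", "data.frame")
  validate_protein_records(rec)
  rec
}

validate_protein_records <- function(rec) {
  if (anyDuplicated(rec$id))
    stop_lpmo("lpmominer_duplicate_id", "duplicate record id(s): %s",
              paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  for (i in seq_len(nrow(rec))) {
    s <- rec$residues[i]
    if (!nzchar(s))
      stop_lpmo("lpmominer_validation", "record '%s' has an empty sequence", rec$id[i])
    bad <- regexpr(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), s)
    if (bad > 0)
      stop_lpmo("lpmominer_validation",
                "record '%s' has illegal residue '%s' at position %d",
                rec$id[i], substr(s, bad, bad), bad)
  }
  invisible(rec)
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and validates the result into a
#' [protein_records] table. Header order is preserved, residues are
#' upper-cased and `*` translation-stop symbols are stripped from the ends
#' of sequences (never from the middle, where they indicate a broken gene
#' model and are reported as illegal residues).
#'
#' @param path path to a FASTA file.
#' @param source provenance tag stored on every record.
#' @return A `protein_records` data frame.
#' @export
read_fasta <- function(path, source = basename(path)) {
  if (!file.exists(path))
    stop_lpmo("lpmominer_io", "FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    stop_lpmo("lpmominer_format", "not parseable as FASTA (%s): %s",
                              conditionMessage(e), path))
  if (length(set) == 0)
    stop_lpmo("lpmominer_format", "FASTA file contains no sequences: %s", path)
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop_lpmo("lpmominer_format", "header-only FASTA entry with no sequence: %s",
              names(set)[!nzchar(seqs)][1])
  # strip stop symbols from sequence ends only
  seqs <- sub("\\*+$", "", sub("^\\*+", "", seqs))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_records(id, seqs, desc, source = source)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: the written file reads back to identical
#' records (id, description and residues).
#'
#' @param records a `protein_records` table.
#' @param path output path.
#' @param line_width residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (nrow(records) == 0) {
    warning("writing an empty FASTA file: ", path)
    cat("", file = path)
    return(invisible(path))
  }
  validate_protein_records(records)
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}

# Column indices in HMMER3's per-domain tabular output (domtblout).
DOMTBL_COLS <- list(query_id = 1L, query_len = 3L, profile_id = 4L,
                    profile_len = 6L, dom_score = 14L, dom_bias = 15L,
                    hmm_from = 16L, hmm_to = 17L, ali_from = 18L, ali_to = 19L)

#' Read profile-HMM domain hits (HMMER3 per-domain tabular dialect)
#'
#' Parses the whitespace-separated per-domain table written by
#' `hmmsearch --domtblout` (or any engine emitting the same 23-column
#' layout). `#`-prefixed comment lines are skipped. The per-domain
#' (independent) score and bias columns are used, together with the
#' profile (`hmm_from`/`hmm_to`) and query alignment (`ali_from`/`ali_to`)
#' coordinate pairs.
#'
#' @param path path to the tabular file.
#' @return A `data.frame` of class `domain_hits` with columns `query_id`,
#'   `profile_id`, `profile_length`, `domain_bitscore`, `bias`,
#'   `query_from`, `query_to`, `hmm_from`, `hmm_to`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path))
    stop_lpmo("lpmominer_io", "hit table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < DOMTBL_COLS$ali_to)
      stop_lpmo("lpmominer_format",
                "line %d: %d columns, fewer than the %d required by the per-domain layout",
                i, length(f), DOMTBL_COLS$ali_to)
    num <- function(col, what) {
      v <- suppressWarnings(as.numeric(f[col]))
      if (is.na(v))
        stop_lpmo("lpmominer_format", "line %d: non-numeric %s '%s'", i, what, f[col])
      v
    }
    data.frame(query_id = f[DOMTBL_COLS$query_id],
               profile_id = f[DOMTBL_COLS$profile_id],
               profile_length = as.integer(num(DOMTBL_COLS$profile_len, "profile length")),
               domain_bitscore = num(DOMTBL_COLS$dom_score, "domain score"),
               bias = num(DOMTBL_COLS$dom_bias, "bias"),
               query_from = as.integer(num(DOMTBL_COLS$ali_from, "query-from coordinate")),
               query_to = as.integer(num(DOMTBL_COLS$ali_to, "query-to coordinate")),
               hmm_from = as.integer(num(DOMTBL_COLS$hmm_from, "hmm-from coordinate")),
               hmm_to = as.integer(num(DOMTBL_COLS$hmm_to, "hmm-to coordinate")),
               stringsAsFactors = FALSE)
  })
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), profile_id = character(),
               profile_length = integer(), domain_bitscore = numeric(),
               bias = numeric(), query_from = integer(), query_to = integer(),
               hmm_from = integer(), hmm_to = integer(), stringsAsFactors = FALSE)
  class(hits) <- c("domain_hits", "data.frame")
  validate_domain_hits(hits)
  hits
}

validate_domain_hits <- function(hits, records = NULL) {
  bad <- hits$query_from > hits$query_to
  if (any(bad))
    stop_lpmo("lpmominer_validation", "hit %s: query_from > query_to",
              hits$query_id[bad][1])
  bad <- hits$hmm_from > hits$hmm_to
  if (any(bad))
    stop_lpmo("lpmominer_validation", "hit %s: hmm_from > hmm_to",
              hits$query_id[bad][1])
  bad <- hits$hmm_to > hits$profile_length
  if (any(bad))
    stop_lpmo("lpmominer_validation",
              "hit %s: hmm_to %d exceeds profile length %d", hits$query_id[bad][1],
              hits$hmm_to[bad][1], hits$profile_length[bad][1])
  if (!is.null(records)) {
    len <- setNames(nchar(records$residues), records$id)
    known <- hits$query_id %in% names(len)
    bad <- known & hits$query_to > len[hits$query_id]
    if (any(bad))
      stop_lpmo("lpmominer_validation",
                "hit %s: query_to %d exceeds sequence length %d",
                hits$query_id[bad][1], hits$query_to[bad][1],
                len[hits$query_id[bad][1]])
  }
  invisible(hits)
}

#' Write domain hits in the HMMER3 per-domain tabular dialect
#'
#' Emits a table that [read_domain_hits()] parses back to identical hits;
#' columns not carried by the hit table (E-values, envelope coordinates,
#' accessions) are filled with placeholders as HMMER does for undefined
#' fields.
#'
#' @param hits a `domain_hits` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# per-domain hit table (HMMER3 domtblout dialect)",
               "# query - - profile - plen ... i-score i-bias hmm_from hmm_to ali_from ali_to ..."),
             con)
  for (i in seq_len(nrow(hits))) {
    f <- rep("-", 23)
    f[DOMTBL_COLS$query_id] <- hits$query_id[i]
    f[DOMTBL_COLS$query_len] <- "0"
    f[DOMTBL_COLS$profile_id] <- hits$profile_id[i]
    f[DOMTBL_COLS$profile_len] <- as.character(hits$profile_length[i])
    f[7:13] <- c("1", "1e-10", "100.0", "1.0", "1", "1", "1e-10")
    f[DOMTBL_COLS$dom_score] <- formatC(hits$domain_bitscore[i], format = "f", digits = 1)
    f[DOMTBL_COLS$dom_bias] <- formatC(hits$bias[i], format = "f", digits = 1)
    f[DOMTBL_COLS$hmm_from] <- as.character(hits$hmm_from[i])
    f[DOMTBL_COLS$hmm_to] <- as.character(hits$hmm_to[i])
    f[DOMTBL_COLS$ali_from] <- as.character(hits$query_from[i])
    f[DOMTBL_COLS$ali_to] <- as.character(hits$query_to[i])
    f[20:23] <- c(as.character(hits$query_from[i]), as.character(hits$query_to[i]),
                  "0.99", "-")
    writeLines(paste(f, collapse = " "), con)
  }
  invisible(path)
}
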