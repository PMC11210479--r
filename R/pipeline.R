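#' Run the full mining and annotation pipeline
#'
#' Orchestrates the stages end to end: profile-hit filtering, completeness
#' classification, mature-sequence derivation, active-site motif mapping,
#' diagnostic-feature calls, cysteine reporting, domain-architecture
#' assembly and GbpA-like classification. Per-record failures are logged
#' and reported as fragment/failed rows; they never abort the run.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{records / fasta}{a `protein_records` table, or a FASTA path.}
#'     \item{hits / hit_table}{a `domain_hits` table, or a per-domain
#'       table path.}
#'     \item{references / reference_table}{a [reference_set], or a TSV
#'       path.}
#'     \item{thresholds}{optional [filter_thresholds].}
#'     \item{sp_min, sp_max}{optional signal-window bounds.}
#'     \item{min_space_len, adjacency_gap}{optional architecture
#'       parameters.}
#'   }
#' @return A list of class `lpmo_annotation`: `annotations` (one row per
#'   annotated protein, the per-protein characteristics table),
#'   `fragments` (ids and reasons), `filter_report` (per-hit filter
#'   decisions), `funnel` (stage counts), `architectures` (named list of
#'   segment tables).
#' @export
run_pipeline <- function(config) {
  records <- config$records %||%
    (if (!is.null(config$fasta)) read_fasta(config$fasta) else
       stop_lpmo("lpmominer_config", "config must name records or fasta"))
  hits <- config$hits %||%
    (if (!is.null(config$hit_table)) read_domain_hits(config$hit_table) else
       stop_lpmo("lpmominer_config", "config must name hits or hit_table"))
  refs <- config$references %||%
    (if (!is.null(config$reference_table))
       read_reference_set(config$reference_table) else
       stop_lpmo("lpmominer_config", "config must name reference annotations"))
  thresholds <- config$thresholds %||% filter_thresholds()
  sp_min <- config$sp_min %||% 10L
  sp_max <- config$sp_max %||% 68L
  min_space_len <- config$min_space_len %||% 60L
  adjacency_gap <- config$adjacency_gap %||% 10L

  validate_domain_hits(hits, records)
  lpmo_hits <- hits[hits$profile_id %in% c("LPMO_10", "LPMO10"), , drop = FALSE]
  filter_report <- apply_filter(lpmo_hits, thresholds)

  annotations <- NULL
  fragments <- NULL
  architectures <- list()
  n_pass <- 0L; n_complete <- 0L

  if (nrow(records) == 0)
    warning("empty input record set: the report will be empty")

  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    rec <- records[i, , drop = FALSE]
    fr <- filter_report[filter_report$query_id == id, , drop = FALSE]
    if (!nrow(fr) || !any(fr$passed)) next   # not mined as an LPMO
    n_pass <- n_pass + 1L
    best <- fr[fr$passed, , drop = FALSE]
    best <- best[which.max(best$domain_bitscore), , drop = FALSE]

    completeness <- classify_completeness(rec, best, refs,
                                          sp_min = sp_min, sp_max = sp_max)
    if (completeness != "complete") {
      fragments <- rbind(fragments, data.frame(id = id, reason = "profile_truncated"))
      next
    }
    row <- tryCatch({
      md <- derive_mature(rec, refs, sp_min = sp_min, sp_max = sp_max)
      site <- map_active_site(md$mature, refs, record_id = id)
      span <- catalytic_domain_span(site, nchar(md$mature))
      diag <- diagnose_specificity(md$mature, site, refs)
      triad <- detect_triad(md$mature, site, refs)
      ala <- detect_conserved_alanine(md$mature, site, refs)
      polar <- scan_polar_motif(md$mature)
      gate <- scan_gatekeeper(md$mature)
      cys <- cysteine_report(rec, md, span)

      rec_hits <- hits[hits$query_id == id, , drop = FALSE]
      rec_hits$query_from <- rec_hits$query_from - md$signal_length
      rec_hits$query_to <- rec_hits$query_to - md$signal_length
      rec_hits <- rec_hits[rec_hits$query_from >= 1 &
                             rec_hits$query_to <= nchar(md$mature), , drop = FALSE]
      rec_hits$profile_id[rec_hits$profile_id == "LPMO_10"] <- "LPMO10"
      arch <- assemble_architecture(rec_hits, nchar(md$mature),
                                    min_space_len = min_space_len,
                                    record_id = id)
      gbpa <- classify_gbpa_like(arch, adjacency_gap = adjacency_gap)
      architectures[[id]] <- arch

      data.frame(
        id = id, full_length = nchar(rec$residues),
        mature_length = nchar(md$mature), signal_length = md$signal_length,
        hx = site$hx, fy = site$fy,
        n_cys_full = cys$n_full, n_cys_catalytic = cys$n_catalytic,
        max_bridges = cys$max_bridges,
        specificity = diag$call, diagnostic_residue = diag$residue %||% NA,
        triad_complete = triad$complete, triad_found = length(triad$found),
        alanine_conserved = ala,
        polar_motif = !is.null(polar),
        gatekeeper_similarity = if (is.null(gate)) NA_real_ else gate$similarity,
        architecture = architecture_string(arch),
        n_functional_domains = count_functional_domains(arch, adjacency_gap),
        gbpa_like = gbpa$gbpa_like,
        stringsAsFactors = FALSE)
    }, lpmominer_error = function(e) {
      fragments <<- rbind(fragments,
                          data.frame(id = id, reason = conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) {
      n_complete <- n_complete + 1L
      annotations <- rbind(annotations, row)
    }
  }

  funnel <- data.frame(
    stage = c("input_records", "lpmo_hits", "passed_filter",
              "complete_annotated", "fragments"),
    count = c(nrow(records), nrow(lpmo_hits), n_pass, n_complete,
              if (is.null(fragments)) 0L else nrow(fragments)))

  structure(list(annotations = annotations, fragments = fragments,
                 filter_report = filter_report, funnel = funnel,
                 architectures = architectures),
            class = "lpmo_annotation")
}

#' Write the annotation report as TSV and JSON
#' @param result a `lpmo_annotation` object.
#' @param tsv,json output paths (either may be NULL).
#' @return `result`, invisibly.
#' @export
write_annotation_report <- function(result, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(result$annotations, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(annotations = result$annotations,
                              funnel = result$funnel),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(result)
}
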