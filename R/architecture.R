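#' Assemble domain hits into an ordered, non-overlapping architecture
#'
#' Accessory-domain hits on one mature protein are resolved into disjoint
#' labeled segments. Precedence on overlap: higher score, then longer
#' span, then smaller start; the lower-precedence segment is trimmed away
#' from the retained one (and dropped when nothing is left). Uncovered
#' gaps of at least `min_space_len` residues between/after segments are
#' reported as `SPACE` segments — the candidate Domain-X regions; 60
#' residues keeps the 88-120 residue inter-domain regions while ignoring
#' short linkers.
#'
#' @param hits `domain_hits` rows for one record, with coordinates in
#'   mature space.
#' @param mature_length length of the mature sequence.
#' @param min_space_len minimum length of a reported SPACE segment.
#' @param record_id label carried on the result.
#' @return A `data.frame` of class `architecture` with columns `label`,
#'   `start`, `end`, `score`, sorted by `start`; attribute `record_id`
#'   and `mature_length`.
#' @export
assemble_architecture <- function(hits, mature_length, min_space_len = 60L,
                                  record_id = NULL) {
  mature_length <- as.integer(mature_length)
  if (mature_length <= 0)
    stop_lpmo("lpmominer_validation", "mature_length must be positive")
  if (nrow(hits) && any(hits$query_to > mature_length))
    stop_lpmo("lpmominer_validation",
              "hit extends past the mature sequence (%d > %d)",
              max(hits$query_to), mature_length)
  record_id <- record_id %||% if (nrow(hits)) hits$query_id[1] else "query"

  segs <- data.frame(label = character(), start = integer(), end = integer(),
                     score = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    # precedence order: score desc, span desc, start asc
    span <- hits$query_to - hits$query_from + 1L
    ord <- order(-hits$domain_bitscore, -span, hits$query_from, hits$profile_id)
    taken <- logical(mature_length)
    for (i in ord) {
      pos <- hits$query_from[i]:hits$query_to[i]
      free <- pos[!taken[pos]]
      if (!length(free)) next
      # trim to the maximal free run containing the most residues
      runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
      run <- runs[[which.max(lengths(runs))]]
      taken[run] <- TRUE
      segs <- rbind(segs, data.frame(label = hits$profile_id[i],
                                     start = min(run), end = max(run),
                                     score = hits$domain_bitscore[i],
                                     stringsAsFactors = FALSE))
    }
    segs <- segs[order(segs$start), , drop = FALSE]
  }

  # SPACE segments in the uncovered gaps
  bounds <- rbind(c(0L, 0L), cbind(segs$start, segs$end), c(mature_length + 1L, 0L))
  spaces <- data.frame(label = character(), start = integer(), end = integer(),
                       score = numeric(), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(bounds) - 1L)) {
    gap_start <- bounds[k, 2L] + 1L
    gap_end <- bounds[k + 1L, 1L] - 1L
    if (gap_end - gap_start + 1L >= min_space_len)
      spaces <- rbind(spaces, data.frame(label = "SPACE", start = gap_start,
                                         end = gap_end, score = 0,
                                         stringsAsFactors = FALSE))
  }
  out <- rbind(segs, spaces)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("architecture", "data.frame"),
            record_id = record_id, mature_length = mature_length)
}

#' Architecture string, e.g. "LPMO10|GbpA_2|SPACE|Ig_like|CBM5_12"
#' @param architecture an [assemble_architecture()] result.
#' @return A single string.
#' @export
architecture_string <- function(architecture) {
  paste(architecture$label, collapse = "|")
}

#' Classify a protein as GbpA-like
#'
#' GbpA-like multidomain LPMOs carry a catalytic domain, a GbpA_2
#' bacterial-surface-binding domain, and a Domain-X region immediately
#' downstream of GbpA_2 (the sequence-level signature of the GbpA_3-like
#' domain). The call is true iff the architecture holds an LPMO10 segment,
#' a GbpA_2 segment and a SPACE segment whose start lies within
#' `adjacency_gap` residues of the GbpA_2 end.
#'
#' @param architecture an `architecture`.
#' @param adjacency_gap maximum separation (residues) between the GbpA_2
#'   end and the SPACE start.
#' @return List `gbpa_like` (flag) and `evidence` (the three segments, or
#'   `NULL`).
#' @export
classify_gbpa_like <- function(architecture, adjacency_gap = 10L) {
  lpmo <- architecture[architecture$label %in% c("LPMO10", "LPMO_10"), , drop = FALSE]
  gbpa <- architecture[architecture$label == "GbpA_2", , drop = FALSE]
  spaces <- architecture[architecture$label == "SPACE", , drop = FALSE]
  if (!nrow(lpmo) || !nrow(gbpa) || !nrow(spaces))
    return(list(gbpa_like = FALSE, evidence = NULL))
  for (g in seq_len(nrow(gbpa))) {
    adj <- spaces$start >= gbpa$end[g] &
      spaces$start - gbpa$end[g] <= adjacency_gap
    if (any(adj)) {
      ev <- rbind(lpmo[1, ], gbpa[g, ], spaces[adj, ][1, ])
      return(list(gbpa_like = TRUE, evidence = ev))
    }
  }
  list(gbpa_like = FALSE, evidence = NULL)
}

#' Count functional domains in an architecture
#'
#' Non-SPACE segments all count; SPACE segments count only when flagged as
#' Domain-X — by default, when adjacent to a GbpA_2 domain
#' (sequence-level rule), or when listed in `confirmed_domain_x`
#' (structure-level confirmation from [classify_gbpa3_like()]).
#'
#' @param architecture an `architecture`.
#' @param adjacency_gap see [classify_gbpa_like()].
#' @param confirmed_domain_x optional integer vector of SPACE segment
#'   start positions confirmed as Domain-X structurally.
#' @return Integer count.
#' @export
count_functional_domains <- function(architecture, adjacency_gap = 10L,
                                     confirmed_domain_x = integer()) {
  if (!nrow(architecture)) return(0L)
  n <- sum(architecture$label != "SPACE")
  spaces <- architecture[architecture$label == "SPACE", , drop = FALSE]
  gbpa <- architecture[architecture$label == "GbpA_2", , drop = FALSE]
  for (s in seq_len(nrow(spaces))) {
    adjacent <- nrow(gbpa) > 0 &&
      any(spaces$start[s] >= gbpa$end & spaces$start[s] - gbpa$end <= adjacency_gap)
    if (adjacent || spaces$start[s] %in% confirmed_domain_x)
      n <- n + 1L
  }
  as.integer(n)
}
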