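## Ground-truthed synthetic data generation.
##
## All generators are pure functions of (parameters, seed). Sequences are
## assembled on a shared AA10-like scaffold of three conserved blocks --
## around His1 (B1), around the second histidine Hx (B2) and around the
## aromatic Fy (B3) -- separated by variable-length random spacers, so that
## alignment-based motif mapping is exercised with realistic geometry
## (Hx and Fy offsets drawn from the ranges observed in the study cohort).
## Cysteine and histidine are excluded from all random draws and planted
## explicitly, which makes cysteine censuses and His1/Hx identification
## exact by construction.

# conserved block consensi; anchor columns are marked by position below
B1_CONS <- "HGAMESPTDRNA"                  # anchors: 1 H, 2 G, 7 P, 10 R
B2_CONS <- "TAHAIDGWSGKLNPVMSDTEGFQKGIQA"  # rel 3 = Hx (H); 8 = triad Wa;
                                           # 28 = conserved Ala (Hx+25)
B3_CONS <- "GNETWKSPWLDVADTGNAFYGQTPDKGS"  # rel 1 G, 5 Wb, 9 Wc, 12 diag,
                                           # 13-18 gatekeeper core, 19 Fy,
                                           # 20 Y, 25 D (Fy+6); rel 26-28
                                           # pad the block edge so the D
                                           # anchor is interior

# offsets of the nine family-conserved anchors relative to H1 / Hx / Fy
B2_OFFSET <- -3L   # B2 rel r sits at mature position hx + (r - 3)
B3_OFFSET <- -19L  # B3 rel r sits at mature position fy + (r - 19)

RANDOM_POOL <- setdiff(AA_LETTERS, c("C", "H", "X"))
SIGNAL_POOL <- c("A", "L", "V", "F", "I", "S", "T", "G", "P")
POLAR_VARIANTS <- c("YEPQSVE", "WNPQSLE", "YEPQSLE", "WEPQSVE")

# conservative substitution used when a block column is forced to vary
VARIANT_MAP <- c(A = "S", D = "E", E = "D", F = "Y", G = "A", I = "L",
                 K = "R", L = "I", M = "F", N = "S", P = "A", Q = "E",
                 R = "K", S = "T", T = "N", V = "I", W = "F", Y = "F")

# nominal accessory-domain profile lengths (match states)
PROFILE_LENGTHS <- c(LPMO_10 = 190L, GbpA_2 = 96L, Fn3 = 95L, Ig_like = 90L,
                     CBM5 = 40L, CBM73 = 60L, CBM5_12 = 65L,
                     Secret_tail_C = 70L)

place_block <- function(chars, start, block_chars, max_pos) {
  idx <- seq_along(block_chars) + start - 1L
  keep <- idx <= max_pos
  chars[idx[keep]] <- block_chars[keep]
  chars
}

# Assemble one mature LPMO sequence from explicit plant parameters.
# Returns list(mature, protected) where protected are the 1-based mature
# positions that mutations must not touch.
build_mature <- function(L, hx, fy, diag_residue, triad_class, has_alanine,
                         has_polar, polar_variant, cys_catalytic_pos,
                         cys_tail_pos, block_overrides = NULL,
                         special_rel11 = NA) {
  if (fy <= hx)
    stop_lpmo("lpmominer_validation", "Fy (%d) must exceed Hx (%d)", fy, hx)
  if (fy + 6L > L)
    stop_lpmo("lpmominer_validation", "mature length %d too short for Fy %d", L, fy)
  chars <- sample(RANDOM_POOL, L, replace = TRUE)

  b2 <- seq_chars(B2_CONS)
  b3 <- seq_chars(B3_CONS)
  b1 <- seq_chars(B1_CONS)
  if (triad_class %in% c("minus_a", "minus_ab")) b2[8] <- "L"
  if (triad_class == "minus_ab") b3[5] <- "F"
  if (!has_alanine) b2[28] <- "S"
  b3[12] <- diag_residue
  if (!is.na(special_rel11)) b3[11] <- special_rel11

  b2_start <- hx + B2_OFFSET + 1L        # = hx - 2
  b3_start <- fy + B3_OFFSET + 1L        # = fy - 18
  chars <- place_block(chars, 1L, b1, L)
  chars <- place_block(chars, b2_start, b2, b3_start - 1L)  # trim at B3
  chars <- place_block(chars, b3_start, b3, L)

  protected <- c(1:12, b2_start:min(b2_start + 27L, b3_start - 1L),
                 b3_start:(fy + 6L))
  if (has_polar) {
    pol_start <- hx + 26L
    if (pol_start + 6L >= b3_start)
      stop_lpmo("lpmominer_validation",
                "no spacer room for the polar motif (Hx %d, Fy %d)", hx, fy)
    chars <- place_block(chars, pol_start, seq_chars(polar_variant), L)
    protected <- c(protected, pol_start:(pol_start + 6L))
  }
  for (p in cys_catalytic_pos) chars[p] <- "C"
  for (p in cys_tail_pos) chars[p] <- "C"
  protected <- sort(unique(c(protected, cys_catalytic_pos, cys_tail_pos)))

  if (!is.null(block_overrides))
    for (k in seq_len(nrow(block_overrides)))
      chars[block_overrides$pos[k]] <- block_overrides$letter[k]

  list(mature = chars, protected = protected)
}

# Destroy polar-motif matches outside an allowed span (deterministic).
repair_polar <- function(chars, allowed_start = NA, protected = integer()) {
  repeat {
    s <- paste(chars, collapse = "")
    hit <- scan_polar_motif(s)
    while (!is.null(hit) && !is.na(allowed_start) && hit$start == allowed_start) {
      # planted match found first: look past it
      rest <- substr(s, hit$start + 1L, nchar(s))
      nxt <- scan_polar_motif(rest)
      hit <- if (is.null(nxt)) NULL else
        list(start = nxt$start + hit$start, end = nxt$end + hit$start)
    }
    if (is.null(hit)) return(chars)
    span <- hit$start:(hit$start + 6L)
    free <- setdiff(span, protected)
    if (!length(free)) return(chars)  # fully protected: leave as is
    chars[free[1]] <- "G"
  }
}

signal_chars <- function(signal_length, n_extra_cys) {
  sig <- c("M", sample(SIGNAL_POOL, signal_length - 1L, replace = TRUE))
  if (n_extra_cys > 0) {
    pos <- seq.int(3L, by = 2L, length.out = n_extra_cys)
    if (max(pos) > signal_length)
      stop_lpmo("lpmominer_validation",
                "signal of %d residues cannot hold %d extra cysteines",
                signal_length, n_extra_cys)
    sig[pos] <- "C"
  }
  sig
}

# Sequential accessory-domain layout in mature coordinates.
plan_layout <- function(tokens, cat_end, linker = 13L, space_len = 100L) {
  segs <- data.frame(label = "LPMO10", start = 1L, end = cat_end,
                     stringsAsFactors = FALSE)
  pos <- cat_end
  for (tok in tokens) {
    if (tok == "SPACE") {
      segs <- rbind(segs, data.frame(label = "SPACE", start = pos + 1L,
                                     end = pos + space_len))
      pos <- pos + space_len
    } else {
      len <- PROFILE_LENGTHS[[tok]]
      start <- pos + if (nrow(segs) && segs$label[nrow(segs)] == "SPACE") 1L
                     else linker + 1L
      segs <- rbind(segs, data.frame(label = tok, start = start,
                                     end = start + len - 1L))
      pos <- start + len - 1L
    }
  }
  segs
}

arch_string_of <- function(layout) paste(layout$label, collapse = "|")

# Domain hits (full-ORF coordinates) implied by a layout.
layout_hits <- function(id, layout, signal_length, base_score) {
  rows <- layout[layout$label != "SPACE", , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    lab <- rows$label[k]
    profile <- if (lab == "LPMO10") "LPMO_10" else lab
    plen <- PROFILE_LENGTHS[[profile]]
    data.frame(query_id = id, profile_id = profile, profile_length = plen,
               domain_bitscore = if (profile == "LPMO_10") base_score
                                 else 60 + 5 * k,
               bias = 1.5, query_from = rows$start[k] + signal_length,
               query_to = rows$end[k] + signal_length,
               hmm_from = 1L, hmm_to = plen, stringsAsFactors = FALSE)
  }))
}

#' Generate one synthetic planted LPMO with ground truth
#'
#' Builds a signal peptide plus a mature AA10-like sequence on the shared
#' scaffold: His1, a second histidine at a realistic offset (87-156), the
#' aromatic Fy (159-227, beyond Hx), the substrate diagnostic residue
#' (Ile/Val for chitin, Arg for cellulose), the tryptophan triad, polar
#' and gatekeeper motifs, planted cysteines and accessory domains per the
#' requested architecture; point mutations are then applied at
#' `mutation_rate` to all non-planted positions.
#'
#' @param spec list with elements `id`, `specificity` (`"chitin"` or
#'   `"cellulose"`), `architecture` (character vector of accessory tokens,
#'   `"SPACE"` allowed), `mutation_rate`, and optional overrides
#'   `signal_length`, `hx`, `fy`, `n_cys_catalytic`, `n_cys_extra`,
#'   `triad_class`, `has_alanine`, `has_polar`.
#' @param seed integer seed.
#' @return List `record` (one-row [protein_records]), `truth` (one-row
#'   data.frame), `layout` (expected architecture segments, mature
#'   coordinates).
#' @export
make_lpmo <- function(spec, seed = 1L) {
  with_seed(seed, {
    specificity <- match.arg(spec$specificity, c("chitin", "cellulose"))
    rate <- spec$mutation_rate %||% 0
    if (rate < 0 || rate >= 1)
      stop_lpmo("lpmominer_validation", "mutation_rate must lie in [0,1)")
    hx <- spec$hx %||% sample(87:156, 1)
    fy <- spec$fy %||% sample(max(159L, hx + 51L):227L, 1)
    if (fy <= hx)
      stop_lpmo("lpmominer_validation", "Fy must exceed Hx")
    signal_length <- spec$signal_length %||% sample(15:45, 1)
    tokens <- spec$architecture %||% character()
    triad_class <- spec$triad_class %||%
      if (specificity == "chitin") "complete" else "minus_ab"
    has_alanine <- spec$has_alanine %||% TRUE
    has_polar <- spec$has_polar %||% (specificity == "chitin")
    diag_residue <- if (specificity == "cellulose") "R" else sample(c("I", "V"), 1)
    n_cat <- spec$n_cys_catalytic %||% sample(0:6, 1)
    n_extra <- spec$n_cys_extra %||% sample(0:2, 1)

    cat_end <- fy + 6L
    layout <- plan_layout(tokens, cat_end)
    L <- max(layout$end) + 4L
    cys_cat <- if (n_cat > 0) seq.int(16L, by = 5L, length.out = n_cat) else integer()
    tail_room <- L - cat_end
    cys_tail <- integer(); extra_in_signal <- n_extra
    if (n_extra > 0 && tail_room >= 30L + 7L * n_extra) {
      cys_tail <- seq.int(cat_end + 20L, by = 7L, length.out = n_extra)
      extra_in_signal <- 0L
    }
    built <- build_mature(L, hx, fy, diag_residue, triad_class, has_alanine,
                          has_polar,
                          POLAR_VARIANTS[1 + (seed %% length(POLAR_VARIANTS))],
                          cys_cat, cys_tail)
    chars <- built$mature
    mutable <- setdiff(seq_len(L), built$protected)
    hitpos <- mutable[stats::runif(length(mutable)) < rate]
    for (p in hitpos) {
      alt <- setdiff(RANDOM_POOL, chars[p])
      chars[p] <- sample(alt, 1)
    }
    sig <- signal_chars(signal_length, extra_in_signal)
    full <- paste(c(sig, chars), collapse = "")
    mature <- paste(chars, collapse = "")

    rec <- protein_records(spec$id %||% "SYN_LPMO",
                           full, "synthetic planted LPMO",
                           source = "synthetic")
    truth <- data.frame(id = rec$id, is_lpmo = TRUE,
                        signal_length = signal_length,
                        full_length = nchar(full), mature_length = L,
                        hx = hx, fy = fy, specificity = specificity,
                        triad_complete = triad_class == "complete",
                        has_alanine = has_alanine,
                        has_polar = !is.null(scan_polar_motif(mature)),
                        n_cys_catalytic = length(cys_cat),
                        n_cys_full = length(cys_cat) + length(cys_tail) +
                          extra_in_signal,
                        architecture = arch_string_of(layout),
                        n_mutable = length(mutable),
                        n_mutated = length(hitpos),
                        stringsAsFactors = FALSE)
    list(record = rec, truth = truth, layout = layout)
  })
}

#' Generate a mixed dataset of planted LPMOs and decoys
#'
#' Decoys are composition-matched shuffles of independently generated
#' planted sequences (so motif detection, not residue composition, is
#' what separates the classes).
#'
#' @param n_lpmo,n_decoy class counts.
#' @param mutation_rate applied to the planted LPMOs.
#' @param seed integer seed.
#' @return List `records`, `truth`, `hits` (a `domain_hits` table from
#'   [make_hit_table()]), `layouts` (per-LPMO expected architectures).
#' @export
make_dataset <- function(n_lpmo, n_decoy, mutation_rate = 0, seed = 1L) {
  archs <- list(c("GbpA_2", "SPACE", "CBM5"), character(),
                c("CBM5", "CBM73"), c("GbpA_2", "SPACE", "CBM73"),
                c("Fn3", "Ig_like"))
  lp <- lapply(seq_len(n_lpmo), function(k)
    make_lpmo(list(id = sprintf("SYN%04d", k),
                   specificity = if (k %% 5 == 0) "cellulose" else "chitin",
                   architecture = archs[[1 + (k %% length(archs))]],
                   mutation_rate = mutation_rate),
              seed = seed * 1000L + k))
  records <- if (n_lpmo) do.call(rbind, lapply(lp, `[[`, "record")) else NULL
  truth <- if (n_lpmo) do.call(rbind, lapply(lp, `[[`, "truth")) else NULL
  layouts <- setNames(lapply(lp, `[[`, "layout"),
                      vapply(lp, function(x) x$record$id, ""))

  dec <- with_seed(seed + 7L, lapply(seq_len(n_decoy), function(k) {
    tmpl <- make_lpmo(list(id = "tmpl", specificity = "chitin",
                           architecture = c("CBM5"), mutation_rate = 0),
                      seed = seed * 2000L + k)
    shuf <- paste(sample(seq_chars(tmpl$record$residues)), collapse = "")
    protein_records(sprintf("DECOY%04d", k), shuf,
                    "synthetic decoy (composition-matched shuffle)",
                    source = "synthetic")
  }))
  drecords <- if (n_decoy) do.call(rbind, dec) else NULL
  dtruth <- if (n_decoy)
    data.frame(id = drecords$id, is_lpmo = FALSE, signal_length = NA_integer_,
               full_length = nchar(drecords$residues),
               mature_length = NA_integer_, hx = NA_integer_, fy = NA_integer_,
               specificity = NA_character_, triad_complete = NA,
               has_alanine = NA, has_polar = NA,
               n_cys_catalytic = NA_integer_, n_cys_full = NA_integer_,
               architecture = NA_character_, n_mutable = NA_integer_,
               n_mutated = NA_integer_, stringsAsFactors = FALSE) else NULL

  all_rec <- rbind(records, drecords)
  all_truth <- rbind(truth, dtruth)
  class(all_rec) <- c("protein_records", "data.frame")
  hits <- make_hit_table(all_rec, all_truth, layouts, seed = seed)
  list(records = all_rec, truth = all_truth, hits = hits, layouts = layouts)
}

#' Emulated profile-search hit table for a synthetic dataset
#'
#' Planted LPMOs receive a full-span LPMO_10 hit scoring far above the
#' mining thresholds plus one hit per planted accessory domain; decoys
#' receive a weak partial LPMO_10 hit that fails all three criteria.
#'
#' @param records a `protein_records` table.
#' @param truth the matching truth table.
#' @param layouts named list of per-LPMO architecture layouts.
#' @param seed integer seed (scores are drawn deterministically).
#' @return A `domain_hits` table.
#' @export
make_hit_table <- function(records, truth, layouts = NULL, seed = 1L) {
  rows <- with_seed(seed + 13L, lapply(seq_len(nrow(records)), function(k) {
    tr <- truth[truth$id == records$id[k], , drop = FALSE]
    if (nrow(tr) == 1 && isTRUE(tr$is_lpmo)) {
      layout <- if (!is.null(layouts)) layouts[[records$id[k]]] else
        data.frame(label = "LPMO10", start = 1L, end = tr$fy + 6L)
      layout_hits(records$id[k], layout, tr$signal_length,
                  base_score = round(stats::runif(1, 150, 320), 1))
    } else {
      data.frame(query_id = records$id[k], profile_id = "LPMO_10",
                 profile_length = 190L,
                 domain_bitscore = round(stats::runif(1, 5, 25), 1),
                 bias = round(stats::runif(1, 3, 8), 1),
                 query_from = 30L,
                 query_to = min(120L, nchar(records$residues[k])),
                 hmm_from = 40L, hmm_to = 130L, stringsAsFactors = FALSE)
    }
  }))
  hits <- do.call(rbind, rows)
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

#' Curated synthetic reference annotations for active-site mapping
#'
#' Two mature references on the family scaffold -- one chitin-active
#' (CBP21-like: Ile at the diagnostic position) and one cellulose-active
#' (Arg) -- with exact anchor positions for Hx, Fy, the diagnostic
#' residue (Fy-7), the tryptophan triad (Hx+5, Fy-14, Fy-10) and the
#' conserved alanine (Hx+25).
#'
#' @return A [reference_set] with two rows.
#' @export
make_reference_set <- function() {
  build_ref <- function(id, hx, fy, L, diag_residue, substrate, seed) {
    with_seed(seed, {
      b <- build_mature(L, hx, fy, diag_residue, "complete", TRUE, TRUE,
                        POLAR_VARIANTS[1], cys_catalytic_pos = integer(),
                        cys_tail_pos = integer())
      data.frame(ref_id = id, sequence = paste(b$mature, collapse = ""),
                 hx = hx, fy = fy, diagnostic_pos = fy - 7L,
                 triad = paste(c(hx + 5L, fy - 14L, fy - 10L), collapse = ","),
                 alanine_anchor = hx + 25L, substrate = substrate,
                 stringsAsFactors = FALSE)
    })
  }
  tab <- rbind(build_ref("REF_CHITIN", 100L, 175L, 200L, "I", "chitin", 421L),
               build_ref("REF_CELLULOSE", 110L, 185L, 210L, "R", "cellulose", 422L))
  reference_set(tab$ref_id, tab$sequence, tab$hx, tab$fy, tab$diagnostic_pos,
                tab$triad, tab$alanine_anchor, tab$substrate)
}

#' Random proper rotation matrix
#' @param seed integer seed.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(seed = 1L) {
  with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
           3, 3, byrow = TRUE)
  })
}

#' Rigid-body perturbation of a coordinate set
#'
#' Applies a random proper rotation and translation plus isotropic
#' Gaussian noise of standard deviation `sigma` per coordinate; the
#' applied transformation is returned as truth.
#'
#' @param coords a `coord_set`.
#' @param sigma noise standard deviation (Angstrom).
#' @param seed integer seed.
#' @return List `coords` (perturbed `coord_set`), `truth` (`rotation`,
#'   `translation`, `sigma`).
#' @export
perturb_structure <- function(coords, sigma = 0, seed = 1L) {
  if (sigma < 0) stop_lpmo("lpmominer_validation", "sigma must be >= 0")
  R <- random_rotation(seed)
  with_seed(seed + 1L, {
    tr <- stats::runif(3, -20, 20)
    X <- coord_xyz(coords) %*% t(R)
    X <- sweep(X, 2, tr, `+`)
    if (sigma > 0) X <- X + matrix(stats::rnorm(length(X), 0, sigma), ncol = 3)
    out <- coords
    out$x <- X[, 1]; out$y <- X[, 2]; out$z <- X[, 3]
    list(coords = out, truth = list(rotation = R, translation = tr,
                                    sigma = sigma))
  })
}

#' Deterministic compact beta-sandwich-like reference fold
#'
#' A meander of antiparallel strands with 3.8 A C-alpha spacing; used as
#' the synthetic stand-in for a GbpA_3 reference domain. Deterministic
#' (no randomness).
#'
#' @param n number of residues.
#' @return A `coord_set`.
#' @export
make_fold_coords <- function(n = 90L) {
  strand_len <- 10L
  xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
  for (i in seq_len(n)) {
    s <- (i - 1L) %/% strand_len          # strand index
    k <- (i - 1L) %% strand_len           # position within strand
    along <- if (s %% 2 == 0) k else strand_len - 1L - k
    xs[i] <- along * 3.4
    ys[i] <- s * 4.8
    zs[i] <- 0.9 * (-1)^k + 0.3 * s
  }
  coord_set(seq_len(n), xs, ys, zs, model_id = "synthetic_gbpa3_fold")
}

#' Self-avoiding random-coil C-alpha trace
#'
#' Random walk with 3.8 A steps and a 3.2 A excluded-volume check,
#' emulating an unstructured inter-domain region.
#'
#' @param n number of residues.
#' @param seed integer seed.
#' @return A `coord_set`.
#' @export
make_coil_coords <- function(n = 90L, seed = 1L) {
  with_seed(seed, {
    X <- matrix(0, n, 3)
    for (i in 2:n) {
      for (try in 1:200) {
        dir <- stats::rnorm(3)
        step <- 3.8 * dir / sqrt(sum(dir^2))
        cand <- X[i - 1, ] + step
        d2 <- rowSums(sweep(X[seq_len(i - 2L), , drop = FALSE], 2, cand)^2)
        if (i <= 2 || !length(d2) || min(d2) > 3.2^2) break
      }
      X[i, ] <- cand
    }
    coord_set(seq_len(n), X[, 1], X[, 2], X[, 3], model_id = "synthetic_coil")
  })
}

#' Synthetic structural model with an optionally planted reference domain
#'
#' Builds a C-alpha model as coil + (rigidly transformed reference copy) +
#' coil when `plant` is true, or pure coil otherwise; truth records the
#' planted residue span.
#'
#' @param reference the reference domain `coord_set`.
#' @param plant whether to embed a transformed copy of the reference.
#' @param n_before,n_after coil lengths flanking the (planted) segment.
#' @param sigma coordinate noise applied to the planted copy.
#' @param seed integer seed.
#' @return List `coords`, `truth` (`planted`, `span`).
#' @export
make_structure_model <- function(reference, plant = TRUE, n_before = 50L,
                                 n_after = 40L, sigma = 0, seed = 1L) {
  nref <- nrow(reference)
  if (plant) {
    seg <- perturb_structure(reference, sigma = sigma, seed = seed)$coords
    c1 <- make_coil_coords(n_before, seed = seed + 101L)
    c2 <- make_coil_coords(n_after, seed = seed + 202L)
    # chain the pieces end to end so the trace is contiguous-ish
    d1 <- as.numeric(coord_xyz(seg)[1, ]) - c(3.8, 0, 0) -
      as.numeric(coord_xyz(c1)[n_before, ])
    c1[, c("x", "y", "z")] <- sweep(coord_xyz(c1), 2, d1, `+`)
    d2 <- as.numeric(coord_xyz(seg)[nref, ]) + c(3.8, 0, 0) -
      as.numeric(coord_xyz(c2)[1, ])
    c2[, c("x", "y", "z")] <- sweep(coord_xyz(c2), 2, d2, `+`)
    X <- rbind(coord_xyz(c1), coord_xyz(seg), coord_xyz(c2))
    span <- c(n_before + 1L, n_before + nref)
  } else {
    coil <- make_coil_coords(n_before + nref + n_after, seed = seed + 303L)
    X <- coord_xyz(coil)
    span <- NA_integer_
  }
  n <- nrow(X)
  list(coords = coord_set(seq_len(n), X[, 1], X[, 2], X[, 3],
                          model_id = sprintf("synthetic_model_%d", seed)),
       truth = list(planted = plant, span = span))
}
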