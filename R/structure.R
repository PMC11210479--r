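#' Read C-alpha coordinates from a PDB file
#'
#' Parses ATOM records via [bio3d::read.pdb()] and returns the C-alpha
#' trace of one chain in residue order. Alternate locations are resolved
#' by first occurrence.
#'
#' @param path PDB file path.
#' @param chain chain identifier, or `NULL` for the first chain present.
#' @param model_id label carried on the result (defaults to the file name).
#' @return A `data.frame` of class `coord_set` with columns `resno`, `x`,
#'   `y`, `z` (Angstrom); attribute `model_id`.
#' @export
read_calpha <- function(path, chain = NULL, model_id = NULL) {
  if (!file.exists(path))
    stop_lpmo("lpmominer_io", "PDB file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  else if (nrow(at)) at <- at[at$chain %in% at$chain[1], , drop = FALSE]
  if (!nrow(at))
    stop_lpmo("lpmominer_empty_model", "no C-alpha ATOM records in %s", path)
  # altloc: keep the first occurrence per residue number
  keyfull <- paste(at$resno, ifelse(is.na(at$alt), "", at$alt))
  if (anyDuplicated(keyfull))
    stop_lpmo("lpmominer_format",
              "duplicate C-alpha for residue %s with identical altloc",
              at$resno[duplicated(keyfull)][1])
  at <- at[!duplicated(at$resno), , drop = FALSE]
  if (is.unsorted(at$resno, strictly = TRUE))
    stop_lpmo("lpmominer_format", "residue numbers not strictly increasing")
  coord_set(at$resno, at$x, at$y, at$z,
            model_id = model_id %||% sub("\\.pdb$", "", basename(path)))
}

#' Construct a C-alpha coordinate set
#' @param resno strictly increasing residue numbers.
#' @param x,y,z coordinates in Angstrom.
#' @param model_id label.
#' @return A `coord_set` data frame.
#' @export
coord_set <- function(resno, x, y, z, model_id = "model") {
  if (is.unsorted(resno, strictly = TRUE))
    stop_lpmo("lpmominer_validation", "residue numbers must be strictly increasing")
  if (!all(is.finite(c(x, y, z))))
    stop_lpmo("lpmominer_validation", "coordinates must be finite")
  structure(data.frame(resno = as.integer(resno), x = x, y = y, z = z),
            class = c("coord_set", "data.frame"), model_id = model_id)
}

coord_xyz <- function(coords) as.matrix(coords[, c("x", "y", "z")])

#' Write a C-alpha trace as a minimal PDB file
#'
#' Emits one fixed-format ATOM record per residue (CA of ALA, chain A),
#' sufficient for [read_calpha()] round trips at the format's 3-decimal
#' precision.
#'
#' @param coords a `coord_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(coords, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), coords$resno, coords$x, coords$y, coords$z)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Kabsch superposition of two C-alpha sets
#'
#' Least-squares optimal rigid-body fit of `mobile` onto `fixed`
#' (correspondence by list order, reflections excluded). The returned
#' transformation maps a mobile point `p` to `rotation %*% p +
#' translation`.
#'
#' @param fixed,mobile `coord_set`s (or Nx3 matrices) of equal length,
#'   at least 3 points.
#' @return List of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_aligned`.
#' @export
kabsch_superpose <- function(fixed, mobile) {
  Pf <- if (is.matrix(fixed)) fixed else coord_xyz(fixed)
  Pm <- if (is.matrix(mobile)) mobile else coord_xyz(mobile)
  if (nrow(Pf) != nrow(Pm))
    stop_lpmo("lpmominer_validation", "point counts differ (%d vs %d)",
              nrow(Pf), nrow(Pm))
  if (nrow(Pf) < 3)
    stop_lpmo("lpmominer_validation", "need at least 3 corresponding points")
  cf <- colMeans(Pf); cm <- colMeans(Pm)
  Fc <- sweep(Pf, 2, cf); Mc <- sweep(Pm, 2, cm)
  H <- crossprod(Mc, Fc)           # 3x3 covariance
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1               # degenerate (collinear) sets: pick the
                                   # proper rotation from the SVD as-is
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  moved <- Mc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Fc)^2)))
  structure(list(rotation = R, translation = as.numeric(cf - R %*% cm),
                 rmsd = rmsd, n_aligned = nrow(F)),
            class = "superposition")
}

#' Apply a superposition to a coordinate set
#' @param sp a `superposition`.
#' @param coords a `coord_set` or Nx3 matrix.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_superposition <- function(sp, coords) {
  X <- if (is.matrix(coords)) coords else coord_xyz(coords)
  Y <- sweep(X %*% t(sp$rotation), 2, sp$translation, `+`)
  if (is.matrix(coords)) return(Y)
  out <- coords
  out$x <- Y[, 1]; out$y <- Y[, 2]; out$z <- Y[, 3]
  out
}

#' Best-fitting window of a model against a reference domain
#'
#' Slides a window of the reference's length along the model C-alpha
#' trace (stride `step`), superposes each window on the reference and
#' returns the window with minimal RMSD (leftmost on ties).
#'
#' @param model,reference `coord_set`s; the model must be at least as
#'   long as the reference.
#' @param step window stride in residues.
#' @return List `span` (first/last model residue numbers of the window),
#'   `start_index`, `superposition`.
#' @export
sliding_domain_match <- function(model, reference, step = 1L) {
  nm <- nrow(model); nr <- nrow(reference)
  if (nm < nr)
    stop_lpmo("lpmominer_validation",
              "model (%d residues) shorter than reference (%d)", nm, nr)
  Rxyz <- coord_xyz(reference)
  Mxyz <- coord_xyz(model)
  best <- NULL
  for (s in seq.int(1L, nm - nr + 1L, by = as.integer(step))) {
    sp <- kabsch_superpose(Rxyz, Mxyz[s:(s + nr - 1L), , drop = FALSE])
    if (is.null(best) || sp$rmsd < best$superposition$rmsd - 1e-12)
      best <- list(span = c(model$resno[s], model$resno[s + nr - 1L]),
                   start_index = s, superposition = sp)
  }
  best
}

#' Structural classification of a Domain-X segment as GbpA_3-like
#'
#' Extracts the model residues inside `segment_span`, requires the
#' overlap with the reference to reach `min_coverage` of the reference
#' length, and calls the segment GbpA_3-like iff the best sliding-window
#' RMSD against the reference is at most `rmsd_cutoff`.
#'
#' @param model a `coord_set` for the whole model.
#' @param segment_span `c(from, to)` residue numbers of the SPACE /
#'   Domain-X segment.
#' @param reference `coord_set` of the GbpA_3 reference domain.
#' @param rmsd_cutoff maximal RMSD (Angstrom).
#' @param min_coverage required fraction of the reference length.
#' @param step window stride.
#' @return List `gbpa3_like`, `rmsd`, `span`, `n_aligned`.
#' @export
classify_gbpa3_like <- function(model, segment_span, reference,
                                rmsd_cutoff = 5.0, min_coverage = 0.8,
                                step = 1L) {
  seg <- model[model$resno >= segment_span[1] & model$resno <= segment_span[2], ,
               drop = FALSE]
  nr <- nrow(reference)
  L <- min(nrow(seg), nr)
  if (L < ceiling(min_coverage * nr) || L < 3)
    return(list(gbpa3_like = FALSE, rmsd = NA_real_, span = NULL,
                n_aligned = L))
  if (nrow(seg) >= nr) {
    best <- sliding_domain_match(seg, reference, step)
  } else {
    # segment shorter than the reference: slide it over reference windows
    best <- sliding_domain_match(reference, seg, step)
    best$span <- c(seg$resno[1], seg$resno[nrow(seg)])
  }
  list(gbpa3_like = best$superposition$rmsd <= rmsd_cutoff,
       rmsd = best$superposition$rmsd, span = best$span,
       n_aligned = best$superposition$n_aligned)
}
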