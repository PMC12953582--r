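# Backbone rigid-body superposition (Kabsch) and AlphaFold confidence
# summaries, as used to validate a predicted Ig-fold model against a
# crystallographic reference.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Build a backbone atom correspondence between two structures
#'
#' @param mobile,reference single-frame [trajectory()] objects (frame 0 is
#'   used).
#' @param pairing `"by_residue_number"`: pair identical
#'   (chain, residue_number, atom_name) backbone atoms present in both;
#'   `"by_sequence_alignment_input"`: use a caller-supplied residue
#'   correspondence.
#' @param correspondence for `"by_sequence_alignment_input"`: a data.frame
#'   (or CSV path) with columns `mobile_resnum,reference_resnum`.
#' @param ca_only use only C-alpha atoms instead of the full N/CA/C/O
#'   backbone.
#' @return object of class `"structure_pair"` with the two structures and a
#'   `map` data.frame of (`mobile_idx`, `reference_idx`) atom-row pairs.
#' @export
build_atom_map <- function(mobile, reference,
                           pairing = c("by_residue_number",
                                       "by_sequence_alignment_input"),
                           correspondence = NULL, ca_only = FALSE) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(mobile, "trajectory"), inherits(reference, "trajectory"))
  bb <- if (ca_only) "CA" else BACKBONE_ATOMS
  am <- mobile$atoms
  ar <- reference$atoms
  im <- which(am$atom_name %in% bb)
  ir <- which(ar$atom_name %in% bb)
  if (length(im) == 0 || length(ir) == 0)
    stop("no backbone atoms found in one of the structures")

  if (pairing == "by_residue_number") {
    key_m <- paste(am$chain_id[im], am$residue_number[im], am$atom_name[im])
    key_r <- paste(ar$chain_id[ir], ar$residue_number[ir], ar$atom_name[ir])
  } else {
    if (is.null(correspondence))
      stop("pairing 'by_sequence_alignment_input' needs a correspondence table")
    if (is.character(correspondence))
      correspondence <- utils::read.csv(correspondence)
    if (!all(c("mobile_resnum", "reference_resnum") %in% names(correspondence)))
      stop("correspondence table needs columns mobile_resnum,reference_resnum")
    # map mobile residue numbers into the reference numbering
    lut <- stats::setNames(correspondence$reference_resnum,
                           correspondence$mobile_resnum)
    mapped <- lut[as.character(am$residue_number[im])]
    keep <- !is.na(mapped)
    im <- im[keep]
    key_m <- paste(mapped[keep], am$atom_name[im])
    key_r <- paste(ar$residue_number[ir], ar$atom_name[ir])
  }
  if (anyDuplicated(key_m) || anyDuplicated(key_r))
    stop("ambiguous backbone atom keys; atom map would not be injective")
  common <- intersect(key_m, key_r)
  if (length(common) < 3)
    stop("fewer than 3 backbone atom pairs (", length(common),
         "); cannot superpose")
  map <- data.frame(mobile_idx = im[match(common, key_m)],
                    reference_idx = ir[match(common, key_r)])
  structure(list(mobile = mobile, reference = reference, map = map),
            class = "structure_pair")
}

#' Least-squares rigid superposition (Kabsch) and backbone RMSD
#'
#' Finds the proper rotation (determinant +1, reflections excluded) and
#' translation minimising the RMSD over the mapped atom pairs, via singular
#' value decomposition of the cross-covariance; equal weights, no outlier
#' trimming.
#'
#' @param pair a [build_atom_map()] result, or a list with elements
#'   `mobile`/`reference` given as plain `n x 3` coordinate matrices of
#'   already-paired points.
#' @return object of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation` (length 3, Angstrom), `rmsd` (Angstrom), `n_atoms`.
#'   The transform maps a mobile point x to `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(pair) {
  if (inherits(pair, "structure_pair")) {
    X <- frame_coords(pair$mobile, 0)[pair$map$mobile_idx, , drop = FALSE]
    Y <- frame_coords(pair$reference, 0)[pair$map$reference_idx, , drop = FALSE]
  } else {
    X <- as.matrix(pair$mobile)
    Y <- as.matrix(pair$reference)
  }
  if (nrow(X) != nrow(Y)) stop("point sets must be paired (equal size)")
  if (nrow(X) < 3) stop("need >= 3 point pairs")
  xbar <- colMeans(X)
  ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar)
  Yc <- sweep(Y, 2, ybar)
  sv <- svd(crossprod(Xc, Yc))
  # collinear point sets leave the rotation about the line unconstrained
  if (sv$d[2] <= 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) point set; superposition is ambiguous")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- tcrossprod(Xc, R)  # Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(ybar - R %*% xbar),
                 rmsd = rmsd, n_atoms = nrow(X)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d atom pairs, RMSD = %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sup a [kabsch_superpose()] result.
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Summarise per-residue model confidence (pLDDT)
#'
#' AlphaFold coordinate files store the per-residue pLDDT in the B-factor
#' column, constant across a residue's atoms. Bins are disjoint so the
#' fractions can be summed: very high confidence is pLDDT > 90, high
#' confidence 70 < pLDDT <= 90.
#'
#' @param model a [trajectory()] read from an AlphaFold PDB file (B-factor
#'   column present).
#' @return object of class `"confidence_summary"`: `n_residues`,
#'   `fraction_very_high`, `fraction_high`.
#' @export
plddt_summary <- function(model) {
  stopifnot(inherits(model, "trajectory"))
  a <- model$atoms
  if (is.null(a$b) || all(is.na(a$b)))
    stop("structure carries no B-factor (pLDDT) values")
  key <- paste(a$chain_id, a$residue_number)
  plddt <- tapply(a$b, key, function(v) v[!is.na(v)][1])
  if (any(is.na(plddt)))
    stop("residue(s) without a confidence value")
  if (any(plddt < 0 | plddt > 100))
    stop("pLDDT values must lie in [0, 100]; found ",
         plddt[which(plddt < 0 | plddt > 100)[1]])
  nres <- length(plddt)
  structure(list(n_residues = nres,
                 fraction_very_high = mean(plddt > 90),
                 fraction_high = mean(plddt > 70 & plddt <= 90)),
            class = "confidence_summary")
}

#' @export
print.confidence_summary <- function(x, ...) {
  cat(sprintf(paste0("model confidence: %d residues, %.0f%% very high ",
                     "(pLDDT > 90), %.0f%% high (70 < pLDDT <= 90)\n"),
              x$n_residues, 100 * x$fraction_very_high,
              100 * x$fraction_high))
  invisible(x)
}
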