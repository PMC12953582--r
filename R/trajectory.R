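#' Construct a coordinate trajectory
#'
#' A trajectory is an ordered sequence of frames sharing one atom table.
#' Coordinates are in Angstrom, time stamps (optional) in nanoseconds, and
#' frames are indexed from 0, following molecular dynamics convention.
#'
#' @param atoms data.frame with columns `atom_id` (unique positive integer),
#'   `atom_name`, `residue_name`, `residue_number`, `chain_id`. Extra columns
#'   (e.g. `b` holding B-factor/pLDDT) are kept.
#' @param xyz numeric array of dimension `c(n_atoms, 3, n_frames)`, Angstrom.
#'   A single `n_atoms x 3` matrix is promoted to a one-frame trajectory.
#' @param time_ns optional numeric vector of per-frame time stamps (ns).
#' @param metadata free-form named list (source file, units, notes).
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(atoms, xyz, time_ns = NULL, metadata = list()) {
  req <- c("atom_id", "atom_name", "residue_name", "residue_number", "chain_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop("xyz must be an n_atoms x 3 x n_frames array")
  if (dim(xyz)[1] != nrow(atoms))
    stop("xyz has ", dim(xyz)[1], " atoms but atom table has ", nrow(atoms))
  if (dim(xyz)[3] < 1L) stop("trajectory needs at least one frame")
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique within a frame")
  if (any(atoms$atom_id <= 0)) stop("atom_id values must be positive")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!is.null(time_ns)) {
    if (length(time_ns) != dim(xyz)[3])
      stop("time_ns length must equal the number of frames")
    if (any(time_ns < 0)) stop("time stamps must be non-negative")
  }
  atoms$atom_name    <- trimws(as.character(atoms$atom_name))
  atoms$residue_name <- trimws(as.character(atoms$residue_name))
  atoms$chain_id     <- trimws(as.character(atoms$chain_id))
  atoms$atom_id        <- as.integer(atoms$atom_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  structure(list(atoms = atoms, xyz = xyz, time_ns = time_ns,
                 metadata = metadata),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Number of atoms per frame
#' @param traj a `trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(traj) dim(traj$xyz)[1]

#' Coordinates of one frame
#' @param traj a `trajectory`.
#' @param frame 0-based frame index.
#' @return `n_atoms x 3` matrix, Angstrom.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 0 || frame >= n_frames(traj))
    stop("frame index ", frame, " out of range [0, ", n_frames(traj) - 1L, "]")
  traj$xyz[, , frame + 1L, drop = TRUE]
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frame(s),", n_atoms(x), "atoms/frame\n")
  if (!is.null(x$time_ns))
    cat("  time span:", min(x$time_ns), "-", max(x$time_ns), "ns\n")
  cat("  residues:", length(unique(paste(x$atoms$chain_id,
                                         x$atoms$residue_number))), "\n")
  invisible(x)
}

#' Define an atom selection
#'
#' A selection is a predicate over atom metadata: AND semantics across the
#' four keys, OR within each vector of admissible values. Matching is exact,
#' case-sensitive, whitespace-stripped.
#'
#' @param label human-readable label used in error messages.
#' @param atom_name,residue_name,residue_number,chain_id admissible values;
#'   `NULL` leaves the key unconstrained.
#' @return object of class `"selection"`.
#' @export
selection <- function(label, atom_name = NULL, residue_name = NULL,
                      residue_number = NULL, chain_id = NULL) {
  structure(list(label = label,
                 atom_name = if (!is.null(atom_name)) trimws(as.character(atom_name)),
                 residue_name = if (!is.null(residue_name)) trimws(as.character(residue_name)),
                 residue_number = if (!is.null(residue_number)) as.integer(residue_number),
                 chain_id = if (!is.null(chain_id)) trimws(as.character(chain_id))),
            class = "selection")
}

#' Read a selection from its JSON specification
#'
#' The JSON dialect is `{"label": str, "atom_name": [...], "residue_name":
#' [...], "residue_number": [...], "chain_id": [...]}`; omitted keys are
#' unconstrained.
#'
#' @param path path to a JSON file, or a literal JSON string.
#' @return a `selection`.
#' @export
read_selection_json <- function(path) {
  spec <- jsonlite::fromJSON(path)
  if (is.null(spec$label)) stop("selection JSON must carry a label")
  selection(label = spec$label,
            atom_name = spec$atom_name,
            residue_name = spec$residue_name,
            residue_number = spec$residue_number,
            chain_id = spec$chain_id)
}

#' Resolve a selection to atom indices
#'
#' The trajectory atom map is constant across frames, so the resolved index
#' list is valid for every frame. Order follows file (atom-table) order.
#'
#' @param traj a `trajectory`.
#' @param sel a `selection`.
#' @return integer vector of 1-based row indices into `traj$atoms`.
#' @export
resolve_selection <- function(traj, sel) {
  stopifnot(inherits(traj, "trajectory"), inherits(sel, "selection"))
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$atom_name))      keep <- keep & a$atom_name %in% sel$atom_name
  if (!is.null(sel$residue_name))   keep <- keep & a$residue_name %in% sel$residue_name
  if (!is.null(sel$residue_number)) keep <- keep & a$residue_number %in% sel$residue_number
  if (!is.null(sel$chain_id))       keep <- keep & a$chain_id %in% sel$chain_id
  idx <- which(keep)
  if (length(idx) == 0)
    stop("selection '", sel$label, "' matches no atoms")
  idx
}

#' Construct a per-frame metric series
#'
#' @param name metric name (used as CSV column header).
#' @param unit one of `"degree"`, `"angstrom"`, `"fraction"`.
#' @param values numeric vector, one value per frame (`NA` on masked frames).
#' @param mask optional logical validity flags (`TRUE` = valid); defaults to
#'   `!is.na(values)`.
#' @param time_ns optional per-frame time stamps, ns.
#' @return object of class `"metric_series"`.
#' @export
metric_series <- function(name, unit = c("degree", "angstrom", "fraction"),
                          values, mask = NULL, time_ns = NULL) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (is.null(mask)) mask <- !is.na(values)
  if (length(mask) != length(values))
    stop("mask length must equal values length")
  if (!is.null(time_ns) && length(time_ns) != length(values))
    stop("time_ns length must equal values length")
  structure(list(name = name, unit = unit, values = values,
                 mask = as.logical(mask), time_ns = time_ns),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("metric_series '%s' [%s]: %d frames (%d valid)\n",
              x$name, x$unit, length(x$values), length(v)))
  if (length(v) > 0)
    cat(sprintf("  mean %.3f  min %.3f  max %.3f\n",
                mean(v), min(v), max(v)))
  invisible(x)
}

#' @export
length.metric_series <- function(x) length(x$values)
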