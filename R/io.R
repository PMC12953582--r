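# Fixed-column PDB and columnar frame-table I/O for trajectories.
# PDB dialect: ATOM/HETATM records, MODEL/ENDMDL frame delimiters, name in
# columns 13-16, resName 18-21 (4-char lipid names occupy column 21, CHARMM/
# AMBER practice), chain 22, resSeq 23-26, x/y/z 31-54, occupancy 55-60,
# B-factor 61-66 (read back as pLDDT for AlphaFold files).

FRAME_TABLE_HEADER <- "frame,atom_id,atom_name,residue_name,residue_number,chain_id,x,y,z"

num_field <- function(lines, from, to, what, line_no) {
  s <- trimws(substr(lines, from, to))
  v <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(v) | s == "")
  if (length(bad) > 0)
    stop("malformed ", what, " field at line ", line_no[bad[1]],
         ": '", s[bad[1]], "'")
  v
}

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per `MODEL` block; a file without `MODEL` records yields a
#' one-frame trajectory. The atom map (id, name, residue, chain) must be
#' identical across models.
#'
#' @param path path to a PDB file.
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign each atom line to a model block (0 = no MODEL records seen yet)
  model_no <- cumsum(is_model)
  atom_idx <- which(is_atom)
  mm <- model_no[atom_idx]
  blocks <- split(atom_idx, factor(mm, levels = sort(unique(mm))))
  blocks <- blocks[vapply(blocks, length, 1L) > 0]

  parse_block <- function(ii) {
    ln <- lines[ii]
    data.frame(
      atom_id = as.integer(num_field(ln, 7, 11, "atom serial", ii)),
      atom_name = trimws(substr(ln, 13, 16)),
      residue_name = trimws(substr(ln, 18, 21)),
      residue_number = as.integer(num_field(ln, 23, 26, "residue number", ii)),
      chain_id = trimws(substr(ln, 22, 22)),
      x = num_field(ln, 31, 38, "x coordinate", ii),
      y = num_field(ln, 39, 46, "y coordinate", ii),
      z = num_field(ln, 47, 54, "z coordinate", ii),
      occ = suppressWarnings(as.numeric(substr(ln, 55, 60))),
      b = suppressWarnings(as.numeric(substr(ln, 61, 66))),
      stringsAsFactors = FALSE)
  }

  frames <- lapply(blocks, parse_block)
  nf <- length(frames)
  ref <- frames[[1]]
  key_cols <- c("atom_id", "atom_name", "residue_name", "residue_number",
                "chain_id")
  for (k in seq_len(nf)) {
    fk <- frames[[k]]
    if (nrow(fk) != nrow(ref))
      stop("inconsistent atom count across models: model ", k, " has ",
           nrow(fk), " atoms, model 1 has ", nrow(ref))
    if (!identical(fk[key_cols], ref[key_cols]))
      stop("atom map differs between model 1 and model ", k)
  }

  xyz <- array(NA_real_, dim = c(nrow(ref), 3L, nf))
  for (k in seq_len(nf))
    xyz[, , k] <- as.matrix(frames[[k]][, c("x", "y", "z")])
  atoms <- ref[key_cols]
  atoms$occ <- ref$occ
  atoms$b <- ref$b
  trajectory(atoms, xyz, metadata = list(source = path, format = "pdb"))
}

pdb_atom_name_field <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

pdb_resname_field <- function(rn) {
  ifelse(nchar(rn) >= 4, substr(rn, 1, 4), sprintf("%3s ", rn))
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  occ <- if (!is.null(a$occ)) ifelse(is.na(a$occ), 1, a$occ) else rep(1, nrow(a))
  b <- if (!is.null(a$b)) ifelse(is.na(a$b), 0, a$b) else rep(0, nrow(a))
  name_f <- pdb_atom_name_field(a$atom_name)
  res_f <- pdb_resname_field(a$residue_name)
  chain <- ifelse(a$chain_id == "", " ", substr(a$chain_id, 1, 1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyzk <- traj$xyz[, , k, drop = TRUE]
    if (is.null(dim(xyzk))) xyzk <- matrix(xyzk, ncol = 3)
    writeLines(sprintf("ATOM  %5d %s %s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       a$atom_id, name_f, res_f, chain, a$residue_number,
                       xyzk[, 1], xyzk[, 2], xyzk[, 3], occ, b), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a columnar frame table as a trajectory
#'
#' Dialect: comma-separated, header exactly
#' `frame,atom_id,atom_name,residue_name,residue_number,chain_id,x,y,z`,
#' coordinates in Angstrom, frame indices contiguous from 0.
#'
#' @param path path to the CSV.
#' @return a [trajectory()].
#' @export
read_frame_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  if (!identical(hdr, FRAME_TABLE_HEADER))
    stop("frame-table header mismatch; expected '", FRAME_TABLE_HEADER, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame = "integer", atom_id = "integer",
                                       atom_name = "character",
                                       residue_name = "character",
                                       residue_number = "integer",
                                       chain_id = "character",
                                       x = "numeric", y = "numeric",
                                       z = "numeric"))
  fr <- sort(unique(df$frame))
  if (!identical(fr, seq(0L, length(fr) - 1L)))
    stop("frame indices must be contiguous from 0; found {",
         paste(fr, collapse = ","), "}")
  blocks <- split(df, factor(df$frame, levels = fr))
  ref <- blocks[[1]]
  key_cols <- c("atom_id", "atom_name", "residue_name", "residue_number",
                "chain_id")
  rownames(ref) <- NULL
  for (k in seq_along(blocks)) {
    bk <- blocks[[k]]; rownames(bk) <- NULL
    if (nrow(bk) != nrow(ref) || !identical(bk[key_cols], ref[key_cols]))
      stop("atom map differs between frame 0 and frame ", k - 1L)
  }
  xyz <- array(NA_real_, dim = c(nrow(ref), 3L, length(blocks)))
  for (k in seq_along(blocks))
    xyz[, , k] <- as.matrix(blocks[[k]][, c("x", "y", "z")])
  trajectory(ref[key_cols], xyz,
             metadata = list(source = path, format = "frame_table"))
}

#' Write a trajectory as a columnar frame table
#'
#' Canonical formatting: coordinates with three decimals, rows ordered by
#' frame then atom-table order, so `write(read(x))` is byte-identical for
#' canonically formatted input.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(FRAME_TABLE_HEADER, con)
  for (k in seq_len(n_frames(traj))) {
    xyzk <- traj$xyz[, , k, drop = TRUE]
    if (is.null(dim(xyzk))) xyzk <- matrix(xyzk, ncol = 3)
    writeLines(sprintf("%d,%d,%s,%s,%d,%s,%.3f,%.3f,%.3f",
                       k - 1L, a$atom_id, a$atom_name, a$residue_name,
                       a$residue_number, a$chain_id,
                       xyzk[, 1], xyzk[, 2], xyzk[, 3]), con)
  }
  invisible(path)
}

#' Write one or more metric series to CSV
#'
#' Columns are `frame,time_ns,<name1>,<name2>,...`. Masked or missing values
#' are written as empty fields (not the string "NA"/"nan").
#'
#' @param series a `metric_series` or list of them, all of equal length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(series, path) {
  if (inherits(series, "metric_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "metric_series")))
  lens <- vapply(series, length, 1L)
  if (length(unique(lens)) != 1)
    stop("all metric series must have the same length; got ",
         paste(lens, collapse = ", "))
  nfr <- lens[1]
  time_ns <- NULL
  for (s in series) if (!is.null(s$time_ns)) { time_ns <- s$time_ns; break }
  fmt_num <- function(v, valid) ifelse(valid & !is.na(v),
                                       formatC(v, format = "fg",
                                               digits = 10, width = -1), "")
  cols <- list(frame = as.character(seq_len(nfr) - 1L),
               time_ns = if (is.null(time_ns)) rep("", nfr)
                         else fmt_num(time_ns, rep(TRUE, nfr)))
  for (s in series) cols[[s$name]] <- fmt_num(s$values, s$mask)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(do.call(paste, c(unname(cols), sep = ",")), con)
  invisible(path)
}
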