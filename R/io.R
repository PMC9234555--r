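# File input/output.  PDB and DCD parsing is delegated to bio3d; GRO files
# (fixed-width, nm units) are parsed here.  All coordinates are stored in
# Angstrom internally; GRO nm values are converted on read.

.file_ext <- function(path) tolower(sub(".*\\.", "", path))

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  atom_tab <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(natoms)) stop("malformed GRO file: bad atom count at line ", i + 1)
    block <- lines[(i + 2):(i + 1 + natoms)]
    resid <- as.integer(substr(block, 1, 5))
    resname <- trimws(substr(block, 6, 10))
    aname <- trimws(substr(block, 11, 15))
    x <- as.numeric(substr(block, 21, 28)) * 10  # nm -> Angstrom
    y <- as.numeric(substr(block, 29, 36)) * 10
    z <- as.numeric(substr(block, 37, 44)) * 10
    if (is.null(atom_tab))
      atom_tab <- list(name = aname, resid = resid, resname = resname)
    frames[[length(frames) + 1]] <- as.vector(rbind(x, y, z))
    i <- i + natoms + 3  # title + count + atoms + box line
  }
  box_line <- strsplit(trimws(lines[i - 1]), "\\s+")[[1]]
  box <- suppressWarnings(as.numeric(box_line[1:3])) * 10
  list(atom = atom_tab, xyz = do.call(rbind, frames),
       box = if (all(is.finite(box))) box else NULL)
}

.read_pdb_any <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  list(atom = list(name = pdb$atom$elety, resid = pdb$atom$resno,
                   resname = pdb$atom$resid),
       xyz = unclass(xyz), box = NULL)
}

#' Read a topology and trajectory into a Trajectory object
#'
#' Supported topology formats: PDB and GRO.  Supported trajectory formats:
#' multi-model PDB, multi-frame GRO and DCD.  If `trajectory_path` is `NULL`
#' the frames of the topology file itself are used.  XTC/TRR are not
#' readable here; pre-convert such trajectories to DCD or multi-model PDB.
#'
#' @param topology_path path to a PDB or GRO file defining atoms.
#' @param trajectory_path optional path to the coordinate trajectory.
#' @param selection atom selection applied after reading (see
#'   [select_atoms()]); must match at least one atom.
#' @param stride keep every `stride`-th frame (default 1 = all).
#' @param dt frame spacing in ps used when the files carry no time
#'   information (default 2 ps).
#' @return A `"trajectory"` object containing only the selected atoms.
#' @export
read_system <- function(topology_path, trajectory_path = NULL,
                        selection = "all", stride = 1L, dt = 2) {
  if (!file.exists(topology_path)) stop("topology file not found: ", topology_path)
  top_raw <- switch(.file_ext(topology_path),
    pdb = , ent = .read_pdb_any(topology_path),
    gro = .read_gro(topology_path),
    stop("unsupported topology format: .", .file_ext(topology_path)))
  xyz <- top_raw$xyz
  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path))
      stop("trajectory file not found: ", trajectory_path)
    ext <- .file_ext(trajectory_path)
    if (ext %in% c("xtc", "trr"))
      stop("XTC/TRR trajectories are not supported; convert to DCD or ",
           "multi-model PDB first (e.g. 'mdconvert' or 'gmx trjconv -o out.pdb')")
    xyz <- switch(ext,
      pdb = , ent = .read_pdb_any(trajectory_path)$xyz,
      gro = .read_gro(trajectory_path)$xyz,
      dcd = unclass(bio3d::read.dcd(trajectory_path, verbose = FALSE)),
      stop("unsupported trajectory format: .", ext))
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  }
  n_at <- length(top_raw$atom$name)
  if (ncol(xyz) != 3L * n_at)
    stop("atom-count mismatch: topology has ", n_at, " atoms but trajectory ",
         "frames have ", ncol(xyz) / 3, " atoms")
  top <- topology(top_raw$atom$name, top_raw$atom$resid, top_raw$atom$resname)
  if (stride > 1L) xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  times <- dt * stride * (seq_len(nrow(xyz)) - 1)
  traj <- trajectory(top, xyz, times, top_raw$box)
  subset_trajectory(traj, selection)
}

#' Write frames as a (multi-model) PDB file
#'
#' @param traj a `"trajectory"` object.
#' @param path output file path.
#' @param frames frame indices to write (default: all).
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(traj, path, frames = seq_len(n_frames(traj))) {
  top <- traj$topology
  multi <- length(frames) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frame_coords(traj, frames[k])
    nm <- top$atom_name
    nm4 <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
    lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     top$atom_id, nm4, substr(top$residue_name, 1, 3),
                     top$residue_id, xyz[, 1], xyz[, 2], xyz[, 3],
                     1.00, 0.00, top$element)
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a time series to CSV
#'
#' @param x an object with an `as.data.frame` method (metric series, contact
#'   series, distribution, centrality profile, ...).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
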