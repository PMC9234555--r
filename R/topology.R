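# Topology and Trajectory containers.
#
# A trajectory stores coordinates bio3d-style: an n_frames x 3N matrix whose
# columns run x1, y1, z1, x2, ... (Angstrom), plus a topology data frame with
# one row per atom.  Residue ids follow the source file and are never
# renumbered, so domain definitions (e.g. lyase 10-87) interpret file numbers.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, MG = 24.305, NA. = 22.990,
                     K = 39.098, CL = 35.45, ZN = 65.38, FE = 55.845)

# Donor/acceptor assignment is by atom-name table (no bond perception):
# protein backbone N donates (except proline) and backbone O accepts;
# side-chain classes cover the standard amino acids plus phosphoserine
# naming dialects (SEP / SP1 / SP2 patches: O1P/O2P/O3P or OP1/OP2/OP3).
.donor_names <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE2", "ND2",
                  "NE1", "OG", "OG1", "OH", "OW")
.acceptor_n_names <- c("ND1", "NE2")  # imidazole nitrogens may accept
.basic_n_names <- c("NZ", "NE", "NH1", "NH2")
.acidic_o_names <- c("OD1", "OD2", "OE1", "OE2",
                     "O1P", "O2P", "O3P", "OP1", "OP2", "OP3",
                     "OT1", "OT2", "OXT")
.phospho_resnames <- c("SEP", "SP1", "SP2", "PSE", "S1P", "S2P")

.guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("MG", "CL", "ZN", "FE"), two,
         ifelse(substr(nm, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
                substr(nm, 1, 1), substr(nm, 1, 1)))
}

#' Build a Topology table
#'
#' Constructs the per-atom annotation table used throughout the package.
#' Element and mass are derived from the atom name unless supplied; hydrogen,
#' donor and acceptor flags come from standard protein atom-name tables
#' (phosphoserine oxygen dialects included).
#'
#' @param atom_name character vector of PDB-style atom names.
#' @param residue_id integer residue numbers as in the source file (1-based,
#'   never renumbered).
#' @param residue_name character residue names (three-letter codes).
#' @param element optional element symbols; guessed from names if `NULL`.
#' @param mass optional atomic masses (amu); looked up by element if `NULL`.
#' @return A `data.frame` with columns `atom_id`, `atom_name`, `residue_id`,
#'   `residue_name`, `element`, `mass`, `is_hydrogen`, `is_donor`,
#'   `is_acceptor`.
#' @export
topology <- function(atom_name, residue_id, residue_name,
                     element = NULL, mass = NULL) {
  n <- length(atom_name)
  stopifnot(length(residue_id) == n, length(residue_name) == n)
  if (is.null(element)) element <- .guess_element(atom_name)
  if (is.null(mass)) {
    mass <- unname(.element_masses[element])
    mass[is.na(mass)] <- 12.011  # unknown heavy atom: treat as carbon
  }
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("all atomic masses must be positive and finite")
  nm <- toupper(atom_name)
  is_h <- element == "H"
  is_donor <- nm %in% .donor_names & !is_h
  # proline backbone N has no amide hydrogen
  is_donor[nm == "N" & toupper(residue_name) == "PRO"] <- FALSE
  is_acceptor <- (element == "O" | nm %in% .acceptor_n_names) & !is_h
  data.frame(atom_id = seq_len(n),
             atom_name = as.character(atom_name),
             residue_id = as.integer(residue_id),
             residue_name = as.character(residue_name),
             element = element,
             mass = mass,
             is_hydrogen = is_h,
             is_donor = is_donor,
             is_acceptor = is_acceptor,
             stringsAsFactors = FALSE)
}

#' Construct a Trajectory
#'
#' @param topology a topology `data.frame` from [topology()].
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`, coordinates in
#'   Angstrom with columns ordered x1, y1, z1, x2, ...  A single frame may be
#'   given as an `n_atoms` x 3 matrix.
#' @param times frame times in ps, strictly increasing; defaults to
#'   `0, 2, 4, ...` (2 ps sampling).
#' @param box optional box lengths (Angstrom, length 3).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, xyz, times = NULL, box = NULL) {
  if (is.matrix(xyz) && ncol(xyz) == 3 && nrow(xyz) == nrow(topology))
    xyz <- matrix(t(xyz), nrow = 1)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(topology))
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x n_atoms (",
         3L * nrow(topology), ")")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(times)) times <- 2 * (seq_len(nrow(xyz)) - 1)
  if (length(times) != nrow(xyz))
    stop("length(times) must equal the number of frames")
  if (nrow(xyz) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz,
                 times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms,",
      length(unique(x$topology$residue_id)), "residues\n")
  cat("  time span:", x$times[1], "-", x$times[n_frames(x)], "ps\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `"trajectory"` object.
#' @return An integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$topology)

#' Coordinates of one frame
#'
#' @param traj a `"trajectory"` object.
#' @param i frame index.
#' @return An `n_atoms` x 3 matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Atom selection mini-language
#'
#' Parses expressions of the form `"name CA"`, `"resid 10-87"`,
#' `"resname SER GLU"`, `"element O"`, `"backbone"`, `"noh"` or `"all"`,
#' combined with `and`.  `resid` accepts space-separated numbers and
#' inclusive ranges (`"resid 10-87 149 280"`).
#'
#' @param traj a `"trajectory"` object (or topology data frame).
#' @param selection selection string, or a logical/integer atom index vector
#'   passed through unchanged.
#' @return Integer vector of selected atom indices (rows of the topology).
#' @export
select_atoms <- function(traj, selection = "all") {
  top <- if (is.data.frame(traj)) traj else traj$topology
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  clauses <- strsplit(trimws(selection), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(top))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(tok[1])
    args <- tok[-1]
    keep <- keep & switch(kw,
      all = rep(TRUE, nrow(top)),
      protein = rep(TRUE, nrow(top)),
      backbone = toupper(top$atom_name) %in% c("N", "CA", "C", "O"),
      calpha = toupper(top$atom_name) == "CA",
      noh = !top$is_hydrogen,
      name = toupper(top$atom_name) %in% toupper(args),
      resname = toupper(top$residue_name) %in% toupper(args),
      element = toupper(top$element) %in% toupper(args),
      resid = top$residue_id %in% .expand_ranges(args),
      stop("unknown selection keyword: '", kw, "'"))
  }
  which(keep)
}

.expand_ranges <- function(args) {
  out <- integer(0)
  for (a in args) {
    if (grepl("-", a, fixed = TRUE) && !grepl("^-", a)) {
      ab <- as.integer(strsplit(a, "-", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(a))
  }
  out
}

#' Subset a trajectory by atoms and/or frames
#'
#' @param traj a `"trajectory"` object.
#' @param selection atom selection (string or indices); `"all"` keeps all.
#' @param frames optional frame indices to keep.
#' @return A new `"trajectory"`.
#' @export
subset_trajectory <- function(traj, selection = "all", frames = NULL) {
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0) stop("selection matches no atoms")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xyz <- traj$xyz[, cols, drop = FALSE]
  times <- traj$times
  if (!is.null(frames)) {
    xyz <- xyz[frames, , drop = FALSE]
    times <- times[frames]
  }
  top <- traj$topology[idx, , drop = FALSE]
  top$atom_id <- seq_len(nrow(top))
  rownames(top) <- NULL
  trajectory(top, xyz, times, traj$box)
}

#' Restrict a trajectory to a time window
#'
#' @param traj a `"trajectory"` object.
#' @param start,stop window bounds in ps (inclusive); `NULL` means open.
#' @return A new `"trajectory"` containing frames with
#'   `start <= time <= stop`.
#' @export
time_window <- function(traj, start = NULL, stop = NULL) {
  keep <- rep(TRUE, n_frames(traj))
  if (!is.null(start)) keep <- keep & traj$times >= start
  if (!is.null(stop)) keep <- keep & traj$times <= stop
  if (!any(keep)) stop("time window contains no frames")
  subset_trajectory(traj, "all", frames = which(keep))
}

#' Default domain map for DNA polymerase beta
#'
#' Named inclusive residue ranges: lyase 10-87, DNA-binding (D) 90-150,
#' catalytic (C) 151-260, nascent base-pair binding (N) 261-335.
#'
#' @param ranges optional named list of `c(first, last)` integer pairs
#'   overriding the defaults.  Ranges must not overlap.
#' @return A named list of integer ranges with class `"domain_map"`.
#' @export
domain_map <- function(ranges = NULL) {
  if (is.null(ranges))
    ranges <- list(Lyase = c(10L, 87L), D = c(90L, 150L),
                   C = c(151L, 260L), N = c(261L, 335L))
  all_ids <- unlist(lapply(ranges, function(r) seq(r[1], r[2])))
  if (anyDuplicated(all_ids)) stop("domain ranges overlap")
  structure(ranges, class = "domain_map")
}

#' Map residue ids to domain labels
#'
#' @param residue_id integer vector of residue numbers.
#' @param map a [domain_map()].
#' @return Character vector of domain names (`NA` outside every range).
#' @export
assign_domain <- function(residue_id, map = domain_map()) {
  out <- rep(NA_character_, length(residue_id))
  for (nm in names(map)) {
    r <- map[[nm]]
    out[residue_id >= r[1] & residue_id <= r[2]] <- nm
  }
  out
}
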