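# Geometric hydrogen-bond and salt-bridge analysis.
#
# H-bond criterion (gmx hbond convention): donor-acceptor distance
# d <= 3.5 A and hydrogen-donor-acceptor angle <= 30 degrees.  Donors,
# hydrogens and acceptors come from the topology name tables; hydrogens are
# attached to their donor geometrically (covalent distance <= 1.25 A).

#' Hydrogen-bond criteria
#'
#' @param max_da_distance maximum donor-acceptor distance in Angstrom
#'   (default 3.5).
#' @param max_angle maximum hydrogen-donor-acceptor angle in degrees
#'   (default 30).
#' @return A list with class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_angle = 30) {
  stopifnot(max_da_distance > 0, max_angle > 0, max_angle < 90)
  structure(list(max_da_distance = max_da_distance, max_angle = max_angle),
            class = "hbond_criteria")
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Attached hydrogens for each donor: same residue, within covalent range.
.donor_hydrogens <- function(coords, top, donor_idx) {
  h_idx <- which(top$is_hydrogen)
  lapply(donor_idx, function(d) {
    cand <- h_idx[top$residue_id[h_idx] == top$residue_id[d]]
    if (!length(cand)) return(integer(0))
    dd <- sqrt(rowSums(sweep(coords[cand, , drop = FALSE], 2, coords[d, ])^2))
    cand[dd <= 1.25]
  })
}

#' Detect hydrogen bonds in a single frame
#'
#' Reports every (donor, hydrogen, acceptor) triple satisfying the distance
#' and angle criteria.  Donors lacking an attached hydrogen are skipped with
#' a warning.
#'
#' @param traj a `"trajectory"` object.
#' @param frame frame index (default 1).
#' @param criteria an [hbond_criteria()] object.
#' @param donors_sel,acceptors_sel selections restricting candidate donors /
#'   acceptors (default: all annotated donors / acceptors).
#' @return A `data.frame` with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` (A) and `angle` (degrees).
#' @export
detect_hbonds_frame <- function(traj, frame = 1L, criteria = hbond_criteria(),
                                donors_sel = "all", acceptors_sel = "all") {
  top <- traj$topology
  co <- frame_coords(traj, frame)
  don <- intersect(select_atoms(traj, donors_sel), which(top$is_donor))
  acc <- intersect(select_atoms(traj, acceptors_sel), which(top$is_acceptor))
  hyd <- .donor_hydrogens(co, top, don)
  no_h <- lengths(hyd) == 0
  if (any(no_h))
    warning(sum(no_h), " donor(s) without attached hydrogen skipped: ",
            paste(utils::head(top$atom_name[don[no_h]], 5), collapse = ", "))
  out <- list()
  for (k in seq_along(don)) {
    d <- don[k]
    if (!length(hyd[[k]])) next
    for (a in setdiff(acc, c(d, hyd[[k]]))) {
      da <- sqrt(sum((co[a, ] - co[d, ])^2))
      if (da > criteria$max_da_distance) next
      for (h in hyd[[k]]) {
        ang <- .angle_deg(co[h, ] - co[d, ], co[a, ] - co[d, ])
        if (ang <= criteria$max_angle)
          out[[length(out) + 1]] <- data.frame(donor = d, hydrogen = h,
                                               acceptor = a, distance = da,
                                               angle = ang)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

.contact_series <- function(times, distance, formed, pair, kind) {
  structure(list(times = times, distance = distance, formed = formed,
                 occupancy = mean(formed), mean_distance = mean(distance),
                 pair = pair, kind = kind), class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("%s %s: occupancy %.3f, mean distance %.2f A over %d frames\n",
              x$kind, x$pair, x$occupancy, x$mean_distance, length(x$formed)))
  invisible(x)
}

#' @export
as.data.frame.contact_series <- function(x, ...) {
  data.frame(time = x$times, distance = x$distance, formed = x$formed)
}

#' Hydrogen-bond occupancy between two residues
#'
#' Occupancy is the fraction of frames in which at least one qualifying
#' hydrogen bond (either direction) exists between the two residues, using
#' all annotated donors/acceptors of both.
#'
#' @param traj a `"trajectory"` object.
#' @param resA,resB residue ids.
#' @param criteria an [hbond_criteria()] object.
#' @return A `"contact_series"`; `distance` holds the per-frame minimum
#'   donor-acceptor distance across the residue pair.
#' @export
hbond_occupancy <- function(traj, resA, resB, criteria = hbond_criteria()) {
  top <- traj$topology
  if (!resA %in% top$residue_id || !resB %in% top$residue_id)
    stop("residue not present in topology")
  selA <- paste("resid", resA); selB <- paste("resid", resB)
  nf <- n_frames(traj)
  formed <- logical(nf); dmin <- numeric(nf)
  donA <- which(top$is_donor & top$residue_id == resA)
  donB <- which(top$is_donor & top$residue_id == resB)
  accA <- which(top$is_acceptor & top$residue_id == resA)
  accB <- which(top$is_acceptor & top$residue_id == resB)
  for (f in seq_len(nf)) {
    hb <- rbind(
      suppressWarnings(detect_hbonds_frame(traj, f, criteria, selA, selB)),
      suppressWarnings(detect_hbonds_frame(traj, f, criteria, selB, selA)))
    formed[f] <- nrow(hb) > 0
    co <- frame_coords(traj, f)
    pairs <- rbind(expand.grid(d = donA, a = accB),
                   expand.grid(d = donB, a = accA))
    dmin[f] <- if (nrow(pairs))
      min(sqrt(rowSums((co[pairs$d, , drop = FALSE] -
                        co[pairs$a, , drop = FALSE])^2))) else NA_real_
  }
  .contact_series(traj$times, dmin, formed,
                  paste0(resA, "-", resB), "H-bond")
}

#' Per-frame hydrogen-bond counts between two atom groups
#'
#' Counts distinct qualifying (donor, hydrogen, acceptor) triples with the
#' donor in one group and the acceptor in the other (both directions).
#'
#' @param traj a `"trajectory"` object.
#' @param groupA_sel,groupB_sel atom selections for the two groups.
#' @param criteria an [hbond_criteria()] object.
#' @return A list with `times`, integer `counts`, and `max` / `mean`
#'   summaries.
#' @export
hbond_count_series <- function(traj, groupA_sel, groupB_sel,
                               criteria = hbond_criteria()) {
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    hb <- rbind(
      suppressWarnings(detect_hbonds_frame(traj, f, criteria,
                                           groupA_sel, groupB_sel)),
      suppressWarnings(detect_hbonds_frame(traj, f, criteria,
                                           groupB_sel, groupA_sel)))
    nrow(unique(hb[c("donor", "hydrogen", "acceptor")]))
  }, integer(1))
  list(times = traj$times, counts = counts,
       max = max(counts), mean = mean(counts))
}

.sidechain_n <- function(top, res) {
  which(top$residue_id == res & toupper(top$atom_name) %in% .basic_n_names)
}
.anionic_o <- function(top, res) {
  nm <- toupper(top$atom_name)
  hit <- top$residue_id == res & nm %in% .acidic_o_names
  # phosphoserine dialects: the OG bridging oxygen is part of the phosphate
  if (any(top$residue_id == res &
          toupper(top$residue_name) %in% .phospho_resnames))
    hit <- hit | (top$residue_id == res & nm %in% c("OG", "O1P", "O2P", "O3P"))
  which(hit)
}

#' Salt-bridge distance series between a basic and an acidic residue
#'
#' Tracks the per-frame minimum distance over all side-chain nitrogen
#' (NZ/NE/NH1/NH2) to anionic oxygen (carboxylate or phosphate, including
#' phosphoserine O1P/O2P/O3P dialects) atom pairs.  The contact is "formed"
#' when that minimum is at or below `cutoff`.  Argument order is immaterial:
#' the basic/acidic roles are resolved from the atom inventory.
#'
#' @param traj a `"trajectory"` object.
#' @param basic_res,acidic_res residue ids of the pair (order-free).
#' @param cutoff formation cutoff in Angstrom (default 4.0).
#' @return A `"contact_series"` with per-frame minimum N-O distance,
#'   `formed`, `occupancy` and `mean_distance`.
#' @export
saltbridge_series <- function(traj, basic_res, acidic_res, cutoff = 4.0) {
  top <- traj$topology
  nA <- .sidechain_n(top, basic_res); oB <- .anionic_o(top, acidic_res)
  if (!length(nA) || !length(oB)) {     # try swapped roles
    nA2 <- .sidechain_n(top, acidic_res); oB2 <- .anionic_o(top, basic_res)
    if (length(nA2) && length(oB2)) { nA <- nA2; oB <- oB2 }
  }
  if (!length(nA) || !length(oB)) {
    inv <- function(r) paste0(r, " [", paste(
      top$atom_name[top$residue_id == r], collapse = " "), "]")
    stop("no basic-N / anionic-O atom pair between residues ",
         inv(basic_res), " and ", inv(acidic_res))
  }
  pairs <- expand.grid(n = nA, o = oB)
  dmin <- vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    min(sqrt(rowSums((co[pairs$n, , drop = FALSE] -
                      co[pairs$o, , drop = FALSE])^2)))
  }, numeric(1))
  .contact_series(traj$times, dmin, dmin <= cutoff,
                  paste0(basic_res, "-", acidic_res), "salt bridge")
}

#' Centered moving average
#'
#' Window mean with the window shrunk symmetrically at the series edges, so
#' the output has the same length as the input.
#'
#' @param x numeric vector or `"contact_series"` (its distances are
#'   smoothed).
#' @param bin_size window length in samples (>= 1, <= length of series).
#' @return Numeric vector of smoothed values.
#' @export
moving_average <- function(x, bin_size) {
  if (inherits(x, "contact_series")) x <- x$distance
  n <- length(x)
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (bin_size > n) stop("bin_size (", bin_size, ") exceeds series length (",
                         n, ")")
  h1 <- floor((bin_size - 1) / 2); h2 <- bin_size - 1 - h1
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h1):min(n, i + h2)]), numeric(1))
}

#' Pearson correlation between two distance traces
#'
#' @param seriesA,seriesB numeric vectors or `"contact_series"` objects of
#'   equal length (>= 3), neither constant.
#' @return Pearson r in \[-1, 1\].
#' @export
trace_correlation <- function(seriesA, seriesB) {
  a <- if (inherits(seriesA, "contact_series")) seriesA$distance else seriesA
  b <- if (inherits(seriesB, "contact_series")) seriesB$distance else seriesB
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3) stop("need at least 3 points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant trace")
  stats::cor(a, b)
}
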