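# Canonical trajectory data model and readers/writers.
#
# The canonical on-disk format is deliberately plain: a particle table
# (one row per particle per frame) plus a box table, both tab-separated,
# so that desk-scale fixtures and converted MD data share one code path.
# Particle columns: frame, time_ps, role (solute|lipid), species,
# molecule_id, x_nm, y_nm, z_nm.  Box columns: frame, time_ps, Lx_nm,
# Ly_nm, Lz_nm.

#' Per-frame simulation box dimensions
#'
#' @param frame integer frame indices.
#' @param time_ps frame times in picoseconds, strictly increasing.
#' @param Lx,Ly,Lz box edge lengths in nm (recycled if scalar).
#' @return A `frame_boxes` data frame.
#' @export
frame_boxes <- function(frame, time_ps, Lx, Ly, Lz) {
  n <- length(frame)
  df <- data.frame(
    frame = as.integer(frame), time_ps = as.numeric(time_ps),
    Lx_nm = rep_len(Lx, n), Ly_nm = rep_len(Ly, n), Lz_nm = rep_len(Lz, n)
  )
  if (any(df$Lx_nm <= 0) || any(df$Ly_nm <= 0) || any(df$Lz_nm <= 0))
    stop("box dimensions must be positive")
  if (n > 1 && any(diff(df$time_ps) <= 0)) {
    bad <- which(diff(df$time_ps) <= 0)[1] + 1L
    stop(sprintf("box time not strictly increasing at row %d", bad))
  }
  class(df) <- c("frame_boxes", "data.frame")
  df
}

#' Single-solute coordinate trace
#'
#' A per-molecule time series of coordinates relative to the bilayer
#' midplane; the raw material for density profiles and crossing detection.
#'
#' @param molecule_id identifier.
#' @param species species label.
#' @param z numeric vector of z coordinates (nm), one per frame.
#' @param sampling_interval time between frames, ps.
#' @param xy optional two-column matrix of lateral coordinates (nm).
#' @return A `solute_trace` object.
#' @export
solute_trace <- function(molecule_id, species, z, sampling_interval = 1,
                         xy = NULL) {
  stopifnot(sampling_interval > 0, length(z) >= 1)
  if (!is.null(xy)) {
    xy <- as.matrix(xy)
    stopifnot(ncol(xy) == 2, nrow(xy) == length(z))
  }
  structure(
    list(molecule_id = molecule_id, species = species, z = as.numeric(z),
         xy = xy, sampling_interval = sampling_interval),
    class = "solute_trace"
  )
}

#' @export
print.solute_trace <- function(x, ...) {
  cat(sprintf("solute_trace %s (%s): %d frames at %g ps, z in [%.3f, %.3f] nm\n",
              x$molecule_id, x$species, length(x$z), x$sampling_interval,
              min(x$z), max(x$z)))
  invisible(x)
}

#' Single-lipid phosphate trace
#'
#' Lateral coordinates are expected unwrapped (continuous across the
#' periodic boundary) because they feed mean-squared-displacement
#' estimates; z coordinates may be wrapped.
#'
#' @param lipid_id identifier.
#' @param species lipid species label.
#' @param xy two-column matrix of unwrapped lateral coordinates (nm).
#' @param z numeric vector of phosphate z coordinates (nm).
#' @param sampling_interval time between frames, ps.
#' @return A `lipid_trace` object.
#' @export
lipid_trace <- function(lipid_id, species, xy, z, sampling_interval = 1) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) == length(z), sampling_interval > 0)
  structure(
    list(lipid_id = lipid_id, species = species, xy = xy, z = as.numeric(z),
         sampling_interval = sampling_interval),
    class = "lipid_trace"
  )
}

#' System specification
#'
#' Scalar metadata describing one simulated system at one temperature.
#'
#' @param temperature kelvin.
#' @param n_solutes number of solute molecules in the box.
#' @param concentration nominal aqueous solute concentration, mM.
#' @param n_lipids_per_leaflet optional lipid count per leaflet.
#' @param area_per_lipid optional average area per lipid, nm^2.
#' @param total_time_us optional total simulated time, microseconds.
#' @return A `system_spec` object.
#' @export
system_spec <- function(temperature, n_solutes, concentration,
                        n_lipids_per_leaflet = NULL, area_per_lipid = NULL,
                        total_time_us = NULL) {
  stopifnot(temperature > 0, n_solutes >= 1, concentration > 0)
  if (!is.null(total_time_us)) stopifnot(total_time_us > 0)
  structure(
    list(temperature = temperature, n_solutes = n_solutes,
         concentration = concentration,
         n_lipids_per_leaflet = n_lipids_per_leaflet,
         area_per_lipid = area_per_lipid, total_time_us = total_time_us),
    class = "system_spec"
  )
}

#' Wrap coordinates into the primary periodic cell
#'
#' Maps coordinates into the half-open interval (-L/2, L/2]; a value just
#' above L/2 wraps to just above -L/2.
#'
#' @param z numeric coordinates (nm).
#' @param L box length (nm).
#' @return Wrapped coordinates.
#' @export
wrap_coord <- function(z, L) {
  stopifnot(L > 0)
  w <- z %% L
  w[w > L / 2] <- w[w > L / 2] - L
  w
}

# Unwrap a time series on a periodic interval of length L by choosing, for
# each step, the image nearest the previous (already unwrapped) position.
unwrap_series <- function(z, L) {
  dz <- diff(z)
  dz <- dz - L * round(dz / L)
  cumsum(c(z[1], dz))
}

#' @keywords internal
#' @noRd
NULL

.box_path_for <- function(path) {
  if (grepl("\\.tsv$", path)) sub("\\.tsv$", "_box.tsv", path)
  else paste0(path, "_box.tsv")
}

#' Write a trajectory in the canonical tabular format
#'
#' Writes the particle table to `path` and the box table next to it
#' (`*_box.tsv`).
#'
#' @param particles data frame with columns frame, time_ps, role, species,
#'   molecule_id, x_nm, y_nm, z_nm.
#' @param boxes a [frame_boxes] table.
#' @param path output path for the particle table (TSV).
#' @param box_path optional explicit path for the box table.
#' @return Invisibly, the two paths written.
#' @export
write_trajectory <- function(particles, boxes, path,
                             box_path = .box_path_for(path)) {
  need <- c("frame", "time_ps", "role", "species", "molecule_id",
            "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(particles)))
    stop("particle table must have columns: ", paste(need, collapse = ", "))
  utils::write.table(particles[, need], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(as.data.frame(boxes)[, c("frame", "time_ps", "Lx_nm",
                                              "Ly_nm", "Lz_nm")],
                     box_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(path, box_path))
}

#' Load a trajectory from the canonical tabular format
#'
#' Reads the particle and box tables, validates frame/time consistency and
#' assembles per-molecule traces aligned on the common frame axis.
#'
#' @param path particle table path (TSV).
#' @param spec optional [system_spec]; if it carries `total_time_us` the
#'   frame count is checked against it (within one frame).
#' @param box_path optional explicit box table path.
#' @param known_species optional character vector; species labels outside it
#'   are rejected.
#' @return A list with elements `solutes` (list of [solute_trace]),
#'   `lipids` (list of [lipid_trace]) and `boxes` ([frame_boxes]).
#' @export
load_trajectory <- function(path, spec = NULL, box_path = .box_path_for(path),
                            known_species = NULL) {
  pt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  bx <- utils::read.table(box_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame", "time_ps", "role", "species", "molecule_id",
            "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(pt)))
    stop("particle table must have columns: ", paste(need, collapse = ", "))
  num <- c("time_ps", "x_nm", "y_nm", "z_nm")
  for (cc in c("frame", num)) {
    v <- suppressWarnings(as.numeric(pt[[cc]]))
    if (anyNA(v)) {
      # +1 for the header line so the message names the file line
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   cc, bad + 1L, path))
    }
    pt[[cc]] <- v
  }
  if (!all(pt$role %in% c("solute", "lipid")))
    stop("unknown role label: ", paste(unique(setdiff(pt$role, c("solute", "lipid"))), collapse = ", "))
  if (!is.null(known_species) && !all(pt$species %in% known_species))
    stop("unknown species label: ",
         paste(unique(setdiff(pt$species, known_species)), collapse = ", "))

  boxes <- frame_boxes(bx$frame, bx$time_ps, bx$Lx_nm, bx$Ly_nm, bx$Lz_nm)
  frames <- boxes$frame
  times <- boxes$time_ps

  mk_traces <- function(sub, maker) {
    out <- list()
    for (id in unique(sub$molecule_id)) {
      rows <- sub[sub$molecule_id == id, , drop = FALSE]
      rows <- rows[order(rows$frame), , drop = FALSE]
      if (anyDuplicated(rows$frame))
        stop(sprintf("duplicate frame %d for molecule %s",
                     rows$frame[anyDuplicated(rows$frame)], id))
      if (!identical(as.integer(rows$frame), as.integer(frames)))
        stop(sprintf("molecule %s missing frames (has %d of %d)",
                     id, nrow(rows), length(frames)))
      tdiff <- diff(rows$time_ps)
      if (length(tdiff) && any(tdiff <= 0)) {
        bad_row <- which(tdiff <= 0)[1] + 1L
        stop(sprintf("time not strictly increasing for molecule %s at row %d",
                     id, bad_row))
      }
      dt <- if (length(frames) > 1) times[2] - times[1] else 1
      out[[as.character(id)]] <-
        maker(id, rows$species[1], rows, dt)
    }
    out
  }
  solutes <- mk_traces(pt[pt$role == "solute", , drop = FALSE],
                       function(id, sp, rows, dt)
                         solute_trace(id, sp, rows$z_nm, dt,
                                      xy = cbind(rows$x_nm, rows$y_nm)))
  lipids <- mk_traces(pt[pt$role == "lipid", , drop = FALSE],
                      function(id, sp, rows, dt)
                        lipid_trace(id, sp, cbind(rows$x_nm, rows$y_nm),
                                    rows$z_nm, dt))
  if (!is.null(spec) && !is.null(spec$total_time_us) && length(frames) > 1) {
    dt <- times[2] - times[1]
    expected <- spec$total_time_us * 1e6 / dt
    if (abs(length(frames) - expected) > 1)
      warning(sprintf("frame count %d differs from total_time/%g ps = %.0f",
                      length(frames), dt, expected))
  }
  list(solutes = solutes, lipids = lipids, boxes = boxes)
}

#' Recentre coordinates on the bilayer midplane
#'
#' Per frame, the midplane is the mean of all phosphate z coordinates after
#' unwrapping each lipid's time series (nearest image to the previous
#' frame); solute coordinates are shifted by the midplane and wrapped back
#' into (-Lz/2, Lz/2].  The result is invariant under a global translation
#' of all coordinates and under adding integer multiples of Lz.
#'
#' @param solute_z numeric vector or frames-by-molecules matrix of raw
#'   solute z coordinates (nm).
#' @param lipid_phosphate_z frames-by-lipids matrix of raw phosphate z
#'   coordinates (nm).
#' @param boxes a [frame_boxes] table (per-frame Lz used for wrapping).
#' @return A list with `z` (recentred solute coordinates, same shape as the
#'   input) and `midplane` (per-frame midplane position, nm).
#' @export
recenter_on_bilayer <- function(solute_z, lipid_phosphate_z, boxes) {
  pz <- as.matrix(lipid_phosphate_z)
  if (ncol(pz) == 0 || nrow(pz) == 0)
    stop("frame with zero phosphates: cannot define the bilayer midplane")
  Lz <- boxes$Lz_nm
  if (length(Lz) == 1) Lz <- rep(Lz, nrow(pz))
  stopifnot(length(Lz) == nrow(pz))
  # unwrap each lipid in time so leaflet membership is stable, then average
  L0 <- Lz[1]
  pz_un <- apply(pz, 2, unwrap_series, L = L0)
  if (is.null(dim(pz_un))) pz_un <- matrix(pz_un, nrow = nrow(pz))
  midplane <- rowMeans(pz_un)
  zm <- as.matrix(solute_z)
  out <- zm - midplane  # recycled by column
  out <- vapply(seq_len(ncol(out)),
                function(j) wrap_coord(out[, j], L0),
                numeric(nrow(out)))
  if (is.vector(solute_z)) out <- drop(out)
  list(z = out, midplane = midplane)
}

#' Membrane area
#'
#' Either the time-averaged lateral box cross-section, or the product of
#' area per lipid and lipid count per leaflet.
#'
#' @param boxes optional [frame_boxes]; uses mean(Lx*Ly).
#' @param spec optional [system_spec] carrying `area_per_lipid` and
#'   `n_lipids_per_leaflet`.
#' @return Membrane area S in nm^2.
#' @export
membrane_area <- function(boxes = NULL, spec = NULL) {
  if (!is.null(boxes)) return(mean(boxes$Lx_nm * boxes$Ly_nm))
  if (!is.null(spec) && !is.null(spec$area_per_lipid) &&
      !is.null(spec$n_lipids_per_leaflet))
    return(spec$area_per_lipid * spec$n_lipids_per_leaflet)
  stop("need either per-frame box dimensions or area_per_lipid with n_lipids_per_leaflet")
}
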