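# Radial and spatial distribution functions.
#
# g(r) is normalised to uniform density: peaks above 1 at O...H distances
# of 200-300 pm signal hydrogen bonds. SDFs report 3-D number density
# (nm^-3) of an observed site in a frame rigidly attached to a reference
# molecule, averaged over references and frames.

#' Radial distribution function between two site selections
#'
#' `g(r) = <pair count in shell> / (shell volume * rho_obs * N_ref)`,
#' with `rho_obs` the uniform number density of the observed selection.
#' Distances use the minimum image convention; bins are half-open
#' `[r, r + dr)`. Self pairs are always excluded; pairs within one molecule
#' are excluded by default (the usual intermolecular convention for
#' ion-ion RDFs) and can be kept with `exclude_intramolecular = FALSE`.
#'
#' @param traj a `Trajectory`.
#' @param topo a `Topology`.
#' @param ref_sel,obs_sel site-label character vectors (reference and
#'   observed selections).
#' @param r_max maximum distance, pm; must not exceed half the smallest
#'   box edge.
#' @param n_bins number of bins.
#' @param exclude_intramolecular drop same-molecule pairs.
#' @return An `RDFResult`: data.frame-like list with `r` (bin centres, pm),
#'   `g`, `counts`, plus `r_max`, `bin_width`, `n_ref`, `n_obs`,
#'   `enumerated`.
#' @export
compute_rdf <- function(traj, topo, ref_sel, obs_sel, r_max = 1000,
                        n_bins = 100, exclude_intramolecular = TRUE) {
  half_min_edge <- min(traj$box) / 2
  if (r_max > half_min_edge)
    stop(sprintf("r_max (%g pm) exceeds half the smallest box edge (%g pm)",
                 r_max, half_min_edge))
  ref <- select_sites(topo, ref_sel)
  obs <- select_sites(topo, obs_sel)
  res <- rdf_count_kernel(as.numeric(traj$coords), dim(traj$coords),
                          ref - 1L, obs - 1L,
                          as.integer(topo$atoms$molecule_id), traj$box,
                          r_max, as.integer(n_bins), exclude_intramolecular)
  dr <- r_max / n_bins
  edges <- dr * (0:n_bins)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  vol <- mean(apply(traj$box, 1, prod))
  rho_obs <- length(obs) / vol
  norm <- n_frames(traj) * length(ref) * shell_vol * rho_obs
  structure(list(r = edges[-1] - dr / 2, g = res$counts / norm,
                 counts = res$counts, r_max = r_max, bin_width = dr,
                 n_ref = length(ref), n_obs = length(obs),
                 enumerated = res$enumerated),
            class = "RDFResult")
}

#' @export
print.RDFResult <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("RDF: %d bins to %g pm; max g = %.3f at r = %g pm\n",
              length(x$g), x$r_max, x$g[pk], x$r[pk]))
  invisible(x)
}

#' Write an RDF as a two-column CSV (r_pm, g)
#' @param rdf an `RDFResult`.
#' @param path output file.
#' @export
write_rdf_csv <- function(rdf, path) {
  write.csv(data.frame(r_pm = rdf$r, g = rdf$g), path, row.names = FALSE)
  invisible(path)
}

#' Unweighted centroid of a ring, made whole across the boundary
#'
#' Ring atoms are reconstructed by minimum image against the first ring
#' atom before averaging, so a ring split across the periodic boundary
#' yields the centroid of the reconstructed ring rather than a naive mean.
#' The result is folded into `[0, L)`.
#'
#' @param frame n_atoms x 3 coordinates, pm.
#' @param idx ring atom indices (>= 3).
#' @param box length-3 box edges, pm.
#' @return length-3 position, pm.
#' @export
ring_centroid <- function(frame, idx, box) {
  if (length(idx) == 0) stop("empty ring atom list")
  if (length(idx) < 3) stop("a ring needs at least 3 atoms")
  xyz <- frame[idx, , drop = FALSE]
  ref <- matrix(xyz[1, ], nrow(xyz), 3, byrow = TRUE)
  whole <- ref + minimum_image(ref, xyz, box)
  ctr <- colMeans(whole)
  ctr - box * floor(ctr / box)
}

#' Local orthonormal frame from three anchor centroids
#'
#' Origin at the centroid of the origin set; x-axis toward the centroid of
#' the x set; z-axis normal to the plane through the three centroids
#' (right-handed: `z = x_dir cross plane_dir`, `y = z cross x`). Anchors
#' are made whole by minimum image against the first origin atom.
#'
#' @param frame n_atoms x 3 coordinates, pm.
#' @param origin_idx,x_idx,plane_idx atom index sets for the three anchors.
#' @param box length-3 box edges, pm.
#' @return a `LocalFrame`: list with `origin` (pm) and `axes` (3 x 3
#'   orthonormal matrix, rows = x, y, z).
#' @export
build_local_frame <- function(frame, origin_idx, x_idx, plane_idx, box) {
  anchor_centroid <- function(idx, ref) {
    xyz <- frame[idx, , drop = FALSE]
    refm <- matrix(ref, nrow(xyz), 3, byrow = TRUE)
    colMeans(refm + minimum_image(refm, xyz, box))
  }
  ref <- frame[origin_idx[1], ]
  o <- anchor_centroid(origin_idx, ref)
  cx <- anchor_centroid(x_idx, ref)
  cp <- anchor_centroid(plane_idx, ref)
  vx <- cx - o
  vp <- cp - o
  nx <- sqrt(sum(vx^2))
  if (nx < 1e-9) stop("degenerate frame: origin and x anchors coincide")
  ex <- vx / nx
  vz <- c(vx[2] * vp[3] - vx[3] * vp[2],
          vx[3] * vp[1] - vx[1] * vp[3],
          vx[1] * vp[2] - vx[2] * vp[1])
  nz <- sqrt(sum(vz^2))
  if (nz < 1e-9) stop("degenerate frame: anchors are collinear")
  ez <- vz / nz
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  structure(list(origin = o, axes = rbind(x = ex, y = ey, z = ez)),
            class = "LocalFrame")
}

#' Spatial distribution function in a reference molecule's local frame
#'
#' For every reference molecule and frame, observed positions (atoms of
#' given site labels, or ring centroids) are expressed in the reference's
#' local frame via minimum image, then binned on a cubic voxel grid
#' spanning `[-extent, extent]` per axis. Densities are number densities
#' in nm^-3: counts / (voxel volume * n_references * n_frames).
#'
#' @param traj a `Trajectory`.
#' @param topo a `Topology`.
#' @param ref_species species carrying the reference frame.
#' @param origin_sites,x_sites,plane_sites within-molecule anchor
#'   definitions: site labels (resolved per reference molecule) or integer
#'   within-molecule atom offsets.
#' @param obs_sel observed sites: character site labels, or
#'   `list(species =, ring =)` to observe ring centroids.
#' @param extent half-width of the grid, pm; must not exceed half the
#'   smallest box edge.
#' @param voxel voxel edge, pm; must divide `2 * extent`.
#' @return An `SDFGrid`: list with `density` (3-D array, nm^-3), voxel
#'   `centers` per axis (pm), `voxel`, `extent`, `n_ref`, `n_frames`,
#'   `n_inside` (average observed count inside the grid per reference per
#'   frame).
#' @export
compute_sdf <- function(traj, topo, ref_species, origin_sites, x_sites,
                        plane_sites, obs_sel, extent = 800, voxel = 50) {
  if (extent > min(traj$box) / 2)
    stop("extent exceeds half the smallest box edge")
  nv <- 2 * extent / voxel
  if (abs(nv - round(nv)) > 1e-9) stop("voxel must divide 2 * extent")
  nv <- as.integer(round(nv))
  refs <- topo$molecules[topo$molecules$species == ref_species, ]
  if (nrow(refs) == 0) stop(sprintf("no molecules of species %s", ref_species))
  resolve <- function(spec, mol) {
    if (is.character(spec)) {
      at <- which(topo$atoms$molecule_id == mol$molecule_id &
                    topo$atoms$site_label %in% spec)
      if (length(at) == 0) stop(sprintf("no anchor atoms '%s' in molecule %d",
                                        paste(spec, collapse = ","),
                                        mol$molecule_id))
      at
    } else mol$first - 1L + as.integer(spec)
  }
  obs_centroid <- !is.character(obs_sel)
  if (obs_centroid) {
    omols <- topo$molecules[topo$molecules$species == obs_sel$species, ]
    if (nrow(omols) == 0) stop(sprintf("no molecules of species %s", obs_sel$species))
    oring <- lapply(omols$molecule_id, ring_indices, topo = topo,
                    ring = obs_sel$ring)
  } else {
    oatoms <- select_sites(topo, obs_sel)
  }
  counts <- array(0, c(nv, nv, nv))
  nf <- n_frames(traj)
  total_inside <- 0
  for (f in seq_len(nf)) {
    fr <- traj$coords[, , f, drop = TRUE]
    box <- traj$box[f, ]
    obs_pos <- if (obs_centroid) {
      t(vapply(oring, function(ix) ring_centroid(fr, ix, box), numeric(3)))
    } else fr[oatoms, , drop = FALSE]
    for (m in seq_len(nrow(refs))) {
      mol <- refs[m, ]
      lf <- build_local_frame(fr,
                              resolve(origin_sites, mol),
                              resolve(x_sites, mol),
                              resolve(plane_sites, mol), box)
      rel <- minimum_image(matrix(lf$origin, nrow(obs_pos), 3, byrow = TRUE),
                           obs_pos, box)
      loc <- rel %*% t(lf$axes)
      ix <- floor((loc + extent) / voxel) + 1
      ok <- rowSums(ix >= 1 & ix <= nv) == 3
      total_inside <- total_inside + sum(ok)
      for (k in which(ok))
        counts[ix[k, 1], ix[k, 2], ix[k, 3]] <-
          counts[ix[k, 1], ix[k, 2], ix[k, 3]] + 1
    }
  }
  denom <- nrow(refs) * nf
  voxel_nm3 <- (voxel / 1000)^3
  centers <- seq(-extent + voxel / 2, extent - voxel / 2, by = voxel)
  structure(list(density = counts / (denom * voxel_nm3),
                 centers = centers, voxel = voxel, extent = extent,
                 n_ref = nrow(refs), n_frames = nf,
                 n_inside = total_inside / denom),
            class = "SDFGrid")
}

#' @export
print.SDFGrid <- function(x, ...) {
  cat(sprintf("SDF: %d^3 voxels of %g pm, max density %.2f nm^-3, %.3f hits/ref/frame\n",
              dim(x$density)[1], x$voxel, max(x$density), x$n_inside))
  invisible(x)
}

#' Integrate an SDF grid back to an average count
#'
#' Returns the average number of observed atoms inside the grid extent per
#' reference per frame (density integral); equals `n_inside` by
#' construction.
#' @param sdf an `SDFGrid`.
#' @export
sdf_integral <- function(sdf) sum(sdf$density) * (sdf$voxel / 1000)^3

#' Write an SDF as a Gaussian-cube-style text grid plus JSON sidecar
#'
#' The cube body stores density in nm^-3 on a grid whose header is given
#' in pm (not bohr); the sidecar records the frame definition and a
#' suggested isovalue (half the maximum).
#'
#' @param sdf an `SDFGrid`.
#' @param path output `.cube` path; the sidecar gets `.json` appended.
#' @export
write_sdf_cube <- function(sdf, path) {
  nv <- dim(sdf$density)[1]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("iltraj spatial distribution function",
               "density in nm^-3; grid units pm (not bohr)"), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", 0,
                     -sdf$extent, -sdf$extent, -sdf$extent), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", nv, sdf$voxel, 0, 0), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", nv, 0, sdf$voxel, 0), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", nv, 0, 0, sdf$voxel), con)
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    row <- sdf$density[i, j, ]
    writeLines(paste(sprintf("%13.5e", row), collapse = " "), con)
  }
  jsonlite::write_json(list(voxel_pm = sdf$voxel, extent_pm = sdf$extent,
                            n_ref = sdf$n_ref, n_frames = sdf$n_frames,
                            isovalue_suggestion = max(sdf$density) / 2),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
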