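# Shared fixture builders. All fixtures are constructed in code; nothing
# is read from disk except through tempfiles written by the tests.

# topology of n single-atom molecules, one species
point_topology <- function(n, label = "X", mass = 1, species = "pt",
                           charge = NA_real_, sigma = NA_real_,
                           epsilon = NA_real_) {
  sp <- list(list(atoms = data.frame(element = "X", site_label = label,
                                     mass = mass, charge = charge,
                                     sigma = sigma, epsilon = epsilon)))
  names(sp) <- species
  counts <- n
  names(counts) <- species
  topology(sp, counts)
}

# static trajectory: one frame repeated, coords given as n x 3 matrix (pm)
static_trajectory <- function(coords, box, frames = 1, timestep = 1) {
  co <- array(0, c(nrow(coords), 3, frames))
  for (f in seq_len(frames)) co[, , f] <- coords
  trajectory(co, box, timestep, wrapped = TRUE)
}

# brute-force minimum-image displacement over all 27 neighbour images
brute_min_image <- function(a, b, box) {
  best <- NULL; best_r <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (b + c(ix, iy, iz) * box) - a
    r <- sqrt(sum(d^2))
    if (r < best_r) { best_r <- r; best <- d }
  }
  best
}

# naive O(N^2) RDF histogram oracle (same binning convention)
brute_rdf_counts <- function(traj, topo, ref, obs, r_max, n_bins,
                             excl_intra = TRUE) {
  dr <- r_max / n_bins
  counts <- numeric(n_bins)
  mol <- topo$atoms$molecule_id
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$coords[, , f, drop = TRUE]
    box <- traj$box[f, ]
    for (i in ref) for (j in obs) {
      if (i == j) next
      if (excl_intra && mol[i] == mol[j]) next
      d <- minimum_image(fr[i, ], fr[j, ], box)
      r <- sqrt(sum(d^2))
      if (r < r_max) {
        b <- floor(r / dr) + 1
        if (b <= n_bins) counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# brute-force pooled occupancy autocorrelation (time-origin average)
brute_acf <- function(h, max_lag_frames) {
  nt <- ncol(h)
  m <- mean(h)
  A <- vapply(0:max_lag_frames, function(tau) {
    vals <- h[, 1:(nt - tau), drop = FALSE] * h[, (1 + tau):nt, drop = FALSE]
    mean(rowMeans(vals))
  }, numeric(1))
  (A - m^2) / (m - m^2)
}

# hand-built BondOccupancy from an explicit logical matrix
manual_occupancy <- function(h, donors, acceptors, topo, timestep = 1,
                             donor_labels = "D", acceptor_labels = "A",
                             r_cut = 300) {
  mol <- topo$atoms$molecule_id
  structure(list(
    pairs = data.frame(donor = donors, acceptor = acceptors,
                       intramolecular = mol[donors] == mol[acceptors]),
    h = h, timestep = timestep,
    criterion = hbond_criterion(donor_labels, acceptor_labels, r_cut),
    n_candidates = nrow(h)), class = "BondOccupancy")
}
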