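# Hydrogen-bond detection, intermittent lifetimes, network topology.
#
# A hydrogen bond exists when the minimum-image O...H distance is at or
# below the cutoff (default 300 pm); no angle criterion is applied. The
# intermittent lifetime is the correlation time of the pair occupancy
# indicator h(t), allowing bonds to break and reform.

#' Geometric hydrogen-bond criterion
#'
#' @param donors site labels of donor hydrogen atoms.
#' @param acceptors site labels of acceptor atoms.
#' @param r_cut distance cutoff, pm (default 300). A pair exactly at the
#'   cutoff counts as bonded (closed ball).
#' @return an `HBondCriterion`.
#' @export
hbond_criterion <- function(donors, acceptors, r_cut = 300) {
  stopifnot(r_cut > 0, length(donors) > 0, length(acceptors) > 0)
  structure(list(donors = donors, acceptors = acceptors, r_cut = r_cut),
            class = "HBondCriterion")
}

#' Hydrogen-bond occupancy time series
#'
#' Scans every (donor-H, acceptor) candidate pair over all frames and
#' records a boolean occupancy matrix. Candidate pairs never bonded during
#' the window are counted (`n_candidates`) but not stored: they carry no
#' lifetime or flow information and would otherwise dominate memory.
#'
#' @param traj a `Trajectory`.
#' @param topo a `Topology`.
#' @param criterion an `HBondCriterion`.
#' @return a `BondOccupancy`: `pairs` data.frame (`donor`, `acceptor`
#'   atom indices, `intramolecular` flag), logical matrix `h`
#'   (pairs x frames), `timestep`, `criterion`, `n_candidates`.
#' @export
occupancy <- function(traj, topo, criterion) {
  if (criterion$r_cut > min(traj$box) / 2)
    stop("r_cut exceeds half the smallest box edge")
  don <- select_sites(topo, criterion$donors)
  acc <- select_sites(topo, criterion$acceptors)
  res <- occupancy_kernel(as.numeric(traj$coords), dim(traj$coords),
                          don - 1L, acc - 1L, traj$box, criterion$r_cut)
  mol <- topo$atoms$molecule_id
  pairs <- data.frame(donor = res$donor, acceptor = res$acceptor,
                      intramolecular = mol[res$donor] == mol[res$acceptor])
  structure(list(pairs = pairs, h = res$h, timestep = traj$timestep,
                 criterion = criterion, n_candidates = res$n_candidates),
            class = "BondOccupancy")
}

#' @export
print.BondOccupancy <- function(x, ...) {
  cat(sprintf("BondOccupancy: %d ever-bonded pairs (of %g candidates), %d frames\n",
              nrow(x$pairs), x$n_candidates, ncol(x$h)))
  invisible(x)
}

# Linear (non-circular) autocorrelation sums S(tau) = sum_t h_t h_{t+tau}
# for each row of h, lags 0..max_lag, via zero-padded FFT.
acf_sums <- function(h, max_lag) {
  nt <- ncol(h)
  n <- 2^ceiling(log2(2 * nt))
  m <- matrix(0, n, nrow(h))
  m[seq_len(nt), ] <- t(h)
  ft <- stats::mvfft(m)
  s <- Re(stats::mvfft(ft * Conj(ft), inverse = TRUE)) / n
  t(s[seq_len(max_lag + 1), , drop = FALSE])
}

#' Intermittent hydrogen-bond lifetime from occupancy autocorrelation
#'
#' Computes `C(t) = (<h(0)h(t)> - <h>^2) / (<h> - <h>^2)`, with the
#' first moment and products pooled over all stored (ever-bonded) pairs
#' and all sliding time origins. The lifetime is the integral of `C`:
#' trapezoid over the resolved lags (down to `c_min`) plus an exponential
#' tail fitted on the last resolved decade of the decay.
#'
#' @param occ a `BondOccupancy`.
#' @param max_lag maximum correlation lag, ps.
#' @param c_min resolution floor: lags after `C` first drops below this
#'   value are considered unresolved noise (default 0.02).
#' @return a `LifetimeResult`: `lag` (ps), `C`, `tau` (ps, or `NA` when
#'   unresolved), `unresolved` flag and reason, tail diagnostics
#'   (`tail_window`, `tail_rate`, `tail_r2`, `plateau`), and a
#'   `near_window_limit` flag when `tau` is comparable to the observation
#'   window (such values carry very large statistical uncertainty).
#' @export
intermittent_lifetime <- function(occ, max_lag = NULL, c_min = 0.02) {
  h <- occ$h * 1
  nt <- ncol(h)
  keep <- rowSums(h) > 0
  if (!any(keep)) stop("no bonds: occupancy matrix is all zeros")
  h <- h[keep, , drop = FALSE]
  dt <- occ$timestep
  if (is.null(max_lag)) max_lag <- (nt - 1) * dt / 2
  lag_f <- floor(max_lag / dt)
  if (lag_f > nt - 1) stop("max_lag exceeds the trajectory length")
  m <- mean(h)
  if (m >= 1 - 1e-12)
    return(structure(list(lag = (0:lag_f) * dt, C = rep(1, lag_f + 1),
                          tau = NA_real_, unresolved = TRUE,
                          reason = "no decay: occupancy constantly bonded"),
                     class = "LifetimeResult"))
  s <- acf_sums(h, lag_f)
  norig <- nt - (0:lag_f)
  A <- colMeans(sweep(s, 2, norig, "/"))   # pooled <h(0)h(t)>
  C <- (A - m^2) / (m - m^2)
  lag <- (0:lag_f) * dt
  below <- which(C <= c_min)
  i_end <- if (length(below) > 0) max(below[1] - 1L, 1L) else lag_f + 1L
  res_idx <- seq_len(i_end)
  trap <- sum(diff(lag[res_idx]) *
                (head(C[res_idx], -1) + tail(C[res_idx], -1)) / 2)
  # exponential tail on the last resolved decade of the decay
  C_end <- C[i_end]
  win <- res_idx[C[res_idx] > 0 & C[res_idx] <= max(10 * C_end, c_min * 10) &
                   lag[res_idx] > 0]
  tail_rate <- NA_real_; tail_r2 <- NA_real_; tail_int <- 0
  if (length(win) >= 3) {
    fit <- lm(log(C[win]) ~ lag[win])
    k <- -coef(fit)[[2]]
    if (is.finite(k) && k > 0) {
      tail_rate <- k
      tail_r2 <- summary(fit)$r.squared
      tail_int <- max(C_end, 0) / k
    }
  }
  tau <- trap + tail_int
  plateau <- if (i_end <= lag_f) mean(C[i_end:(lag_f + 1)]) else NA_real_
  tail_win <- if (length(win) > 0) range(lag[win]) else c(NA_real_, NA_real_)
  structure(list(lag = lag, C = C, tau = tau, unresolved = FALSE,
                 reason = NULL,
                 tail_window = tail_win, tail_rate = tail_rate,
                 tail_r2 = tail_r2, plateau = plateau,
                 near_window_limit = is.finite(tau) && tau > nt * dt / 4),
            class = "LifetimeResult")
}

#' @export
print.LifetimeResult <- function(x, ...) {
  if (x$unresolved) cat(sprintf("Lifetime: unresolved (%s)\n", x$reason))
  else cat(sprintf("Lifetime: tau = %.4g ps%s\n", x$tau,
                   if (isTRUE(x$near_window_limit))
                     " [near window limit: large uncertainty]" else ""))
  invisible(x)
}

#' Export a lifetime curve and summary
#' @param lt a `LifetimeResult`.
#' @param csv_path CSV output (lag_ps, C).
#' @param json_path JSON summary output.
#' @export
write_lifetime <- function(lt, csv_path, json_path = NULL) {
  write.csv(data.frame(lag_ps = lt$lag, C = lt$C), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(tau_ps = lt$tau, unresolved = lt$unresolved,
           tail_rate = lt$tail_rate, tail_r2 = lt$tail_r2,
           near_window_limit = isTRUE(lt$near_window_limit)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Export / import an occupancy matrix (CSV manifest + run-length payload)
#'
#' The manifest records pairs, timestep and cutoff; the payload compresses
#' each pair's 0/1 series as run lengths (starting from state 0), one line
#' per pair.
#'
#' @param occ a `BondOccupancy`.
#' @param manifest_path,payload_path output files.
#' @export
write_occupancy <- function(occ, manifest_path, payload_path) {
  mf <- occ$pairs
  mf$timestep <- occ$timestep
  mf$r_cut <- occ$criterion$r_cut
  mf$n_frames <- ncol(occ$h)
  write.csv(mf, manifest_path, row.names = FALSE)
  lines <- apply(occ$h, 1, function(row) {
    r <- rle(as.integer(row))
    if (r$values[1] == 1L) r <- list(values = c(0L, r$values),
                                     lengths = c(0L, r$lengths))
    paste(r$lengths, collapse = " ")
  })
  writeLines(lines, payload_path)
  invisible(manifest_path)
}

#' @rdname write_occupancy
#' @param donors,acceptors site labels to restore into the criterion.
#' @export
read_occupancy <- function(manifest_path, payload_path,
                           donors = "H", acceptors = "O") {
  mf <- read.csv(manifest_path)
  lines <- readLines(payload_path)
  nf <- mf$n_frames[1]
  h <- t(vapply(lines, function(s) {
    lens <- as.integer(strsplit(s, " ")[[1]])
    vals <- rep(c(0L, 1L), length.out = length(lens))
    as.logical(inverse.rle(list(lengths = lens, values = vals)))
  }, logical(nf), USE.NAMES = FALSE))
  structure(list(pairs = mf[, c("donor", "acceptor", "intramolecular")],
                 h = h, timestep = mf$timestep[1],
                 criterion = hbond_criterion(donors, acceptors, mf$r_cut[1]),
                 n_candidates = nrow(mf)),
            class = "BondOccupancy")
}

#' Hydrogen-bond network topology (Sankey) table
#'
#' Aggregates time-averaged bond counts into donor-class x acceptor-class
#' flows. Flows are reported per donor atom of the row class; acceptor
#' per-atom averages use acceptor-atom denominators. Denominators count
#' every topology atom of the class (bonded or not). Intramolecular bonds
#' can be excluded per class pair, e.g. to drop the permanent internal
#' O-H...O(Car) bond of salicylate from the diagram.
#'
#' @param occ a `BondOccupancy`.
#' @param topo a `Topology`.
#' @param class_map named character: site label -> class, covering every
#'   donor and acceptor label of the criterion.
#' @param exclude_intramolecular class pairs whose intramolecular bonds
#'   are dropped: `TRUE` (all), `FALSE`/`NULL` (none), or a character
#'   vector of `"donorClass->acceptorClass"` entries.
#' @return a `SankeyTable`: `flow` matrix (average bonds per donor atom of
#'   the row class), `donor_per_atom`, `acceptor_per_atom`,
#'   `donor_atoms`, `acceptor_atoms`, `donor_molecules`,
#'   `acceptor_molecules`, `total` (system-wide average bond count).
#' @export
sankey <- function(occ, topo, class_map, exclude_intramolecular = NULL) {
  crit <- occ$criterion
  labels <- unique(c(crit$donors, crit$acceptors))
  unmapped <- setdiff(labels, names(class_map))
  if (length(unmapped) > 0)
    stop(sprintf("site label(s) not mapped to a class: %s",
                 paste(unmapped, collapse = ", ")))
  lab <- topo$atoms$site_label
  dclass_atom <- class_map[lab[occ$pairs$donor]]
  aclass_atom <- class_map[lab[occ$pairs$acceptor]]
  dclasses <- unique(unname(class_map[crit$donors]))
  aclasses <- unique(unname(class_map[crit$acceptors]))
  excl_pair <- function(d, a) {
    if (isTRUE(exclude_intramolecular)) return(TRUE)
    if (is.null(exclude_intramolecular) ||
        isFALSE(exclude_intramolecular)) return(FALSE)
    paste0(d, "->", a) %in% exclude_intramolecular
  }
  mean_h <- rowMeans(occ$h)
  drop <- occ$pairs$intramolecular &
    mapply(excl_pair, dclass_atom, aclass_atom)
  flow_tot <- matrix(0, length(dclasses), length(aclasses),
                     dimnames = list(dclasses, aclasses))
  ok <- !drop
  if (any(ok)) {
    agg <- stats::aggregate(mean_h[ok],
                            list(d = dclass_atom[ok], a = aclass_atom[ok]), sum)
    for (r in seq_len(nrow(agg)))
      flow_tot[agg$d[r], agg$a[r]] <- agg$x[r]
  }
  class_atoms <- function(classes, labels) {
    vapply(classes, function(cl) {
      ls <- labels[class_map[labels] == cl]
      sum(lab %in% ls)
    }, numeric(1))
  }
  class_mols <- function(classes, labels) {
    vapply(classes, function(cl) {
      ls <- labels[class_map[labels] == cl]
      length(unique(topo$atoms$molecule_id[lab %in% ls]))
    }, numeric(1))
  }
  d_atoms <- class_atoms(dclasses, crit$donors)
  a_atoms <- class_atoms(aclasses, crit$acceptors)
  structure(list(
    flow = flow_tot / d_atoms,
    donor_per_atom = rowSums(flow_tot) / d_atoms,
    acceptor_per_atom = colSums(flow_tot) / a_atoms,
    donor_atoms = d_atoms, acceptor_atoms = a_atoms,
    donor_molecules = class_mols(dclasses, crit$donors),
    acceptor_molecules = class_mols(aclasses, crit$acceptors),
    total = sum(flow_tot)), class = "SankeyTable")
}

#' @export
print.SankeyTable <- function(x, ...) {
  cat("Hydrogen-bond flow (average bonds per donor atom):\n")
  print(round(x$flow, 3))
  cat(sprintf("total average bond count: %.3f\n", x$total))
  invisible(x)
}

#' Per-molecule donated / accepted hydrogen-bond counts
#'
#' Scales per-atom class averages by the number of atoms of that class per
#' molecule: e.g. 0.83 bonds per ring proton with 3 ring protons per
#' cation gives 2.49 bonds donated per cation.
#'
#' @param table a `SankeyTable`.
#' @return list with `donated` and `accepted` named vectors (per molecule
#'   of each class).
#' @export
per_molecule_counts <- function(table) {
  list(donated = table$donor_per_atom *
         (table$donor_atoms / table$donor_molecules),
       accepted = table$acceptor_per_atom *
         (table$acceptor_atoms / table$acceptor_molecules))
}

#' Export a Sankey table as JSON (nodes, flows, per-atom and per-molecule
#' numbers) or CSV matrix
#' @param table a `SankeyTable`.
#' @param path output path.
#' @export
write_sankey_json <- function(table, path) {
  pm <- per_molecule_counts(table)
  flows <- data.frame(donor = rep(rownames(table$flow), ncol(table$flow)),
                      acceptor = rep(colnames(table$flow),
                                     each = nrow(table$flow)),
                      per_donor_atom = as.vector(table$flow))
  jsonlite::write_json(
    list(donors = rownames(table$flow), acceptors = colnames(table$flow),
         flows = flows,
         donor_per_atom = as.list(table$donor_per_atom),
         acceptor_per_atom = as.list(table$acceptor_per_atom),
         donor_per_molecule = as.list(pm$donated),
         acceptor_per_molecule = as.list(pm$accepted),
         total = table$total),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sankey_json
#' @export
write_sankey_csv <- function(table, path) {
  write.csv(as.data.frame(table$flow), path, row.names = TRUE)
  invisible(path)
}
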