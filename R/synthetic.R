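# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of its `seed`: the RNG state of the
# calling session is saved and restored, and the same seed always yields
# the same output.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ideal-gas trajectory (uniform, uncorrelated positions)
#'
#' Positions are drawn i.i.d. uniform in the box each frame, giving a
#' structureless fluid: the radial distribution function of this fixture is
#' 1 at every distance up to bin noise, which makes it the oracle for the
#' RDF uniform-density normalisation.
#'
#' @param n number of particles.
#' @param frames number of frames.
#' @param box length-3 box edges, pm.
#' @param timestep frame spacing, ps.
#' @param seed RNG seed.
#' @return a wrapped `Trajectory`.
#' @export
gen_ideal_gas <- function(n = 1000, frames = 500, box = c(3000, 3000, 3000),
                          timestep = 1, seed = 1) {
  with_seed(seed, {
    co <- array(runif(n * 3 * frames), c(n, 3, frames))
    for (d in 1:3) co[, d, ] <- co[, d, ] * box[d]
    trajectory(co, box, timestep, wrapped = TRUE)
  })
}

#' Brownian (Wiener) trajectory with known diffusion coefficient
#'
#' Per-step displacements are i.i.d. Gaussian with variance `2 * D * dt`
#' per dimension, so the Einstein relation `MSD(tau) = 6 D tau` holds
#' exactly in expectation. Output is unwrapped (continuous), as required by
#' MSD analysis.
#'
#' @param n particles.
#' @param frames frames.
#' @param D diffusion coefficient, pm^2/ps (1 pm^2/ps = 1e-12 m^2/s).
#' @param timestep ps.
#' @param box length-3 nominal box, pm (starting positions are uniform in it).
#' @param seed RNG seed.
#' @return an unwrapped `Trajectory`.
#' @export
gen_brownian <- function(n = 500, frames = 2000, D = 100, timestep = 1,
                         box = c(10000, 10000, 10000), seed = 1) {
  stopifnot(D >= 0, frames >= 2)
  with_seed(seed, {
    sdev <- sqrt(2 * D * timestep)
    co <- array(0, c(n, 3, frames))
    co[, , 1] <- matrix(runif(n * 3), n, 3) %*% diag(box)
    steps <- array(rnorm(n * 3 * (frames - 1), sd = sdev), c(n, 3, frames - 1))
    for (f in 2:frames) co[, , f] <- co[, , f - 1] + steps[, , f - 1]
    trajectory(co, box, timestep, wrapped = FALSE)
  })
}

#' Telegraph (two-state Markov) hydrogen-bond fixture
#'
#' Each donor/acceptor pair flips between bound and unbound states as a
#' two-state Markov chain with exact exponential-clock per-step
#' probabilities `1 - exp(-k dt)`, started from the stationary
#' distribution. Geometry realises the state as an O...H distance:
#' `bound_dist` pm when bound, `unbound_dist` pm when unbound, straddling
#' the usual 300 pm criterion with margin, so geometric detection recovers
#' the hidden state exactly. Pairs are laid out on a coarse lattice so
#' cross-pair distances never fall below the cutoff.
#'
#' The analytic intermittent autocorrelation of each pair is
#' `exp(-(k_form + k_break) t)`, giving lifetime `1/(k_form + k_break)`.
#'
#' @param n_pairs donor/acceptor pairs.
#' @param frames frames.
#' @param k_form,k_break formation / breaking rates, 1/ps (>= 0; the chain
#'   needs `k_form + k_break > 0` to mix).
#' @param timestep ps.
#' @param bound_dist,unbound_dist O...H distances in the two states, pm.
#' @param spacing lattice spacing between pairs, pm.
#' @param start optional fixed initial state for all pairs ("bound",
#'   "unbound") instead of a stationary draw.
#' @param seed RNG seed.
#' @return list with `trajectory`, `topology` and the hidden `states`
#'   matrix (`n_pairs x frames`, logical, TRUE = bound).
#' @export
gen_telegraph_bonds <- function(n_pairs = 200, frames = 20000,
                                k_form = 0.001, k_break = 0.01,
                                timestep = 0.5, bound_dist = 250,
                                unbound_dist = 500, spacing = 2000,
                                start = NULL, seed = 1) {
  stopifnot(k_form >= 0, k_break >= 0, frames >= 2)
  with_seed(seed, {
    p_bind <- 1 - exp(-k_form * timestep)
    p_break <- 1 - exp(-k_break * timestep)
    states <- matrix(FALSE, n_pairs, frames)
    states[, 1] <- if (is.null(start)) {
      runif(n_pairs) < k_form / (k_form + k_break)
    } else identical(start, "bound")
    u <- matrix(runif(n_pairs * (frames - 1)), n_pairs, frames - 1)
    for (f in 2:frames) {
      s <- states[, f - 1]
      states[, f] <- ifelse(s, u[, f - 1] >= p_break, u[, f - 1] < p_bind)
    }
    ncell <- ceiling(n_pairs^(1 / 3))
    L <- (ncell + 1) * spacing
    cell <- arrayInd(seq_len(n_pairs), rep(ncell, 3))
    origin <- (cell - 1) * spacing + spacing / 2
    co <- array(0, c(2 * n_pairs, 3, frames))
    oi <- seq(1, 2 * n_pairs, by = 2)   # acceptor O
    hi <- oi + 1                        # donor H
    for (f in seq_len(frames)) {
      fr <- matrix(0, 2 * n_pairs, 3)
      fr[oi, ] <- origin
      d <- ifelse(states[, f], bound_dist, unbound_dist)
      fr[hi, ] <- origin + cbind(d, 0, 0)
      co[, , f] <- fr
    }
    traj <- trajectory(co, rep(L, 3), timestep, wrapped = TRUE)
    species <- list(
      accmol = list(atoms = data.frame(element = "O", site_label = "O(Acc)",
                                       mass = 15.999)),
      donmol = list(atoms = data.frame(element = "H", site_label = "H(Don)",
                                       mass = 1.008)))
    counts <- rep(c(accmol = 1L, donmol = 1L), n_pairs)
    names(counts) <- rep(c("accmol", "donmol"), n_pairs)
    topo <- topology(species, counts)
    list(trajectory = traj, topology = topo, states = states)
  })
}

#' Ring-stacked pair fixture for spatial distribution functions
#'
#' A rigid reference hexagon sits at the box centre in the xy-plane; a
#' partner hexagon's centroid is jittered isotropically around
#' `(0, 0, +/- offset)`, the sign alternating at random per frame. This is
#' the pi-stacking geometry seen between aromatic anions and cations: the
#' SDF of the partner ring centroid in the reference ring's local frame
#' shows exactly two density maxima, above and below the ring plane.
#'
#' @param frames frames.
#' @param offset stacking distance, pm.
#' @param jitter isotropic Gaussian jitter SD of the partner centroid, pm.
#' @param ring_radius hexagon circumradius, pm.
#' @param box length-3 box edges, pm.
#' @param seed RNG seed.
#' @return list with `trajectory` and `topology` (species `refring`,
#'   `partner`, each with a declared ring).
#' @export
gen_stacked_pair <- function(frames = 2000, offset = 350, jitter = 40,
                             ring_radius = 140, box = c(4000, 4000, 4000),
                             seed = 1) {
  with_seed(seed, {
    ctr <- box / 2
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    hex <- cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
    co <- array(0, c(12, 3, frames))
    sgn <- sample(c(-1, 1), frames, replace = TRUE)
    jit <- matrix(rnorm(3 * frames, sd = jitter), frames, 3)
    for (f in seq_len(frames)) {
      ref <- sweep(hex, 2, ctr, "+")
      pc <- ctr + c(0, 0, sgn[f] * offset) + jit[f, ]
      par <- sweep(hex, 2, pc, "+")
      co[, , f] <- rbind(ref, par)
    }
    traj <- trajectory(co, box, 1, wrapped = TRUE)
    ring_atoms <- data.frame(element = "C", site_label = "C(Ring)",
                             mass = 12.011)
    species <- list(
      refring = list(atoms = ring_atoms[rep(1, 6), ], rings = list(ring = 1:6)),
      partner = list(atoms = ring_atoms[rep(1, 6), ], rings = list(ring = 1:6)))
    topo <- topology(species, c(refring = 1L, partner = 1L))
    list(trajectory = traj, topology = topo)
  })
}

#' Gaussian potential-energy traces for the solvation-enthalpy estimator
#'
#' Emulates the three averaged potential-energy series that enter
#' `dH_solv = (E_solution - E_pureIL - E_vacuum) / n_units`: i.i.d.
#' Gaussian samples around stated means.
#'
#' @param means,sds length-3 numeric: solution, pure IL, vacuum strand
#'   (kJ/mol).
#' @param n samples per trace.
#' @param seed RNG seed.
#' @return named list of three numeric vectors
#'   (`solution`, `pure_il`, `vacuum`).
#' @export
gen_energy_traces <- function(means = c(-260000, -255000, -600),
                              sds = c(300, 300, 50), n = 2000, seed = 1) {
  stopifnot(length(means) == 3, length(sds) == 3, all(sds >= 0))
  with_seed(seed, {
    list(solution = rnorm(n, means[1], sds[1]),
         pure_il  = rnorm(n, means[2], sds[2]),
         vacuum   = rnorm(n, means[3], sds[3]))
  })
}

#' Solubility / solvation-enthalpy calibration points on an exact log law
#'
#' Generates pairs obeying `dH_i = c2 * ln(S_i) + c1 + noise`, the
#' relationship used to calibrate the solubility model.
#'
#' @param S solubilities, wt.-% (all > 0).
#' @param c1 intercept, kJ/mol per glucose unit.
#' @param c2 slope, kJ/mol per glucose unit per ln-unit.
#' @param noise_sd Gaussian noise SD on dH, kJ/mol.
#' @param seed RNG seed.
#' @return data.frame with columns `name`, `S`, `dH`.
#' @export
gen_solubility_points <- function(S = c(0.5, 1, 2, 4, 6, 8, 10),
                                  c1 = -60, c2 = -15, noise_sd = 0,
                                  seed = 1) {
  stopifnot(all(S > 0), noise_sd >= 0)
  with_seed(seed, {
    dH <- c2 * log(S) + c1 + rnorm(length(S), 0, noise_sd)
    data.frame(name = sprintf("pt%02d", seq_along(S)), S = S, dH = dH)
  })
}
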