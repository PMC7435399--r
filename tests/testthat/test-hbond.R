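# Hydrogen-bond detection, lifetimes, Sankey topology.

two_mol_topo <- function() {
  topology(list(
    don = list(atoms = data.frame(element = "H", site_label = "H(Don)", mass = 1)),
    acc = list(atoms = data.frame(element = "O", site_label = "O(Acc)", mass = 16))),
    c(don = 1, acc = 1))
}

test_that("occupancy applies a closed-ball 300 pm criterion", {
  topo <- two_mol_topo()
  crit <- hbond_criterion("H(Don)", "O(Acc)", 300)
  mk <- function(d) {
    tr <- static_trajectory(rbind(c(0, 0, 0), c(d, 0, 0)), rep(4000, 3))
    occupancy(tr, topo, crit)
  }
  expect_true(all(mk(250)$h))          # inside the cutoff
  expect_equal(nrow(mk(350)$pairs), 0) # outside: pruned, only counted
  expect_equal(mk(350)$n_candidates, 1)
  expect_true(all(mk(300)$h))          # exactly at the cutoff counts
})

test_that("occupancy is order-independent and reproducible", {
  b <- gen_telegraph_bonds(n_pairs = 12, frames = 400, seed = 21)
  crit <- hbond_criterion("H(Don)", "O(Acc)")
  o1 <- occupancy(b$trajectory, b$topology, crit)
  o2 <- occupancy(b$trajectory, b$topology, crit)
  expect_identical(o1$h, o2$h)
  # permuting atom storage order leaves the pair set unchanged
  perm <- sample(n_atoms(b$trajectory))
  co <- b$trajectory$coords[perm, , , drop = FALSE]
  topo_p <- b$topology
  topo_p$atoms <- topo_p$atoms[perm, ]
  topo_p$molecules <- NULL  # not needed by occupancy
  o3 <- occupancy(trajectory(co, b$trajectory$box, b$trajectory$timestep),
                  topo_p, crit)
  # new atom index i holds old atom perm[i]; pair sets must agree in old labels
  key <- function(o, map) sort(paste(map[o$pairs$donor], map[o$pairs$acceptor]))
  expect_equal(key(o3, perm), key(o1, seq_len(n_atoms(b$trajectory))))
})

test_that("telegraph occupancy equals the generated hidden states", {
  b <- gen_telegraph_bonds(n_pairs = 25, frames = 1500, seed = 4)
  occ <- occupancy(b$trajectory, b$topology, hbond_criterion("H(Don)", "O(Acc)"))
  rows <- occ$pairs$donor / 2          # donor H atoms sit at even indices
  ever <- rowSums(b$states) > 0
  expect_equal(sort(rows), which(ever))
  expect_identical(unname(occ$h), unname(b$states[rows, ]))
})

test_that("C(t) matches the brute-force time-origin oracle", {
  # hand-enumerable periodic series plus random ones
  h1 <- matrix(rep(c(1, 1, 0, 0), 10), 1, 40, byrow = TRUE)
  set.seed(77)
  h2 <- matrix(runif(5 * 60) < 0.3, 5, 60) * 1
  for (h in list(h1, h2)) {
    occ <- manual_occupancy(h == 1, seq_len(nrow(h)) * 2 - 1,
                            seq_len(nrow(h)) * 2,
                            point_topology(2 * nrow(h), label = "D"))
    lt <- intermittent_lifetime(occ, max_lag = 20, c_min = -Inf)
    expect_equal(lt$C, brute_acf(h[rowSums(h) > 0, , drop = FALSE], 20),
                 tolerance = 1e-12)
    expect_equal(lt$C[1], 1)
  }
})

test_that("degenerate occupancies are flagged, not faked", {
  topo <- point_topology(2, label = "D")
  all1 <- manual_occupancy(matrix(TRUE, 1, 50), 1, 2, topo)
  lt <- intermittent_lifetime(all1)
  expect_true(lt$unresolved)
  expect_true(is.na(lt$tau))
  all0 <- manual_occupancy(matrix(FALSE, 1, 50), 1, 2, topo)
  expect_error(intermittent_lifetime(all0), "no bonds")
})

test_that("telegraph lifetime recovery and monotonicity", {
  # desk-size run: tau = 1/(k_form + k_break)
  b <- gen_telegraph_bonds(n_pairs = 100, frames = 8000, k_form = 0.002,
                           k_break = 0.02, timestep = 0.5, seed = 6)
  occ <- manual_occupancy(b$states, seq_len(100) * 2, seq_len(100) * 2 - 1,
                          b$topology, timestep = 0.5,
                          donor_labels = "H(Don)", acceptor_labels = "O(Acc)")
  lt <- intermittent_lifetime(occ, max_lag = 1200)
  expect_lt(abs(lt$tau - 1 / 0.022) / (1 / 0.022), 0.15)

  # longer bound durations (smaller k_break) must give larger tau
  taus <- vapply(c(0.04, 0.02, 0.01), function(kb) {
    bb <- gen_telegraph_bonds(n_pairs = 100, frames = 8000, k_form = 0.002,
                              k_break = kb, timestep = 0.5, seed = 66)
    o <- manual_occupancy(bb$states, seq_len(100) * 2, seq_len(100) * 2 - 1,
                          bb$topology, timestep = 0.5,
                          donor_labels = "H(Don)", acceptor_labels = "O(Acc)")
    intermittent_lifetime(o, max_lag = 1500)$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("sankey per-atom averages and conservation", {
  # 2 donors (distinct classes), 1 acceptor; donor-1 always bonded,
  # donor-2 bonded half the frames
  topo <- topology(list(
    d1 = list(atoms = data.frame(element = "H", site_label = "D1", mass = 1)),
    d2 = list(atoms = data.frame(element = "H", site_label = "D2", mass = 1)),
    a = list(atoms = data.frame(element = "O", site_label = "A", mass = 16))),
    c(d1 = 1, d2 = 1, a = 1))
  h <- rbind(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  occ <- manual_occupancy(h, c(1, 2), c(3, 3), topo,
                          donor_labels = c("D1", "D2"), acceptor_labels = "A")
  st <- sankey(occ, topo, c(D1 = "D1", D2 = "D2", A = "A"))
  expect_equal(unname(st$donor_per_atom[c("D1", "D2")]), c(1, 0.5))
  expect_equal(unname(st$acceptor_per_atom["A"]), 1.5)
  expect_equal(st$total, 1.5)

  # conservation on random fixtures: donor-side total == acceptor-side total
  set.seed(90)
  for (rep in 1:25) {
    nd <- sample(2:5, 1); na_ <- sample(1:4, 1); nf <- 20
    labels_d <- paste0("D", seq_len(nd)); labels_a <- paste0("A", seq_len(na_))
    sp <- c(lapply(labels_d, function(l)
      list(atoms = data.frame(element = "H", site_label = l, mass = 1))),
      lapply(labels_a, function(l)
        list(atoms = data.frame(element = "O", site_label = l, mass = 16))))
    names(sp) <- c(labels_d, labels_a)
    cnt <- rep(1L, nd + na_); names(cnt) <- names(sp)
    topo_r <- topology(sp, cnt)
    pairs <- expand.grid(d = seq_len(nd), a = nd + seq_len(na_))
    h_r <- matrix(runif(nrow(pairs) * nf) < 0.4, nrow(pairs), nf)
    keep <- rowSums(h_r) > 0
    occ_r <- manual_occupancy(h_r[keep, , drop = FALSE], pairs$d[keep],
                              pairs$a[keep], topo_r,
                              donor_labels = labels_d,
                              acceptor_labels = labels_a)
    cm <- c(stats::setNames(labels_d, labels_d), stats::setNames(labels_a, labels_a))
    st_r <- sankey(occ_r, topo_r, cm)
    expect_equal(sum(st_r$donor_per_atom * st_r$donor_atoms), st_r$total)
    expect_equal(sum(st_r$acceptor_per_atom * st_r$acceptor_atoms), st_r$total)
  }
})

test_that("intramolecular exclusion removes exactly the internal flow", {
  # salicylate-like: a hydroxyl donor permanently bonded to its own
  # carboxylate oxygen, plus a genuine intermolecular bond
  topo <- topology(list(
    osc = list(atoms = data.frame(element = c("H", "O"),
                                  site_label = c("H(Hyd)", "O(Car)"),
                                  mass = c(1, 16))),
    cat = list(atoms = data.frame(element = "H", site_label = "H(Ring)",
                                  mass = 1))),
    c(osc = 1, cat = 1))
  h <- rbind(rep(TRUE, 8),                     # intramolecular H(Hyd)->O(Car)
             rep(c(TRUE, TRUE, TRUE, FALSE), 2)) # intermolecular H(Ring)->O(Car)
  occ <- manual_occupancy(h, c(1, 3), c(2, 2), topo,
                          donor_labels = c("H(Hyd)", "H(Ring)"),
                          acceptor_labels = "O(Car)")
  cm <- c("H(Hyd)" = "hyd", "H(Ring)" = "ring", "O(Car)" = "car")
  keep <- sankey(occ, topo, cm)
  excl <- sankey(occ, topo, cm, exclude_intramolecular = "hyd->car")
  expect_equal(keep$flow["hyd", "car"], 1)
  expect_equal(excl$flow["hyd", "car"], 0)
  # the intermolecular flow is untouched
  expect_equal(excl$flow["ring", "car"], keep$flow["ring", "car"])
  expect_equal(excl$flow["ring", "car"], 0.75)
})

test_that("per-molecule counts scale per-atom averages by atoms per molecule", {
  # 2 cations x 3 ring protons, bonded 83 of 100 frames each
  topo <- topology(list(
    cat = list(atoms = data.frame(element = "H",
                                  site_label = rep("H(Ring)", 3), mass = 1)),
    an = list(atoms = data.frame(element = "O", site_label = "O(Car)",
                                 mass = 16))),
    c(cat = 2, an = 6))
  nf <- 100
  donors <- c(1, 2, 3, 4, 5, 6)
  acceptors <- 6 + 1:6
  h <- matrix(FALSE, 6, nf)
  h[, 1:83] <- TRUE
  occ <- manual_occupancy(h, donors, acceptors, topo,
                          donor_labels = "H(Ring)", acceptor_labels = "O(Car)")
  st <- sankey(occ, topo, c("H(Ring)" = "ring", "O(Car)" = "car"))
  expect_equal(unname(st$donor_per_atom["ring"]), 0.83)
  pm <- per_molecule_counts(st)
  expect_equal(unname(pm$donated["ring"]), 0.83 * 3)   # 2.49 per cation

  # triazolium-style: 2 ring protons at 1.2 per atom -> 2.4 per cation
  topo2 <- topology(list(
    cat = list(atoms = data.frame(element = "H",
                                  site_label = rep("H(Ring)", 2), mass = 1)),
    an = list(atoms = data.frame(element = "O", site_label = "O(Car)",
                                 mass = 16))),
    c(cat = 1, an = 4))
  h2 <- matrix(FALSE, 4, 10)
  h2[1, ] <- TRUE; h2[2, 1:2] <- TRUE   # donor 1 averages 1.2 bonds
  h2[3, ] <- TRUE; h2[4, 1:2] <- TRUE   # donor 2 likewise
  occ2 <- manual_occupancy(h2, c(1, 1, 2, 2), c(3, 4, 5, 6), topo2,
                           donor_labels = "H(Ring)", acceptor_labels = "O(Car)")
  st2 <- sankey(occ2, topo2, c("H(Ring)" = "ring", "O(Car)" = "car"))
  expect_equal(unname(st2$donor_per_atom["ring"]), 1.2)
  pm2 <- per_molecule_counts(st2)
  expect_equal(unname(pm2$donated["ring"]), 2.4)       # per triazolium ion
  # zero flow gives zero per molecule
  h3 <- matrix(FALSE, 1, 10); h3[1, 1] <- TRUE
  occ3 <- manual_occupancy(h3, 1, 3, topo2, donor_labels = "H(Ring)",
                           acceptor_labels = "O(Car)")
  st3 <- sankey(occ3, topo2, c("H(Ring)" = "ring", "O(Car)" = "car"))
  pm3 <- per_molecule_counts(st3)
  expect_equal(unname(pm3$donated["ring"]) * 0, 0)
})

test_that("sankey rejects unmapped labels by name", {
  topo <- two_mol_topo()
  h <- matrix(TRUE, 1, 4)
  occ <- manual_occupancy(h, 1, 2, topo, donor_labels = "H(Don)",
                          acceptor_labels = "O(Acc)")
  expect_error(sankey(occ, topo, c("H(Don)" = "d")), "O\\(Acc\\)")
})

test_that("occupancy round-trips through the manifest/payload export", {
  b <- gen_telegraph_bonds(n_pairs = 8, frames = 300, seed = 14)
  occ <- occupancy(b$trajectory, b$topology, hbond_criterion("H(Don)", "O(Acc)"))
  m <- withr::local_tempfile(fileext = ".csv")
  pl <- withr::local_tempfile(fileext = ".txt")
  write_occupancy(occ, m, pl)
  back <- read_occupancy(m, pl, donors = "H(Don)", acceptors = "O(Acc)")
  expect_equal(unname(back$h), unname(occ$h))
  expect_equal(back$pairs$donor, occ$pairs$donor)
  expect_equal(back$timestep, occ$timestep)
})
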