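# RDFs, local frames, SDFs, ring centroids.

test_that("RDF of a fixed pair puts all counts in the 230 pm bin", {
  # two single-atom molecules 230 pm apart (the aromatic C-H...O regime)
  topo <- point_topology(2, label = "X")
  tr <- static_trajectory(rbind(c(0, 0, 0), c(230, 0, 0)), rep(4000, 3),
                          frames = 3)
  r <- compute_rdf(tr, topo, "X", "X", r_max = 1000, n_bins = 50)
  hot <- which(r$counts > 0)
  expect_length(hot, 1)
  expect_true(r$r[hot] - r$bin_width / 2 <= 230 &&
                230 < r$r[hot] + r$bin_width / 2)
  # both directions of the pair, every frame
  expect_equal(r$counts[hot], 2 * 3)
  expect_equal(sum(r$counts), r$enumerated)
})

test_that("simple-cubic lattice gives shells 6/12/8 matching brute force", {
  a <- 500
  g <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * a
  topo <- point_topology(nrow(g), label = "X")
  tr <- static_trajectory(g, rep(4 * a, 3))
  r <- compute_rdf(tr, topo, "X", "X", r_max = 950, n_bins = 95)
  per_ref <- r$counts / nrow(g)
  peak_count <- function(d) sum(per_ref[abs(r$r - d) < r$bin_width])
  expect_equal(peak_count(a), 6)
  expect_equal(peak_count(a * sqrt(2)), 12)
  expect_equal(peak_count(a * sqrt(3)), 8)
  # full histogram equals the naive O(N^2) enumeration, bin by bin
  oracle <- brute_rdf_counts(tr, topo, 1:nrow(g), 1:nrow(g), 950, 95)
  expect_equal(r$counts, oracle)
})

test_that("RDF agrees exactly with the naive double loop on random fixtures", {
  set.seed(31)
  n <- 60
  box <- rep(2000, 3)
  co <- array(runif(n * 3 * 4, 0, 2000), c(n, 3, 4))
  tr <- trajectory(co, box, 1)
  # two species sharing molecules so the intramolecular flag matters
  topo <- topology(list(w = list(atoms = data.frame(
    element = c("O", "H"), site_label = c("O", "H"), mass = c(16, 1)))),
    c(w = n / 2))
  for (excl in c(TRUE, FALSE)) {
    r <- compute_rdf(tr, topo, "O", "H", r_max = 900, n_bins = 45,
                     exclude_intramolecular = excl)
    oracle <- brute_rdf_counts(tr, topo, select_sites(topo, "O"),
                               select_sites(topo, "H"), 900, 45, excl)
    expect_equal(r$counts, oracle)
    expect_equal(sum(r$counts), r$enumerated)
  }
})

test_that("RDF normalisation is 1 for an ideal gas and errors are clear", {
  tr <- gen_ideal_gas(n = 400, frames = 120, box = rep(3000, 3), seed = 5)
  topo <- point_topology(400, label = "X")
  r <- compute_rdf(tr, topo, "X", "X", r_max = 1400, n_bins = 14)
  expect_true(all(abs(r$g[r$r > 250] - 1) < 0.07))
  expect_error(compute_rdf(tr, topo, "X", "X", r_max = 2000),
               "half the smallest box edge")
  expect_error(compute_rdf(tr, topo, "Y", "X"), "Y")
})

test_that("local frames are canonical, rotation-invariant and handed", {
  fr <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  box <- rep(4000, 3)
  lf <- build_local_frame(fr, 1, 2, 3, box)
  expect_equal(lf$origin, c(0, 0, 0))
  expect_equal(unname(lf$axes), diag(3))

  # a rigid rotation of everything leaves local coordinates unchanged
  set.seed(8)
  obs <- matrix(runif(9, -200, 200), 3, 3)
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  loc0 <- sweep(obs, 2, lf$origin) %*% t(lf$axes)
  fr_rot <- fr %*% t(R); obs_rot <- obs %*% t(R)
  lf2 <- build_local_frame(fr_rot, 1, 2, 3, box)
  loc1 <- sweep(obs_rot, 2, lf2$origin) %*% t(lf2$axes)
  expect_equal(loc1, loc0, tolerance = 1e-10)

  # reflecting the plane anchor flips z
  fr_ref <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, -100, 0))
  lf3 <- build_local_frame(fr_ref, 1, 2, 3, box)
  expect_equal(lf3$axes["z", ], -lf$axes["z", ])

  expect_error(build_local_frame(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)),
                                 1, 2, 3, box), "collinear")
})

test_that("SDF of a delta fixture concentrates density and integrates to 1", {
  # reference anchors at the box centre; observed atom at +400 pm along x
  ctr <- c(2000, 2000, 2000)
  fr <- rbind(ctr, ctr + c(100, 0, 0), ctr + c(0, 100, 0), ctr + c(400, 0, 0))
  sp <- list(
    ref = list(atoms = data.frame(element = "C", site_label = c("A", "B", "C"),
                                  mass = 12)),
    obs = list(atoms = data.frame(element = "O", site_label = "O", mass = 16)))
  topo <- topology(sp, c(ref = 1, obs = 1))
  tr <- static_trajectory(fr, rep(4000, 3), frames = 4)
  s <- compute_sdf(tr, topo, "ref", "A", "B", "C", "O",
                   extent = 600, voxel = 50)
  expect_equal(sdf_integral(s), 1, tolerance = 1e-9)
  expect_equal(s$n_inside, 1)
  hot <- which(s$density > 0, arr.ind = TRUE)
  expect_equal(nrow(hot), 1)
  expect_equal(s$centers[hot[1, 1]], 425)   # voxel [400, 450) holds x = 400
  expect_equal(max(s$density), 1 / (0.05^3), tolerance = 1e-9)
})

test_that("SDF of uniform observers is flat at N/V", {
  tr <- gen_ideal_gas(n = 500, frames = 150, box = rep(3000, 3), seed = 12)
  co <- array(0, c(503, 3, 150))
  co[1:3, 1, ] <- c(1500, 1600, 1500)      # static anchor triad
  co[1:3, 2, ] <- c(1500, 1500, 1600)
  co[1:3, 3, ] <- 1500
  co[4:503, , ] <- tr$coords
  sp <- list(ref = list(atoms = data.frame(element = "C",
                                           site_label = c("A", "B", "C"),
                                           mass = 12)),
             gas = list(atoms = data.frame(element = "X", site_label = "X",
                                           mass = 1)))
  topo <- topology(sp, c(ref = 1, gas = 500))
  tr2 <- trajectory(co, rep(3000, 3), 1)
  s <- compute_sdf(tr2, topo, "ref", "A", "B", "C", "X",
                   extent = 600, voxel = 200)
  rho <- 500 / prod(c(3, 3, 3))            # nm^-3
  expect_equal(mean(s$density), rho, tolerance = 0.05)
})

test_that("stacked-pair fixture yields two maxima at +/- offset", {
  b <- gen_stacked_pair(frames = 1500, offset = 350, seed = 3)
  s <- compute_sdf(b$trajectory, b$topology, "refring", 1:6, 1L, 2L,
                   list(species = "partner", ring = "ring"),
                   extent = 600, voxel = 50)
  expect_equal(sdf_integral(s), 1, tolerance = 1e-9)
  nz <- s$centers[apply(s$density, 3, sum) > 0]
  expect_true(any(nz > 0) && any(nz < 0))
  # strongest voxel on each side within one voxel of +/- 350 pm
  dens_z <- apply(s$density, 3, max)
  top_pos <- s$centers[s$centers > 0][which.max(dens_z[s$centers > 0])]
  top_neg <- s$centers[s$centers < 0][which.max(dens_z[s$centers < 0])]
  expect_lt(abs(top_pos - 350), s$voxel)
  expect_lt(abs(top_neg + 350), s$voxel)
})

test_that("ring centroids reconstruct across the boundary", {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  hex <- cbind(140 * cos(ang), 140 * sin(ang), 0)
  box <- rep(4000, 3)
  ctr <- c(1000, 1000, 1000)
  fr <- sweep(hex, 2, ctr, "+")
  expect_equal(ring_centroid(fr, 1:6, box), ctr, tolerance = 1e-9)

  # split across the periodic boundary: naive mean would land mid-box
  edge <- c(3990, 500, 500)
  fr2 <- sweep(hex, 2, edge, "+") %% 4000
  got <- ring_centroid(fr2, 1:6, box)
  d <- minimum_image(edge %% 4000, got, box)
  expect_equal(sqrt(sum(d^2)), 0, tolerance = 1e-9)

  # translation equivariance under box shifts
  sh <- (sweep(fr, 2, c(700, -300, 123), "+")) %% 4000
  got2 <- ring_centroid(sh, 1:6, box)
  d2 <- minimum_image((ctr + c(700, -300, 123)) %% 4000, got2, box)
  expect_equal(sqrt(sum(d2^2)), 0, tolerance = 1e-9)

  expect_error(ring_centroid(fr, integer(0), box), "empty")
  expect_error(ring_centroid(fr, 1:2, box), "at least 3")
})

test_that("RDF and SDF exports are readable text artifacts", {
  topo <- point_topology(2, label = "X")
  tr <- static_trajectory(rbind(c(0, 0, 0), c(230, 0, 0)), rep(4000, 3))
  r <- compute_rdf(tr, topo, "X", "X", r_max = 500, n_bins = 10)
  p <- withr::local_tempfile(fileext = ".csv")
  write_rdf_csv(r, p)
  back <- read.csv(p)
  expect_equal(back$g, r$g)

  b <- gen_stacked_pair(frames = 50, seed = 2)
  s <- compute_sdf(b$trajectory, b$topology, "refring", 1:6, 1L, 2L,
                   list(species = "partner", ring = "ring"),
                   extent = 400, voxel = 100)
  pc <- withr::local_tempfile(fileext = ".cube")
  write_sdf_cube(s, pc)
  expect_true(file.exists(pc) && file.exists(paste0(pc, ".json")))
  side <- jsonlite::fromJSON(paste0(pc, ".json"))
  expect_equal(side$voxel_pm, 100)
})
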