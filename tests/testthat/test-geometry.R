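test_that("centroids equal brute-force means", {
  df <- rbind(ca_residue("A", "A", 1, 0, 0, 0),
              ca_residue("A", "A", 2, 2, 0, 0))
  top <- make_topology(df)
  coords <- frame_coords(topo_trajectory(top), 1)
  expect_equal(centroid(coords, 1:2), c(1, 0, 0))
  expect_equal(centroid(coords, 2L), c(2, 0, 0))
  expect_error(centroid(coords, integer(0)), "empty")

  set.seed(1)
  big <- do.call(rbind, lapply(1:83, function(i) {
    ca_residue("A", "A", i, rnorm(1, 0, 10), rnorm(1, 0, 10), rnorm(1, 0, 10))
  }))
  btop <- make_topology(big)
  bc <- frame_coords(topo_trajectory(btop), 1)
  expect_equal(centroid(bc, 1:83), brute_centroid(bc, 1:83), tolerance = 1e-9)
})

test_that("hinge angle reproduces constructed geometries and symmetries", {
  df <- rbind(ca_residue("HD", "A", 1, 0, 1, 0),
              ca_residue("HG", "B", 1, 0, 0, 0),
              ca_residue("AR", "C", 1, 1, 0, 0))
  traj <- topo_trajectory(make_topology(df))
  def <- hinge_definition("HD:1:CA", "HG:1:CA", "AR:1:CA")
  expect_equal(hinge_angle(traj, def), 90, tolerance = 1e-9)

  # collinear with the hinge between head and arm end -> 180 degrees
  df2 <- df
  df2$x <- c(-1, 0, 1)
  df2$y <- 0
  traj2 <- topo_trajectory(make_topology(df2))
  expect_equal(hinge_angle(traj2, def), 180, tolerance = 1e-9)

  # invariant to swapping head and arm end
  swapped <- hinge_definition("AR:1:CA", "HG:1:CA", "HD:1:CA")
  expect_equal(hinge_angle(traj, swapped), hinge_angle(traj, def))

  # coincident centroids are an error
  df3 <- df
  df3[3, c("x", "y", "z")] <- df3[2, c("x", "y", "z")]
  expect_error(hinge_angle(topo_trajectory(make_topology(df3)), def),
               "coincident")

  # synthetic articulated structure built at its nominal angle
  spec <- synthetic_spec(n_runs = 1, frames_per_run = 1, seed = 1,
                         hinge = hinge_gaussian(121.6, 0), jitter_sd = 0)
  straj <- generate_trajectory(spec)$trajectory
  expect_equal(hinge_angle(straj, default_manifest()$hinge), 121.6,
               tolerance = 1e-6)
})

test_that("helix axes follow the endpoint-window convention", {
  # 28-residue ideal helix: the window phases cancel (1800 degrees of twist
  # between window centers) so the endpoint axis is exactly the helix axis
  h <- ideal_helix(28)
  df <- do.call(rbind, lapply(1:28, function(i) {
    ca_residue("A", "A", i, h[i, 1], h[i, 2], h[i, 3])
  }))
  traj <- topo_trajectory(make_topology(df))
  ax <- helix_axis(traj, helix_definition("A", 1, 28))
  expect_equal(ax, c(0, 0, 1), tolerance = 1e-6)

  # reversing the residue order negates the axis
  dfr <- df
  dfr$resno <- rev(df$resno)
  axr <- helix_axis(topo_trajectory(make_topology(dfr)),
                    helix_definition("A", 1, 28))
  expect_equal(axr, -ax, tolerance = 1e-6)

  # a 10-residue helix with window 10 clamps with a warning ...
  df10 <- df[1:10, ]
  t10 <- topo_trajectory(make_topology(df10))
  expect_warning(helix_axis(t10, helix_definition("A", 1, 10)), "clamped")
  # ... and is a degeneracy error when clamping is disabled
  expect_error(
    helix_axis(t10, helix_definition("A", 1, 10, clamp = FALSE)),
    "degenerate")
})

test_that("interhelical angle is the supplement of the raw axis angle", {
  # two straight CA traces with a raw 80-degree crossing
  z <- (0:9) * 1.5
  a2 <- c(sin(80 * pi / 180), 0, cos(80 * pi / 180))
  df <- rbind(
    do.call(rbind, lapply(1:10, function(i) {
      ca_residue("A", "A", i, 0, 0, z[i])
    })),
    do.call(rbind, lapply(1:10, function(i) {
      ca_residue("A", "A", 20 + i, 20 + a2[1] * z[i], 20, a2[3] * z[i])
    }))
  )
  traj <- topo_trajectory(make_topology(df))
  def <- interhelical_definition(helix_definition("A", 1, 10, 9),
                                 helix_definition("A", 21, 30, 9))
  raw <- brute_angle(c(0, 0, 1) + c(1, 1, 1), c(1, 1, 1), a2 + c(1, 1, 1))
  expect_equal(raw, 80, tolerance = 1e-9)
  expect_equal(interhelical_angle(traj, def), 100, tolerance = 1e-6)

  # symmetry in the two helices
  rev_def <- interhelical_definition(helix_definition("A", 21, 30, 9),
                                     helix_definition("A", 1, 10, 9))
  expect_equal(interhelical_angle(traj, rev_def),
               interhelical_angle(traj, def))

  # parallel -> 180, antiparallel -> 0
  dfp <- df
  dfp[11:20, c("x", "y", "z")] <- cbind(20, 20, z)
  tp <- topo_trajectory(make_topology(dfp))
  expect_equal(interhelical_angle(tp, def), 180, tolerance = 1e-9)
  dfa <- df
  dfa[11:20, c("x", "y", "z")] <- cbind(20, 20, rev(z))
  ta <- topo_trajectory(make_topology(dfa))
  expect_equal(interhelical_angle(ta, def), 0, tolerance = 1e-9)
})

test_that("pair distances match planted geometry", {
  df <- rbind(ca_residue("A", "A", 1, 0, 0, 0),
              ca_residue("A", "A", 2, 3, 4, 0))
  traj <- topo_trajectory(make_topology(df))
  expect_equal(pair_distance(traj, distance_definition("A:1:CA", "A:2:CA")), 5)
  expect_equal(pair_distance(traj, distance_definition("A:1:CA", "A:1:CA")), 0)

  spec <- synthetic_spec(n_runs = 1, frames_per_run = 3, seed = 3,
                         domain_separation = 30)
  straj <- generate_trajectory(spec)$trajectory
  for (f in 1:3) {
    expect_equal(
      pair_distance(straj, default_manifest()$ntc_ctc_distance, frame = f),
      30, tolerance = 1e-6)
  }
})

test_that("metric series preserve frame order and recover planted angles", {
  spec <- synthetic_spec(n_runs = 2, frames_per_run = 50, seed = 5)
  out <- generate_trajectory(spec)
  s <- metric_series(out$trajectory, default_manifest()$hinge)
  expect_equal(nrow(s), 100L)
  expect_equal(s$value, out$ground_truth$hinge_angles, tolerance = 1e-6)
  expect_equal(attr(s, "n_failed"), 0L)
  expect_equal(s$run_id, out$trajectory$run_id)

  # static trajectory -> identical values
  one <- generate_trajectory(synthetic_spec(n_runs = 1, frames_per_run = 1,
                                            seed = 5))$trajectory
  static <- as_trajectory(one$topology,
                          matrix(rep(one$xyz[1, ], 5), nrow = 5, byrow = TRUE))
  sv <- metric_series(static, default_manifest()$hinge)$value
  expect_equal(sv, rep(sv[1], 5))
})

test_that("internal metrics are invariant under global rigid-body motion", {
  spec <- synthetic_spec(n_runs = 1, frames_per_run = 20, seed = 9)
  traj <- generate_trajectory(spec)$trajectory
  set.seed(123)
  R <- random_rotation()
  moved <- rigid_transform_trajectory(traj, R, c(12.3, -45.6, 7.8))
  man <- default_manifest()
  for (m in list(man$hinge, man$ntc_ctc_distance)) {
    expect_equal(metric_series(moved, m)$value,
                 metric_series(traj, m)$value, tolerance = 1e-9)
  }
  suppressWarnings({
    expect_equal(metric_series(moved, man$ab_angle)$value,
                 metric_series(traj, man$ab_angle)$value, tolerance = 1e-9)
  })
})

test_that("planted Gaussian hinge distributions are recovered statistically", {
  mu <- 121.6
  sigma <- 7.2
  n <- 1500
  spec <- synthetic_spec(n_runs = 1, frames_per_run = n, seed = 17,
                         hinge = hinge_gaussian(mu, sigma))
  s <- metric_series(generate_trajectory(spec)$trajectory,
                     default_manifest()$hinge)
  expect_lt(abs(mean(s$value) - mu), 3 * sigma / sqrt(n))
  expect_lt(abs(sd(s$value) - sigma) / sigma, 0.10)
})
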