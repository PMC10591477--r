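test_that("superposition matches the quaternion-method oracle", {
  set.seed(21)
  P <- matrix(rnorm(150, sd = 8), ncol = 3)

  # identity and pure translation are exact
  self <- superpose(P, P)
  expect_equal(attr(self, "rmsd"), 0, tolerance = 1e-9)
  shifted <- sweep(P, 2, c(5, -3, 2), `+`)
  back <- superpose(shifted, P)
  expect_equal(attr(back, "rmsd"), 0, tolerance = 1e-9)
  expect_equal(unclass(back), P, tolerance = 1e-9, ignore_attr = TRUE)

  # rotated + jittered copy: post-RMSD equals the independent quaternion
  # solution, and is bounded by the jitter magnitude
  R <- random_rotation()
  Q <- sweep(P %*% t(R), 2, c(1, 2, 3), `+`) + matrix(rnorm(150, sd = 0.1), ncol = 3)
  fitted <- superpose(Q, P)
  expect_equal(attr(fitted, "rmsd"), quaternion_rmsd(Q, P), tolerance = 1e-6)
  expect_lt(attr(fitted, "rmsd"), attr(fitted, "rmsd_before") + 1e-12)

  # cross-check against the reference implementation in bio3d (which
  # reports at 3 decimals)
  b3d <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  expect_lt(abs(attr(fitted, "rmsd") - b3d), 6e-4)

  expect_error(superpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("RMSF is zero for static trajectories and sqrt(3)*sigma for jitter", {
  spec0 <- synthetic_spec(n_runs = 1, frames_per_run = 1, seed = 2)
  base <- generate_trajectory(spec0)$trajectory
  static <- as_trajectory(base$topology,
                          matrix(rep(base$xyz[1, ], 4), nrow = 4, byrow = TRUE))
  prof <- rmsf(static)
  expect_true(all(prof$rmsf < 1e-9))
  expect_error(rmsf(as_trajectory(base$topology, base$xyz[1, , drop = FALSE])),
               "at least 2")

  # frozen hinge + tail jitter: flexible tail converges to sigma * sqrt(3)
  sigma <- 0.5
  spec <- synthetic_spec(n_runs = 1, frames_per_run = 800, seed = 23,
                         hinge = hinge_gaussian(121.6, 0), jitter_sd = sigma)
  traj <- generate_trajectory(spec)$trajectory
  prof <- rmsf(traj)
  flex <- prof$subunit == "TnI" & prof$resno <= 33
  expect_lt(max(abs(prof$rmsf[flex] - sigma * sqrt(3))) / (sigma * sqrt(3)),
            0.05)
  expect_true(all(prof$rmsf[!flex] < 0.05))

  # doubling the jitter doubles the RMSF
  spec2 <- synthetic_spec(n_runs = 1, frames_per_run = 800, seed = 23,
                          hinge = hinge_gaussian(121.6, 0), jitter_sd = 2 * sigma)
  prof2 <- rmsf(generate_trajectory(spec2)$trajectory)
  ratio <- mean(prof2$rmsf[flex]) / mean(prof$rmsf[flex])
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("pairwise RMSD matrices match a per-pair oracle and are symmetric", {
  spec <- synthetic_spec(n_runs = 2, frames_per_run = 5, seed = 31)
  traj <- generate_trajectory(spec)$trajectory
  m <- pairwise_rmsd(traj)
  expect_equal(dim(m), c(10L, 10L))
  expect_true(all(diag(m) == 0))
  expect_lt(max(abs(m - t(m))), 1e-9)

  # independent quaternion oracle, elementwise
  hv <- resolve_selection(traj$topology,
                          as.list(sprintf("%s:%d-%d:heavy",
                                          traj$topology$subunit_ranges$subunit,
                                          traj$topology$subunit_ranges$first,
                                          traj$topology$subunit_ranges$last)))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      o <- quaternion_rmsd(frame_coords(traj, i)[hv, ],
                           frame_coords(traj, j)[hv, ])
      expect_lt(abs(m[i, j] - o), 1e-6)
    }
  }

  # identical frames give an all-zero matrix
  dup <- as_trajectory(traj$topology,
                       matrix(rep(traj$xyz[1, ], 2), nrow = 2, byrow = TRUE))
  expect_equal(unclass(pairwise_rmsd(dup)), matrix(0, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-9)

  # invariance under a global rigid-body transform of every frame
  set.seed(33)
  moved <- rigid_transform_trajectory(traj, random_rotation(), c(3, 14, -9))
  expect_equal(unclass(pairwise_rmsd(moved)), unclass(m),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("memory guard refuses huge strided matrices", {
  spec <- synthetic_spec(n_runs = 1, frames_per_run = 3, seed = 1)
  traj <- generate_trajectory(spec)$trajectory
  expect_error(pairwise_rmsd(traj, stride = 1, max_frames = 3,
                             override = FALSE),
               NA)  # 3 frames is fine
  # the guard path itself (simulated via a tiny threshold is not possible;
  # assert the error message formatting through direct striding maths)
  expect_error(pairwise_rmsd(traj, stride = 0.0001), "20,000")
})

test_that("representative structure is the brute-force medoid with stable ties", {
  # two identical frames plus one distant frame -> first of the pair
  spec <- synthetic_spec(n_runs = 1, frames_per_run = 2, seed = 41,
                         hinge = hinge_gaussian(121.6, 12), jitter_sd = 0)
  traj <- generate_trajectory(spec)$trajectory
  xyz3 <- rbind(traj$xyz[1, ], traj$xyz[1, ], traj$xyz[2, ])
  t3 <- as_trajectory(traj$topology, xyz3)
  r <- representative_structure(pairwise_rmsd(t3))
  expect_equal(r$frame, 1L)

  # all identical -> run 1, frame 1 by tie-break
  tid <- as_trajectory(traj$topology,
                       matrix(rep(traj$xyz[1, ], 4), nrow = 4, byrow = TRUE),
                       run_id = c(1, 1, 2, 2))
  rid <- representative_structure(pairwise_rmsd(tid))
  expect_equal(rid$run_id, 1L)
  expect_equal(rid$frame_index, 1L)

  # 50-frame cloud with a planted medoid: duplicating one conformation
  # k > n/2 times forces it to be the medoid
  spec50 <- synthetic_spec(n_runs = 1, frames_per_run = 24, seed = 43,
                           hinge = hinge_gaussian(121.6, 7.2))
  t50 <- generate_trajectory(spec50)$trajectory
  planted <- t50$xyz[7, ]
  xyz <- rbind(t50$xyz, matrix(rep(planted, 26), nrow = 26, byrow = TRUE))
  tm <- as_trajectory(t50$topology, xyz)
  mat <- pairwise_rmsd(tm)
  rep50 <- representative_structure(mat)
  # brute-force row-sum scan oracle (to float tolerance: the 27 copies of
  # the planted conformation tie)
  rs <- rowSums(mat)
  expect_lt(rs[rep50$row] - min(rs), 1e-9)
  # the planted conformation, first occurrence (frame 7) by tie-break
  expect_equal(rep50$frame, 7L)

  # permutation equivariance
  perm <- sample(nrow(xyz))
  tperm <- as_trajectory(tm$topology, xyz[perm, , drop = FALSE])
  rp <- representative_structure(pairwise_rmsd(tperm))
  expect_equal(tperm$xyz[rp$frame, ], planted)
})
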