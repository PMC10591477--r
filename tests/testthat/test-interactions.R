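arg_glu_topology <- function(sep_dist) {
  # minimal Arg/Glu pair: side-chain tips placed sep_dist apart
  df <- rbind(
    data.frame(subunit = "TnC", chain = "A", resno = 10, resid = "ARG",
               elety = c("CA", "NE", "NH1", "NH2"), element = c("C", "N", "N", "N"),
               x = c(-8, -2, 0, -2), y = c(0, 1.2, 0, -1.2), z = 0),
    data.frame(subunit = "TnC", chain = "A", resno = 50, resid = "GLU",
               elety = c("CA", "OE1", "OE2"), element = c("C", "O", "O"),
               x = c(8 + sep_dist, sep_dist, sep_dist + 1.0),
               y = c(0, 0, 1.1), z = 0)
  )
  make_topology(df)
}

ring_coords_fixture <- function() {
  ring <- function(resno, cx) {
    th <- (0:5) * pi / 3
    data.frame(subunit = "TnC", chain = "A", resno = resno, resid = "PHE",
               elety = c("CA", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
               element = "C",
               x = c(cx - 4, rep(cx, 6)),
               y = c(0, 1.39 * cos(th)), z = c(0, 1.39 * sin(th)))
  }
  make_topology(rbind(ring(5, 0), ring(40, 4.0)))
}

test_that("atom typing follows the residue rule tables", {
  top <- arg_glu_topology(3.0)
  ty <- assign_atom_types(top)
  arg <- top$atoms$resid == "ARG" & top$atoms$elety != "CA"
  expect_true(all(ty$donor[arg]))
  expect_true(all(ty$charge[arg] == 1L))
  expect_length(unique(ty$charge_group[arg]), 1L)
  glu <- top$atoms$elety %in% c("OE1", "OE2")
  expect_true(all(ty$acceptor[glu]))
  expect_true(all(ty$charge[glu] == -1L))

  # SEP: phosphate oxygens form one anionic group of acceptors
  sep <- read_topology(write_sep_pdb(tempfile(fileext = ".pdb")))
  tys <- assign_atom_types(sep)
  po <- sep$atoms$elety %in% c("O1P", "O2P", "O3P")
  expect_true(all(tys$acceptor[po]))
  expect_true(all(tys$charge[po] == -1L))
  expect_length(unique(tys$charge_group[po]), 1L)

  # Phe: 6-membered ring on CG..CZ
  ring <- ring_coords_fixture()
  tyr <- assign_atom_types(ring)
  on_ring <- ring$atoms$elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  expect_true(all(!is.na(tyr$ring_id[on_ring])))
  expect_length(unique(tyr$ring_id[ring$atoms$resno == 5 & on_ring]), 1L)

  # unknown residues degrade to van-der-Waals-only with a warning
  odd <- make_topology(ca_residue("X", "X", 1, 0, 0, 0, resid = "LIG"))
  expect_warning(tyo <- assign_atom_types(odd), "unknown residue")
  expect_false(any(tyo$donor))
  expect_equal(tyo$vdw_radius, 1.70)
})

test_that("interaction detection honours the distance criteria", {
  cut <- interaction_cutoffs()

  close <- arg_glu_topology(3.8)
  ty <- assign_atom_types(close)
  ev <- detect_interactions(frame_coords(topo_trajectory(close), 1), ty, cut)
  expect_true("ionic" %in% ev$type)

  # at 3.0 A the pair is both ionic and hydrogen-bonded (NH1 donor, OE1
  # acceptor; no explicit H so the distance criterion applies alone)
  very_close <- arg_glu_topology(3.0)
  ev2 <- detect_interactions(frame_coords(topo_trajectory(very_close), 1),
                             assign_atom_types(very_close), cut)
  expect_setequal(intersect(ev2$type, c("ionic", "hbond")),
                  c("ionic", "hbond"))

  # beyond every cutoff: nothing
  far <- arg_glu_topology(6.5)
  ev3 <- detect_interactions(frame_coords(topo_trajectory(far), 1),
                             assign_atom_types(far), cut)
  expect_equal(nrow(ev3[ev3$type != "vdw", ]), 0L)

  # stacked ideal rings at 4.0 A centroid distance -> aromatic
  rings <- ring_coords_fixture()
  coords <- frame_coords(topo_trajectory(rings), 1)
  # brute-force centroid check of the fixture itself
  c1 <- brute_centroid(coords, 2:7)
  c2 <- brute_centroid(coords, 9:14)
  expect_equal(sqrt(sum((c1 - c2)^2)), 4.0, tolerance = 1e-9)
  eva <- detect_interactions(coords, assign_atom_types(rings), cut)
  expect_true("aromatic" %in% eva$type)

  # determinism: identical frame -> identical event set
  expect_identical(eva,
                   detect_interactions(coords, assign_atom_types(rings), cut))
})

test_that("loosening a cutoff never removes events", {
  spec <- synthetic_spec(n_runs = 1, frames_per_run = 1, seed = 3)
  traj <- generate_trajectory(spec)$trajectory
  ty <- assign_atom_types(traj$topology)
  coords <- frame_coords(traj, 1)
  tight <- detect_interactions(coords, ty, interaction_cutoffs())
  loose <- detect_interactions(coords, ty,
                               interaction_cutoffs(hbond = 4.5, ionic = 5.5,
                                                   aromatic = 6.5))
  key <- function(e) paste(e$sub_a, e$res_a, e$sub_b, e$res_b, e$type)
  expect_true(all(key(tight[tight$type != "vdw", ]) %in% key(loose)))
})

test_that("aggregation produces exact counts, percentages and symmetry", {
  ev <- data.frame(frame = c(1, 1, 2, 3),
                   sub_a = "TnC", res_a = c(10L, 10L, 10L, 12L),
                   sub_b = "TnI", res_b = c(5L, 7L, 5L, 9L),
                   type = c("ionic", "hbond", "ionic", "vdw"))
  ft <- aggregate_interactions(ev, n_frames = 4)
  expect_equal(interaction_percent(ft, "TnC:10", "TnI:5", "ionic"), 50)
  expect_equal(interaction_percent(ft, "TnI:5", "TnC:10", "ionic"), 50)
  expect_equal(interaction_percent(ft, "TnC:10", "TnI:7", "hbond"), 25)
  expect_equal(interaction_percent(ft, "TnC:99", "TnI:5", "ionic"), 0)
  expect_equal(sum(ft$count), 4L)

  # a pair present in 30,000 of 37,500 frames is an 80% interaction
  ev80 <- data.frame(frame = seq_len(30000), sub_a = "TnC", res_a = 83L,
                     sub_b = "TnC", res_b = 159L, type = "ionic")
  expect_equal(
    interaction_percent(aggregate_interactions(ev80, 37500),
                        "TnC:83", "TnC:159", "ionic"), 80)

  # no events -> empty table with all-zero lookups
  empty <- aggregate_interactions(ev[0, ], n_frames = 10)
  expect_equal(nrow(empty), 0L)
  expect_equal(interaction_percent(empty, "TnC:1", "TnC:2", "vdw"), 0)

  # out-of-range frames are rejected
  expect_error(aggregate_interactions(ev, n_frames = 2), "1..n_frames")
})

test_that("planted contact occupancies are recovered within binomial bounds", {
  n <- 600
  spec <- synthetic_spec(n_runs = 1, frames_per_run = n, seed = 51)
  out <- generate_trajectory(spec)
  ft <- profile_interactions(out$trajectory)
  gt <- out$ground_truth
  for (k in seq_len(nrow(gt$contacts))) {
    got <- interaction_percent(ft, gt$contacts$res_a[k], gt$contacts$res_b[k],
                               gt$contacts$type[k])
    # exact agreement with the realized Bernoulli draws ...
    expect_equal(got, 100 * gt$contacts$f_realized[k], tolerance = 1e-9)
    # ... and within the exact binomial 99% interval of the nominal f
    f <- gt$contacts$occupancy[k]
    lo <- 100 * qbinom(0.005, n, f) / n
    hi <- 100 * qbinom(0.995, n, f) / n
    expect_gte(got, lo)
    expect_lte(got, hi)
  }
})

test_that("state comparison reports percentage-point deltas with absent pairs as zero", {
  ta <- aggregate_interactions(
    data.frame(frame = 1:80, sub_a = "TnC", res_a = 1L, sub_b = "TnI",
               res_b = 2L, type = "ionic"), 100)
  tb <- aggregate_interactions(
    data.frame(frame = 1:80, sub_a = "TnC", res_a = 1L, sub_b = "TnI",
               res_b = 2L, type = "ionic"), 100)
  d0 <- compare_states(ta, tb)
  expect_equal(d0$delta, 0)

  # 0% -> 80% is +80 points
  dup <- compare_states(aggregate_interactions(
    data.frame(frame = integer(0), sub_a = character(0), res_a = integer(0),
               sub_b = character(0), res_b = integer(0), type = character(0)),
    100), tb)
  expect_equal(dup$delta, 80)
  expect_equal(dup$percent_a, 0)

  # planted occupancies 0.6 vs 0.3 -> about -30 points
  set.seed(61)
  n <- 800
  mk <- function(f) aggregate_interactions(
    data.frame(frame = which(runif(n) < f), sub_a = "TnC", res_a = 1L,
               sub_b = "TnI", res_b = 2L, type = "hbond"), n)
  dd <- compare_states(mk(0.6), mk(0.3))
  ci <- 3 * 100 * sqrt(0.6 * 0.4 / n + 0.3 * 0.7 / n)
  expect_lt(abs(dd$delta - (-30)), ci)
})

test_that("heat-map matrices are shaped by residue ranges", {
  empty <- aggregate_interactions(
    data.frame(frame = integer(0), sub_a = character(0), res_a = integer(0),
               sub_b = character(0), res_b = integer(0), type = character(0)),
    10)
  m0 <- heatmap_matrix(empty, "TnI:1-34", "TnC:1-84", "ionic")
  expect_equal(dim(m0), c(34L, 84L))
  expect_true(all(m0 == 0))

  ev <- data.frame(frame = c(1, 1, 2), sub_a = "TnC",
                   res_a = c(15L, 25L, 15L), sub_b = "TnI",
                   res_b = c(9L, 12L, 9L), type = "ionic")
  ft <- aggregate_interactions(ev, 4)
  m <- heatmap_matrix(ft, "TnI:1-34", "TnC:1-84", "ionic")
  expect_equal(sum(m != 0), 2L)
  expect_equal(m["TnI_9", "TnC_15"], 50)
  expect_equal(m["TnI_12", "TnC_25"], 25)
  expect_error(heatmap_matrix(ft, "TnI:1-34", "TnC:1-84", "nope"),
               NA)  # unknown type just yields zeros
})
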