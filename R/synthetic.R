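# Synthetic two-domain trajectories with planted ground truth.
#
# The generator emulates the statistical structure of troponin MD output:
# a mobile regulatory head ("NcTnC", carrying two ideal alpha-helices)
# hinging against a static arm assembly ("CTnC" + TnI + TnT), per-frame
# hinge angles drawn from a planted distribution and realized exactly by
# rigid rotation, Gaussian positional jitter on a flexible tail, and
# residue-pair contacts present in a Bernoulli fraction of frames.

#' Gaussian hinge-angle distribution
#' @param mean,sd Mean and standard deviation in degrees.
#' @return Distribution spec for [synthetic_spec()].
#' @export
hinge_gaussian <- function(mean, sd) {
  list(type = "gaussian", mean = mean, sd = sd)
}

#' Bimodal (two-component Gaussian mixture) hinge-angle distribution
#' @param means,sds Length-2 component means and standard deviations,
#'   degrees.
#' @param weights Length-2 mixture weights summing to 1.
#' @return Distribution spec for [synthetic_spec()].
#' @export
hinge_bimodal <- function(means, sds, weights = c(0.5, 0.5)) {
  stopifnot(length(means) == 2L, length(sds) == 2L, length(weights) == 2L)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  list(type = "bimodal", mean = means, sd = sds, weight = weights)
}

#' Default planted contacts
#'
#' One contact per interaction class, with occupancies spanning the range
#' seen in interaction heat maps of real trajectories: a strong ionic pair
#' (80%), a medium hydrogen bond (25%) and a rare aromatic stacking (5%).
#'
#' @return Data.frame with `res_a`, `res_b`, `type`, `occupancy`.
#' @export
default_planted_contacts <- function() {
  data.frame(
    res_a = c("TnC:100", "TnC:102", "TnC:104"),
    res_b = c("TnC:140", "TnC:142", "TnC:144"),
    type = c("ionic", "hbond", "aromatic"),
    occupancy = c(0.80, 0.25, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic trajectory
#'
#' Defaults mirror the study conditions of long-timescale troponin MD:
#' five independent runs, a Gaussian hinge-angle distribution with mean
#' 121.6 and standard deviation 7.2 degrees, an A/B interhelical angle of
#' 101.8 degrees, a 30 Angstrom head-to-hinge (NTnC-CTnC) separation, and
#' contact occupancies spanning weak to strong. Frames per run (1000) and
#' the 0.5 Angstrom tail jitter are desk-scale choices documented in the
#' methods vignette.
#'
#' @param n_runs Independent runs.
#' @param frames_per_run Frames per run.
#' @param seed Integer seed of the single PRNG stream.
#' @param hinge Hinge-angle distribution ([hinge_gaussian()] or
#'   [hinge_bimodal()]).
#' @param helix_angle Planted A/B interhelical angle, degrees (endpoint-axis
#'   convention).
#' @param jitter_sd Per-coordinate Gaussian jitter applied to the flexible
#'   tail atoms, Angstrom.
#' @param contacts Planted-contact table (see
#'   [default_planted_contacts()]); may have zero rows.
#' @param domain_separation Head-centroid to hinge-centroid distance,
#'   Angstrom.
#' @param arm_length Hinge-centroid to arm-end-centroid distance, Angstrom.
#' @return A `tn_synth_spec`.
#' @export
synthetic_spec <- function(n_runs = 5L, frames_per_run = 1000L, seed = 1L,
                           hinge = hinge_gaussian(121.6, 7.2),
                           helix_angle = 101.8, jitter_sd = 0.5,
                           contacts = default_planted_contacts(),
                           domain_separation = 30, arm_length = 35) {
  stopifnot(n_runs >= 1L, frames_per_run >= 1L, jitter_sd >= 0,
            domain_separation > 0, arm_length > 0,
            helix_angle > 0, helix_angle < 180)
  if (nrow(contacts) > 0) {
    stopifnot(all(contacts$occupancy >= 0 & contacts$occupancy <= 1),
              all(contacts$type %in% c("ionic", "hbond", "aromatic")))
  }
  structure(list(n_runs = as.integer(n_runs),
                 frames_per_run = as.integer(frames_per_run),
                 seed = as.integer(seed), hinge = hinge,
                 helix_angle = helix_angle, jitter_sd = jitter_sd,
                 contacts = contacts,
                 domain_separation = domain_separation,
                 arm_length = arm_length),
            class = "tn_synth_spec")
}

#' Ideal alpha-helix alpha-carbon coordinates
#'
#' Canonical alpha-helix geometry: 1.5 Angstrom rise and 100 degrees of
#' twist per residue on a 2.3 Angstrom radius, axis along +z.
#'
#' @param n Number of residues.
#' @param radius,rise,twist Helix parameters (Angstrom, Angstrom/residue,
#'   degrees/residue).
#' @return n x 3 coordinate matrix.
#' @export
ideal_helix <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  i <- seq_len(n) - 1L
  th <- i * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

# unit vector from the centroid of the first w points to the centroid of
# the last w points (the endpoint-window axis convention)
endpoint_axis <- function(pts, w) {
  n <- nrow(pts)
  w <- min(w, n - 1L)
  v <- colMeans(pts[seq.int(n - w + 1L, n), , drop = FALSE]) -
    colMeans(pts[seq_len(w), , drop = FALSE])
  v / sqrt(sum(v^2))
}

# proper rotation mapping unit vector a onto unit vector b
rotation_from_to <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# rotate points (n x 3) about an axis through `center` by `deg` degrees
rotate_about <- function(pts, center, axis, deg) {
  th <- deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}

# deterministic block of n points on a centered 3D grid
grid_block <- function(n, center, spacing = 4.5, nx = 5L, ny = 5L) {
  nz <- ceiling(n / (nx * ny))
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  g <- as.matrix(g[seq_len(n), ]) * spacing
  sweep(g, 2, colMeans(g)) + matrix(center, n, 3, byrow = TRUE)
}

.contact_atoms <- list(
  ionic    = list(res_a = list(resid = "ARG", atoms = "NH1", elem = "N"),
                  res_b = list(resid = "GLU", atoms = "OE1", elem = "O"),
                  cutoff = 4.0, on_frac = 0.95),
  hbond    = list(res_a = list(resid = "SER", atoms = "OG", elem = "O"),
                  res_b = list(resid = "ASN", atoms = "OD1", elem = "O"),
                  cutoff = 3.5, on_frac = 0.857),
  aromatic = list(res_a = list(resid = "PHE",
                               atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                               elem = "C"),
                  res_b = list(resid = "PHE",
                               atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                               elem = "C"),
                  cutoff = 5.0, on_frac = 0.80)
)

# hexagonal ring (radius 1.39 A) in the y-z plane centered at `center`
ring_coords <- function(center) {
  th <- (0:5) * pi / 3
  cbind(rep(center[1], 6), center[2] + 1.39 * cos(th),
        center[3] + 1.39 * sin(th))
}

# Full deterministic construction: topology + base coordinates + the
# bookkeeping needed to animate it. Internal.
build_toy <- function(spec) {
  res_list <- list()
  add_res <- function(subunit, chain, resno, resid, atoms, elem, coords) {
    res_list[[length(res_list) + 1L]] <<- list(
      subunit = subunit, chain = chain, resno = resno, resid = resid,
      atoms = atoms, elem = elem, coords = coords)
  }

  # parse planted contacts and allocate their zone slots
  contacts <- spec$contacts
  contact_info <- list()
  special <- list()  # "sub:resno" -> list(resid, atoms, elem, coords)
  if (nrow(contacts) > 0) {
    for (k in seq_len(nrow(contacts))) {
      type <- contacts$type[k]
      proto <- .contact_atoms[[type]]
      anchor <- c(14 * (k - 1), -40, 0)
      on_d <- proto$on_frac * proto$cutoff
      off_d <- 1.6 * proto$cutoff
      if (type == "aromatic") {
        ca_coords <- ring_coords(anchor)
        cb_base <- ring_coords(anchor + c(off_d, 0, 0))
      } else {
        ca_coords <- matrix(anchor, 1, 3)
        cb_base <- matrix(anchor + c(off_d, 0, 0), 1, 3)
      }
      special[[contacts$res_a[k]]] <- c(proto$res_a, list(coords = ca_coords))
      special[[contacts$res_b[k]]] <- c(proto$res_b, list(coords = cb_base))
      contact_info[[k]] <- list(res_a = contacts$res_a[k],
                                res_b = contacts$res_b[k], type = type,
                                occupancy = contacts$occupancy[k],
                                anchor = anchor, on_d = on_d, off_d = off_d,
                                dir = c(1, 0, 0))
    }
  }

  add_plain <- function(subunit, chain, resno, coord) {
    key <- sprintf("%s:%d", subunit, resno)
    sp <- special[[key]]
    if (is.null(sp)) {
      add_res(subunit, chain, resno, "ALA", "CA", "C", matrix(coord, 1, 3))
    } else {
      add_res(subunit, chain, resno, sp$resid,
              c("CA", sp$atoms), c("C", rep(sp$elem, length(sp$atoms))),
              rbind(coord, sp$coords))
    }
  }

  # --- head domain (TnC 1-85), built locally then placed -----------------
  gamma <- 180 - spec$helix_angle  # raw angle between N->C axes
  hxA <- ideal_helix(12)           # residues 14-25
  hxB <- ideal_helix(10)           # residues 38-47
  RA <- rotation_from_to(endpoint_axis(hxA, 10L), c(0, 0, 1))
  dB <- c(sin(gamma * pi / 180), 0, cos(gamma * pi / 180))
  RB <- rotation_from_to(endpoint_axis(hxB, 10L), dB)
  hxA <- sweep(sweep(hxA, 2, colMeans(hxA)) %*% t(RA), 2, c(-3, 0, 0), `+`)
  hxB <- sweep(sweep(hxB, 2, colMeans(hxB)) %*% t(RB), 2, c(6, 8, 0), `+`)
  head_other <- grid_block(63, c(0, 0, -14), nx = 5L, ny = 5L)
  head_local <- matrix(NA_real_, 85, 3)  # row r = residue r
  head_local[14:25, ] <- hxA
  head_local[38:47, ] <- hxB
  head_local[c(1:13, 26:37, 48:85), ] <- head_other

  # --- static assembly ---------------------------------------------------
  ctc <- grid_block(76, c(0, 0, 0), nx = 5L, ny = 5L)           # TnC 86-161
  arm <- grid_block(19, c(spec$arm_length, 0, 0), nx = 3L, ny = 3L)
  tnt_bulk <- grid_block(41, c(12, -18, 0), nx = 7L, ny = 7L)   # TnT 200-240
  tnt_tail <- grid_block(9, c(spec$arm_length + 8, -8, 0), nx = 3L, ny = 3L)
  tni_mid <- grid_block(35, c(12, 18, 0), nx = 5L, ny = 5L)     # TnI 34-68
  tni_flex <- grid_block(33, c(14, 40, 0), nx = 4L, ny = 3L)    # TnI 1-33
  tni_ct <- grid_block(4, c(spec$arm_length, 10, 0), nx = 2L, ny = 2L) # 77-80

  # hinge centroid and arm direction from the constructed static part
  hinge_rows <- 94:157 - 85           # rows of ctc (residues 86-161)
  H <- colMeans(ctc[hinge_rows, , drop = FALSE])
  arm_c <- colMeans(arm)
  u2 <- arm_c - H
  u2 <- u2 / sqrt(sum(u2^2))
  e <- if (abs(u2[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  n_axis <- c(u2[2] * e[3] - u2[3] * e[2], u2[3] * e[1] - u2[1] * e[3],
              u2[1] * e[2] - u2[2] * e[1])
  n_axis <- n_axis / sqrt(sum(n_axis^2))
  m_hat <- c(n_axis[2] * u2[3] - n_axis[3] * u2[2],
             n_axis[3] * u2[1] - n_axis[1] * u2[3],
             n_axis[1] * u2[2] - n_axis[2] * u2[1])

  theta0 <- if (spec$hinge$type == "gaussian") spec$hinge$mean else
    sum(spec$hinge$weight * spec$hinge$mean)
  target <- H + spec$domain_separation *
    (cos(theta0 * pi / 180) * u2 + sin(theta0 * pi / 180) * m_hat)
  c_head <- colMeans(head_local[3:85, , drop = FALSE])
  head_local <- sweep(head_local, 2, target - c_head, `+`)

  # --- assemble atom table (chain order A, B, C) -------------------------
  for (r in 1:85) add_plain("TnC", "A", r, head_local[r, ])
  for (r in 86:161) add_plain("TnC", "A", r, ctc[r - 85, ])
  for (r in 1:33) add_plain("TnI", "B", r, tni_flex[r, ])
  for (r in 34:68) add_plain("TnI", "B", r, tni_mid[r - 33, ])
  for (r in 69:76) add_plain("TnI", "B", r, arm[11 + (r - 68), ])
  for (r in 77:80) add_plain("TnI", "B", r, tni_ct[r - 76, ])
  for (r in 200:240) add_plain("TnT", "C", r, tnt_bulk[r - 199, ])
  for (r in 241:251) add_plain("TnT", "C", r, arm[r - 240, ])
  for (r in 252:260) add_plain("TnT", "C", r, tnt_tail[r - 251, ])

  nat <- sum(vapply(res_list, function(r) length(r$atoms), integer(1)))
  atoms <- data.frame(
    atom_index = seq_len(nat),
    eleno = seq_len(nat),
    elety = unlist(lapply(res_list, `[[`, "atoms")),
    element = unlist(lapply(res_list, `[[`, "elem")),
    resid = rep(vapply(res_list, `[[`, "", "resid"),
                vapply(res_list, function(r) length(r$atoms), integer(1))),
    chain = rep(vapply(res_list, `[[`, "", "chain"),
                vapply(res_list, function(r) length(r$atoms), integer(1))),
    subunit = rep(vapply(res_list, `[[`, "", "subunit"),
                  vapply(res_list, function(r) length(r$atoms), integer(1))),
    resno = rep(vapply(res_list, function(r) r$resno, integer(1)),
                vapply(res_list, function(r) length(r$atoms), integer(1))),
    stringsAsFactors = FALSE
  )
  base <- do.call(rbind, lapply(res_list, `[[`, "coords"))
  topology <- new_topology(atoms, xyz = as.numeric(t(base)),
                           source = "synthetic")

  # atom bookkeeping for animation
  head_atoms <- which(atoms$subunit == "TnC" & atoms$resno <= 85)
  flexible <- which(atoms$subunit == "TnI" & atoms$resno <= 33)
  for (k in seq_along(contact_info)) {
    ci <- contact_info[[k]]
    pb <- strsplit(ci$res_b, ":", fixed = TRUE)[[1]]
    proto <- .contact_atoms[[ci$type]]
    idx <- which(atoms$subunit == pb[1] & atoms$resno == as.integer(pb[2]) &
                   atoms$elety %in% proto$res_b$atoms)
    contact_info[[k]]$move_idx <- idx
    grp_c <- colMeans(base[idx, , drop = FALSE])
    contact_info[[k]]$move_rel <- sweep(base[idx, , drop = FALSE], 2, grp_c)
  }

  list(topology = topology, base = base, head_atoms = head_atoms,
       flexible = flexible, contact_info = contact_info,
       H = H, n_axis = n_axis, theta0 = theta0)
}

#' Build the toy two-domain topology
#'
#' Deterministic for a fixed spec: repeated calls give identical
#' structures. Residue numbering reuses the canonical troponin anchor
#' ranges (toy TnC 1-161, TnI 1-80, TnT 200-260) so [default_manifest()]
#' runs unmodified on synthetic data.
#'
#' @param spec A `tn_synth_spec`.
#' @return A `tn_topology` whose `xyz` holds the base conformation.
#' @export
build_toy_topology <- function(spec = synthetic_spec()) {
  build_toy(spec)$topology
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Per frame: a hinge angle is drawn from the planted distribution and
#' realized exactly by rigidly rotating the head domain about the axis
#' through the hinge centroid perpendicular to the head and arm vectors;
#' each planted contact is switched on (atoms placed within its cutoff) in
#' an independent Bernoulli(occupancy) subset of frames and parked beyond
#' 1.6x its cutoff otherwise; i.i.d. Gaussian jitter of `jitter_sd` per
#' coordinate is added to the flexible-tail atoms. A single seeded PRNG
#' stream drives every draw and all draws are recorded.
#'
#' @param spec A `tn_synth_spec`.
#' @return List with `trajectory` (a `tn_trajectory`) and `ground_truth`:
#'   `hinge_angles` (per frame, degrees), `component` (mixture component
#'   per frame, Gaussian: all 1), `helix_angle`, `domain_separation`,
#'   `contacts` (with realized occupancy `f_realized`), `presence`
#'   (frames x contacts logical matrix), `jitter_sd`, `flexible_atoms`,
#'   `seed`.
#' @export
generate_trajectory <- function(spec = synthetic_spec()) {
  tt <- build_toy(spec)
  nf <- spec$n_runs * spec$frames_per_run
  nat <- nrow(tt$base)

  set.seed(spec$seed)
  if (spec$hinge$type == "gaussian") {
    component <- rep(1L, nf)
    angles <- stats::rnorm(nf, spec$hinge$mean, spec$hinge$sd)
  } else {
    component <- sample(1:2, nf, replace = TRUE, prob = spec$hinge$weight)
    angles <- stats::rnorm(nf, spec$hinge$mean[component],
                           spec$hinge$sd[component])
  }
  nc <- length(tt$contact_info)
  presence <- matrix(FALSE, nf, nc)
  for (k in seq_len(nc)) {
    presence[, k] <- stats::runif(nf) < tt$contact_info[[k]]$occupancy
  }

  xyz <- matrix(NA_real_, nf, 3L * nat)
  for (f in seq_len(nf)) {
    coords <- tt$base
    delta <- angles[f] - tt$theta0
    if (delta != 0) {
      coords[tt$head_atoms, ] <- rotate_about(
        coords[tt$head_atoms, , drop = FALSE], tt$H, tt$n_axis, delta)
    }
    for (k in seq_len(nc)) {
      ci <- tt$contact_info[[k]]
      d <- if (presence[f, k]) ci$on_d else ci$off_d
      grp_c <- ci$anchor + d * ci$dir
      coords[ci$move_idx, ] <- sweep(ci$move_rel, 2, grp_c, `+`)
    }
    if (spec$jitter_sd > 0 && length(tt$flexible)) {
      coords[tt$flexible, ] <- coords[tt$flexible, ] +
        stats::rnorm(3L * length(tt$flexible), 0, spec$jitter_sd)
    }
    xyz[f, ] <- as.numeric(t(coords))
  }

  contacts <- spec$contacts
  if (nc > 0) contacts$f_realized <- colMeans(presence)
  gt <- list(hinge_angles = angles, component = component,
             helix_angle = spec$helix_angle,
             domain_separation = spec$domain_separation,
             contacts = contacts, presence = presence,
             jitter_sd = spec$jitter_sd, flexible_atoms = tt$flexible,
             seed = spec$seed)
  traj <- as_trajectory(tt$topology, xyz,
                        run_id = rep(seq_len(spec$n_runs),
                                     each = spec$frames_per_run))
  list(trajectory = traj, ground_truth = gt)
}
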