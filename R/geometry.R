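#' Centroid of a selection in one frame
#'
#' Unweighted arithmetic mean of the selected atom coordinates.
#'
#' @param coords N x 3 coordinate matrix (one frame, see [frame_coords()]).
#' @param idx Integer atom indices (from [resolve_selection()]).
#' @return Length-3 numeric vector, Angstrom.
#' @export
centroid <- function(coords, idx) {
  if (length(idx) == 0L) stop("empty selection in centroid()")
  colMeans(coords[idx, , drop = FALSE])
}

# Angle between two vectors in degrees via atan2(|u x v|, u.v): numerically
# stable near 0 and 180 where acos loses precision.
vec_angle <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

#' Define an interdomain hinge angle
#'
#' The hinge angle is measured at the hinge-point centroid between the
#' vector to the head centroid (the regulatory N-lobe of TnC) and the vector
#' to the end of the IT arm. Each of the three anchor points is the centroid
#' of a selection; the arm end may pool residue ranges from several subunits
#' into a single joint centroid.
#'
#' @param head,hinge,arm_end Selection strings (or vectors of them, pooled).
#' @return A `tn_hinge_def`.
#' @seealso [default_manifest()] for the canonical troponin anchors.
#' @export
hinge_definition <- function(head, hinge, arm_end) {
  structure(list(head = head, hinge = hinge, arm_end = arm_end,
                 metric_name = "hinge_angle"),
            class = c("tn_hinge_def", "tn_metric"))
}

#' Define a helix by residue range
#'
#' The helix axis is the vector from the centroid of the first
#' `endpoint_window` alpha carbons to the centroid of the last
#' `endpoint_window` alpha carbons (N-to-C orientation). When the helix has
#' fewer than `endpoint_window + 1` residues the window is clamped to
#' `length - 1` with a warning so the two endpoint centroids remain
#' distinct; with `clamp = FALSE` such a helix is an error instead.
#'
#' @param subunit Subunit label.
#' @param from,to Inclusive residue range (author numbering).
#' @param endpoint_window Number of alpha carbons averaged per end
#'   (default 10).
#' @param clamp Clamp over-long windows rather than erroring (default TRUE).
#' @return A `tn_helix_def`.
#' @export
helix_definition <- function(subunit, from, to, endpoint_window = 10L,
                             clamp = TRUE) {
  stopifnot(from <= to, endpoint_window >= 1L)
  if (to - from + 1L < 4L) stop("helix must span at least 4 residues")
  structure(list(subunit = subunit, from = from, to = to,
                 endpoint_window = as.integer(endpoint_window),
                 clamp = isTRUE(clamp)),
            class = "tn_helix_def")
}

#' Define an interhelical angle metric
#'
#' The interhelical angle is the supplement of the angle between the two
#' helix axes (both N-to-C oriented): antiparallel axes give 0 degrees,
#' parallel axes 180 degrees. For the troponin A/B helix pair, values above
#' 110 degrees label the "open" conformation.
#'
#' @param helix_a,helix_b `tn_helix_def` objects.
#' @param metric_name Label for output series.
#' @return A `tn_interhelical_def`.
#' @export
interhelical_definition <- function(helix_a, helix_b,
                                    metric_name = "interhelical_angle") {
  stopifnot(inherits(helix_a, "tn_helix_def"),
            inherits(helix_b, "tn_helix_def"))
  structure(list(helix_a = helix_a, helix_b = helix_b,
                 metric_name = metric_name),
            class = c("tn_interhelical_def", "tn_metric"))
}

#' Define a centroid-to-centroid distance metric
#'
#' @param sel_a,sel_b Selection strings (or vectors, pooled per side).
#' @param metric_name Label for output series.
#' @return A `tn_distance_def`.
#' @export
distance_definition <- function(sel_a, sel_b, metric_name = "pair_distance") {
  structure(list(sel_a = sel_a, sel_b = sel_b, metric_name = metric_name),
            class = c("tn_distance_def", "tn_metric"))
}

#' Canonical troponin metric manifest
#'
#' The field-standard anchors for the cardiac troponin core, in author
#' numbering: hinge head = TnC 3-85 (CA), hinge point = TnC 94-157 (CA), IT
#' arm end = pooled TnT 241-251 and TnI 69-76 (CA); helix A = TnC 14-25,
#' helix B = TnC 38-47 (endpoint window 10); NTnC/CTnC centers = TnC 3-85
#' and TnC 94-157. Every entry is overridable: the manifest is plain data.
#'
#' @return Named list with `tn_metric` entries `hinge`, `ab_angle`,
#'   `ntc_ctc_distance`, plus the open-state threshold `ab_open_threshold`
#'   (110 degrees).
#' @export
default_manifest <- function() {
  list(
    hinge = hinge_definition(
      head    = "TnC:3-85:CA",
      hinge   = "TnC:94-157:CA",
      arm_end = c("TnT:241-251:CA", "TnI:69-76:CA")
    ),
    ab_angle = interhelical_definition(
      helix_definition("TnC", 14, 25),
      helix_definition("TnC", 38, 47),
      metric_name = "ab_angle"
    ),
    ntc_ctc_distance = distance_definition(
      "TnC:3-85:CA", "TnC:94-157:CA",
      metric_name = "ntc_ctc_distance"
    ),
    ab_open_threshold = 110
  )
}

resolve_hinge <- function(topology, def) {
  list(head    = resolve_selection(topology, as.list(def$head)),
       hinge   = resolve_selection(topology, as.list(def$hinge)),
       arm_end = resolve_selection(topology, as.list(def$arm_end)))
}

hinge_angle_resolved <- function(coords, res) {
  h  <- centroid(coords, res$hinge)
  v1 <- centroid(coords, res$head) - h
  v2 <- centroid(coords, res$arm_end) - h
  if (sum(v1^2) == 0 || sum(v2^2) == 0) {
    stop("coincident centroids: hinge angle undefined")
  }
  vec_angle(v1, v2)
}

#' Interdomain hinge angle of one frame
#'
#' Angle at the hinge centroid between the hinge-to-head and
#' hinge-to-arm-end vectors, in degrees within [0, 180].
#'
#' @param trajectory A `tn_trajectory` (or `coords` given directly).
#' @param def A `tn_hinge_def`.
#' @param frame Pooled frame number.
#' @return Angle in degrees.
#' @export
hinge_angle <- function(trajectory, def, frame = 1L) {
  res <- resolve_hinge(trajectory$topology, def)
  hinge_angle_resolved(frame_coords(trajectory, frame), res)
}

# Returns the CA indices of the two endpoint windows, honouring the clamp
# rule. CA atoms ordered by residue number.
resolve_helix <- function(topology, def) {
  at <- topology$atoms
  keep <- at$subunit == def$subunit & at$elety == "CA" &
    at$resno >= def$from & at$resno <= def$to
  idx <- at$atom_index[keep][order(at$resno[keep])]
  len <- length(idx)
  if (len < 4L) {
    stop(sprintf("helix %s:%d-%d resolves to %d CA atoms (need >= 4)",
                 def$subunit, def$from, def$to, len))
  }
  w <- def$endpoint_window
  if (w > len - 1L) {
    if (!def$clamp) {
      stop(sprintf(
        "endpoint window %d covers the whole %d-residue helix: degenerate axis",
        w, len))
    }
    warning(sprintf(
      "endpoint window %d clamped to %d for %d-residue helix %s:%d-%d",
      w, len - 1L, len, def$subunit, def$from, def$to), call. = FALSE)
    w <- len - 1L
  }
  list(n_window = idx[seq_len(w)], c_window = idx[seq.int(len - w + 1L, len)])
}

helix_axis_resolved <- function(coords, res) {
  a <- centroid(coords, res$n_window)
  b <- centroid(coords, res$c_window)
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) stop("helix endpoint centroids coincide: axis undefined")
  v / nv
}

#' Helix axis of one frame
#'
#' Unit vector from the N-end window centroid to the C-end window centroid.
#'
#' @inheritParams hinge_angle
#' @param def A `tn_helix_def`.
#' @return Unit length-3 vector (N-to-C oriented).
#' @export
helix_axis <- function(trajectory, def, frame = 1L) {
  res <- resolve_helix(trajectory$topology, def)
  helix_axis_resolved(frame_coords(trajectory, frame), res)
}

#' Interhelical angle of one frame
#'
#' `180 - angle(axis_a, axis_b)` in degrees, both axes N-to-C oriented.
#' Symmetric in its two helices.
#'
#' @inheritParams hinge_angle
#' @param def A `tn_interhelical_def`.
#' @return Angle in degrees within [0, 180].
#' @export
interhelical_angle <- function(trajectory, def, frame = 1L) {
  ra <- resolve_helix(trajectory$topology, def$helix_a)
  rb <- resolve_helix(trajectory$topology, def$helix_b)
  coords <- frame_coords(trajectory, frame)
  180 - vec_angle(helix_axis_resolved(coords, ra),
                  helix_axis_resolved(coords, rb))
}

#' Centroid-to-centroid distance of one frame
#'
#' @inheritParams hinge_angle
#' @param def A `tn_distance_def`.
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(trajectory, def, frame = 1L) {
  top <- trajectory$topology
  ia <- resolve_selection(top, as.list(def$sel_a))
  ib <- resolve_selection(top, as.list(def$sel_b))
  coords <- frame_coords(trajectory, frame)
  sqrt(sum((centroid(coords, ia) - centroid(coords, ib))^2))
}

#' Evaluate a metric on every frame
#'
#' Resolves the metric's selections once against the topology, then
#' evaluates it per frame. Frames where the metric is undefined (e.g.
#' coincident centroids) are excluded and counted; more than 10% failed
#' frames is an error.
#'
#' @param trajectory A `tn_trajectory`.
#' @param metric A `tn_metric` (hinge, interhelical or distance definition).
#' @return A `tn_series` data.frame with columns `frame`, `run_id`,
#'   `frame_index`, `value`, and attributes `metric_name` and `n_failed`.
#' @export
metric_series <- function(trajectory, metric) {
  stopifnot(inherits(metric, "tn_metric"))
  top <- trajectory$topology
  fun <- if (inherits(metric, "tn_hinge_def")) {
    res <- resolve_hinge(top, metric)
    function(coords) hinge_angle_resolved(coords, res)
  } else if (inherits(metric, "tn_interhelical_def")) {
    ra <- resolve_helix(top, metric$helix_a)
    rb <- resolve_helix(top, metric$helix_b)
    function(coords) {
      180 - vec_angle(helix_axis_resolved(coords, ra),
                      helix_axis_resolved(coords, rb))
    }
  } else if (inherits(metric, "tn_distance_def")) {
    ia <- resolve_selection(top, as.list(metric$sel_a))
    ib <- resolve_selection(top, as.list(metric$sel_b))
    function(coords) sqrt(sum((centroid(coords, ia) - centroid(coords, ib))^2))
  } else {
    stop("unknown metric class: ", paste(class(metric), collapse = "/"))
  }
  nf <- n_frames(trajectory)
  vals <- numeric(nf)
  ok <- logical(nf)
  for (i in seq_len(nf)) {
    v <- tryCatch(fun(frame_coords(trajectory, i)), error = function(e) NA_real_)
    vals[i] <- v
    ok[i] <- is.finite(v)
  }
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * nf) {
    stop(sprintf("metric '%s' failed on %d of %d frames (> 10%%)",
                 metric$metric_name, n_failed, nf))
  }
  out <- data.frame(frame = which(ok),
                    run_id = trajectory$run_id[ok],
                    frame_index = trajectory$frame_index[ok],
                    value = vals[ok])
  structure(out, metric_name = metric$metric_name, n_failed = n_failed,
            class = c("tn_series", "data.frame"))
}

#' @export
print.tn_series <- function(x, ...) {
  cat(sprintf("Metric series '%s': %d frames, %d run(s)",
              attr(x, "metric_name"), nrow(x), length(unique(x$run_id))))
  nf <- attr(x, "n_failed")
  if (!is.null(nf) && nf > 0) cat(sprintf(" (%d failed frames excluded)", nf))
  cat(sprintf("\n  mean %.3f  sd %.3f  range [%.3f, %.3f]\n",
              mean(x$value), stats::sd(x$value), min(x$value), max(x$value)))
  invisible(x)
}

#' Write a metric series as CSV
#' @param series A `tn_series`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_series_csv <- function(series, file) {
  df <- as.data.frame(series)
  df$value <- round(df$value, 6)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
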