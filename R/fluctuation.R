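# Kabsch rotation: returns the 3x3 matrix U minimizing |P U - Q|_F for
# centered point sets P (mobile) and Q (reference), with the determinant
# sign corrected so U is a proper rotation.
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose one frame onto another
#'
#' Least-squares rigid-body superposition (Kabsch algorithm) of the mobile
#' coordinates onto the reference, fitted over a selection and applied to
#' all atoms.
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param idx Integer atom indices of the fit selection (>= 3 atoms).
#' @return The transformed mobile coordinates (N x 3), with attributes
#'   `rmsd_before` and `rmsd` (fit-selection RMSD after superposition).
#' @export
superpose <- function(mobile, reference, idx = seq_len(nrow(mobile))) {
  if (length(idx) < 3L) stop("superposition needs at least 3 atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  U <- kabsch_rotation(sweep(P, 2, cp), sweep(Q, 2, cq))
  out <- sweep(sweep(mobile, 2, cp) %*% U, 2, cq, `+`)
  before <- sqrt(mean(rowSums((P - Q)^2)))
  after <- sqrt(mean(rowSums((out[idx, , drop = FALSE] - Q)^2)))
  attr(out, "rmsd_before") <- before
  attr(out, "rmsd") <- after
  out
}

# RMSD between two centered coordinate sets after optimal rotation, without
# forming the rotated coordinates: msd = (tr PP' + tr QQ' - 2(s1+s2+/-s3))/N.
rmsd_centered <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- s$d
  if (det(s$u) * det(s$v) < 0) d[3] <- -d[3]
  msd <- (sum(P^2) + sum(Q^2) - 2 * sum(d)) / nrow(P)
  sqrt(max(msd, 0))
}

#' Per-residue root mean square fluctuation
#'
#' Frames are superposed onto an iterated mean structure (align to the first
#' frame, average, re-align to the average; two iterations) over the fit
#' selection, then the RMSF of each selected residue's alpha carbon about
#' its mean position is reported.
#'
#' @param trajectory A `tn_trajectory` with >= 2 frames.
#' @param selection Selection(s) resolved to the alpha carbons whose
#'   fluctuation is reported; default every subunit's full CA range.
#' @param fit_selection Selection used for the superposition; defaults to
#'   `selection`.
#' @return A `tn_rmsf` data.frame: `subunit`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(trajectory, selection = NULL, fit_selection = NULL) {
  if (n_frames(trajectory) < 2L) stop("RMSF needs at least 2 frames")
  top <- trajectory$topology
  if (is.null(selection)) {
    selection <- sprintf("%s:%d-%d:CA", top$subunit_ranges$subunit,
                         top$subunit_ranges$first, top$subunit_ranges$last)
  }
  idx <- resolve_selection(top, as.list(selection))
  idx <- idx[top$atoms$elety[idx] == "CA"]
  if (length(idx) == 0L) stop("selection contains no CA atoms")
  fit_idx <- if (is.null(fit_selection)) idx else
    resolve_selection(top, as.list(fit_selection))

  nf <- n_frames(trajectory)
  frames <- lapply(seq_len(nf), function(i) frame_coords(trajectory, i))
  ref <- frames[[1]]
  for (iter in 1:2) {
    frames <- lapply(frames, superpose, reference = ref, idx = fit_idx)
    ref <- Reduce(`+`, frames) / nf
  }
  sel_arr <- vapply(frames, function(f) f[idx, , drop = FALSE],
                    matrix(0, length(idx), 3))
  mean_pos <- apply(sel_arr, c(1, 2), mean)
  dev2 <- apply(sel_arr, 3, function(f) rowSums((f - mean_pos)^2))
  per_atom <- sqrt(rowMeans(matrix(dev2, nrow = length(idx))))

  at <- top$atoms[idx, ]
  key <- paste(at$subunit, at$resno)
  agg <- tapply(per_atom, key, mean)
  ord <- match(unique(key), names(agg))
  out <- data.frame(
    subunit = at$subunit[!duplicated(key)],
    resno = at$resno[!duplicated(key)],
    rmsf = as.numeric(agg[ord])
  )
  structure(out, class = c("tn_rmsf", "data.frame"))
}

#' Pairwise RMSD matrix over trajectory frames
#'
#' RMSD after optimal superposition for every frame pair, over a selection
#' (all heavy atoms by default, the convention for representative-structure
#' selection). Frames are strided so at most `max_frames` enter the matrix;
#' more than 20,000 frames after striding is refused without
#' `override = TRUE`.
#'
#' @param trajectory A `tn_trajectory`.
#' @param selection Selection(s); default all heavy atoms of every subunit.
#' @param stride Keep every stride-th pooled frame. Default (`NULL`) picks
#'   the smallest stride with at most `max_frames` frames.
#' @param max_frames Frame budget used when `stride` is `NULL`
#'   (default 2000).
#' @param override Allow more than 20,000 strided frames.
#' @return A `tn_rmsd_matrix`: symmetric matrix with zero diagonal,
#'   Angstrom, with `run_id`/`frame_index` labels and the stride recorded
#'   as attributes.
#' @export
pairwise_rmsd <- function(trajectory, selection = NULL, stride = NULL,
                          max_frames = 2000L, override = FALSE) {
  top <- trajectory$topology
  if (is.null(selection)) {
    selection <- sprintf("%s:%d-%d:heavy", top$subunit_ranges$subunit,
                         top$subunit_ranges$first, top$subunit_ranges$last)
  }
  idx <- resolve_selection(top, as.list(selection))
  nf <- n_frames(trajectory)
  if (is.null(stride)) stride <- max(1L, ceiling(nf / max_frames))
  keep <- seq.int(1L, nf, by = stride)
  if (length(keep) > 20000L && !override) {
    stop(length(keep), " frames after striding exceeds the 20,000-frame ",
         "guard; pass override = TRUE to proceed")
  }
  if (length(keep) < 2L) stop("need at least 2 frames after striding")
  centered <- lapply(keep, function(i) {
    P <- frame_coords(trajectory, i)[idx, , drop = FALSE]
    sweep(P, 2, colMeans(P))
  })
  n <- length(keep)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    Pi <- centered[[i]]
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- rmsd_centered(Pi, centered[[j]])
    }
  }
  lab <- sprintf("r%d.f%d", trajectory$run_id[keep],
                 trajectory$frame_index[keep])
  dimnames(m) <- list(lab, lab)
  structure(m, run_id = trajectory$run_id[keep],
            frame_index = trajectory$frame_index[keep],
            frame = keep, stride = stride,
            class = c("tn_rmsd_matrix", "matrix", "array"))
}

#' Representative structure (medoid) from a pairwise RMSD matrix
#'
#' The conformation with the lowest combined (summed) RMSD to all other
#' structures in the group. Ties are broken by the lowest
#' (`run_id`, `frame_index`) pair.
#'
#' @param mat A `tn_rmsd_matrix` (or plain symmetric matrix).
#' @return List: `run_id`, `frame_index`, `frame` (pooled frame number when
#'   known), `row` (matrix row), `row_sum`.
#' @export
representative_structure <- function(mat) {
  rs <- rowSums(mat)
  run_id <- attr(mat, "run_id")
  frame_index <- attr(mat, "frame_index")
  if (is.null(run_id)) run_id <- rep(1L, nrow(mat))
  if (is.null(frame_index)) frame_index <- seq_len(nrow(mat))
  cand <- which(rs <= min(rs) + 1e-12)
  best <- cand[order(run_id[cand], frame_index[cand])][1]
  frame <- attr(mat, "frame")
  list(run_id = run_id[best], frame_index = frame_index[best],
       frame = if (!is.null(frame)) frame[best] else best,
       row = unname(best), row_sum = unname(rs[best]))
}

#' @export
print.tn_rmsd_matrix <- function(x, ...) {
  cat(sprintf("Pairwise RMSD matrix: %d frames (stride %d), mean %.3f A\n",
              nrow(x), attr(x, "stride"),
              mean(x[upper.tri(x)])))
  invisible(x)
}
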