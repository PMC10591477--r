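#' Default chain-to-subunit mapping
#'
#' Troponin core structures deposited in the PDB conventionally place the
#' calcium-binding subunit (TnC) on chain A, the inhibitory subunit (TnI) on
#' chain B and the tropomyosin-binding subunit (TnT) on chain C. Chains not
#' listed in the map keep their chain ID as the subunit label.
#'
#' @return Named character vector mapping chain IDs to subunit labels.
#' @export
default_chain_map <- function() {
  c(A = "TnC", B = "TnI", C = "TnT")
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL of a PDB file into a
#' topology: the ordered atom table against which selections are resolved and
#' trajectory frames are interpreted. Coordinates of the first model are kept
#' alongside so a single-structure PDB is immediately usable as a one-frame
#' trajectory.
#'
#' @param file Path to a PDB file.
#' @param chain_map Named character vector mapping chain IDs to subunit
#'   labels (default [default_chain_map()]). Unmapped chains keep their
#'   chain ID.
#' @return An object of class `tn_topology`: a list with elements
#'   \describe{
#'     \item{atoms}{data.frame with one row per atom: `atom_index` (1-based,
#'       file order), `eleno`, `elety` (PDB atom name), `element`, `resid`
#'       (3-letter residue name, `SEP` marks phosphoserine), `chain`,
#'       `subunit`, `resno` (author numbering).}
#'     \item{subunit_ranges}{data.frame of residue-number ranges per subunit.}
#'     \item{xyz}{numeric vector of first-model coordinates (bio3d layout).}
#'   }
#' @export
read_topology <- function(file, chain_map = default_chain_map()) {
  if (!file.exists(file)) stop("PDB file not found: ", file)
  pdb <- tryCatch(
    bio3d::read.pdb(file, multi = FALSE, verbose = FALSE),
    error = function(e) {
      stop("PDB parse error in ", file, ": ", conditionMessage(e),
           call. = FALSE)
    })
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in ", file)
  bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))
  if (length(bad)) {
    stop("missing coordinates for atom record ", bad[1],
         " (serial ", at$eleno[bad[1]], ") in ", file)
  }
  dup <- which(duplicated(at$eleno))
  if (length(dup)) {
    stop("duplicate atom serial ", at$eleno[dup[1]],
         " at atom record ", dup[1], " in ", file)
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- " "
  subunit <- ifelse(chain %in% names(chain_map), chain_map[chain], chain)
  atoms <- data.frame(
    atom_index = seq_len(nrow(at)),
    eleno      = at$eleno,
    elety      = at$elety,
    element    = infer_element(at$elesy, at$elety),
    resid      = at$resid,
    chain      = chain,
    subunit    = subunit,
    resno      = at$resno,
    stringsAsFactors = FALSE
  )
  new_topology(atoms, xyz = pdb$xyz[1, ], source = file)
}

new_topology <- function(atoms, xyz = NULL, source = NA_character_) {
  subs <- unique(atoms$subunit)
  subunit_ranges <- do.call(rbind, lapply(subs, function(s) {
    r <- atoms$resno[atoms$subunit == s]
    data.frame(subunit = s, first = min(r), last = max(r),
               n_residues = length(unique(r)), stringsAsFactors = FALSE)
  }))
  structure(
    list(atoms = atoms, subunit_ranges = subunit_ranges,
         xyz = xyz, source = source),
    class = "tn_topology"
  )
}

# Element from the PDB element column when present, else from the atom name:
# leading digits stripped, names beginning with H (incl. 1HB-style) are
# hydrogen, otherwise the first alphabetic character.
infer_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  need <- el == ""
  if (any(need)) {
    nm <- gsub("^[0-9']+", "", toupper(trimws(elety[need])))
    first <- substr(nm, 1, 1)
    two <- substr(nm, 1, 2)
    guess <- first
    guess[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA") &
            nchar(nm) == 2] <- two[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA") &
                                     nchar(nm) == 2]
    el[need] <- guess
  }
  el
}

#' @export
print.tn_topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      nrow(x$subunit_ranges), "subunit(s)\n")
  for (i in seq_len(nrow(x$subunit_ranges))) {
    r <- x$subunit_ranges[i, ]
    cat(sprintf("  %-4s residues %d-%d (%d residues)\n",
                r$subunit, r$first, r$last, r$n_residues))
  }
  nsep <- length(unique(x$atoms$resno[x$atoms$resid == "SEP"]))
  if (nsep) cat("  phosphoserine (SEP) residues:", nsep, "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology A `tn_topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Parse a selection expression
#'
#' Selections use the compact string form `"subunit:lo-hi:filter"`, e.g.
#' `"TnC:3-85:CA"` for the alpha carbons of TnC residues 3 to 85. The residue
#' range is inclusive and in author numbering; a single residue may be given
#' as `"TnC:5:CA"`. The atom filter is one of `CA` (alpha carbons), `heavy`
#' (non-hydrogen) or `all`, defaulting to `CA`.
#'
#' @param x Selection string, or an already-parsed `tn_selection`.
#' @return A `tn_selection`: list(subunit, range, filter).
#' @export
parse_selection <- function(x) {
  if (inherits(x, "tn_selection")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || length(parts) > 3L) {
    stop("selection must be 'subunit:lo-hi[:filter]', got: ", x)
  }
  rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
  rng <- suppressWarnings(as.integer(rng))
  if (any(is.na(rng)) || length(rng) > 2L) {
    stop("bad residue range in selection: ", x)
  }
  if (length(rng) == 1L) rng <- c(rng, rng)
  if (rng[1] > rng[2]) stop("residue range lo > hi in selection: ", x)
  filter <- if (length(parts) == 3L) parts[3] else "CA"
  if (!filter %in% c("CA", "heavy", "all")) {
    stop("atom filter must be CA, heavy or all, got: ", filter)
  }
  structure(list(subunit = parts[1], range = rng, filter = filter),
            class = "tn_selection")
}

#' @export
print.tn_selection <- function(x, ...) {
  cat(sprintf("%s:%d-%d:%s\n", x$subunit, x$range[1], x$range[2], x$filter))
  invisible(x)
}

#' Resolve a selection to atom indices
#'
#' Resolves one selection (or the union of several) against a topology,
#' returning atom indices in topology order. The `CA` filter keeps exactly
#' one alpha carbon per residue.
#'
#' @param topology A `tn_topology`.
#' @param expr A selection string, a `tn_selection`, or a list/character
#'   vector of them (union of disjoint ranges).
#' @return Sorted integer vector of 1-based atom indices.
#' @export
resolve_selection <- function(topology, expr) {
  if (is.character(expr) && length(expr) > 1L) expr <- as.list(expr)
  if (is.list(expr) && !inherits(expr, "tn_selection")) {
    idx <- sort(unique(unlist(lapply(expr, resolve_selection,
                                     topology = topology))))
    return(idx)
  }
  sel <- parse_selection(expr)
  at <- topology$atoms
  keep <- at$subunit == sel$subunit &
    at$resno >= sel$range[1] & at$resno <= sel$range[2]
  keep <- keep & switch(sel$filter,
    CA    = at$elety == "CA",
    heavy = at$element != "H",
    all   = TRUE
  )
  idx <- at$atom_index[keep]
  if (length(idx) == 0L) {
    stop(sprintf("selection %s:%d-%d:%s matches no atoms",
                 sel$subunit, sel$range[1], sel$range[2], sel$filter))
  }
  idx
}

#' Read trajectory frames
#'
#' Reads one or more trajectory files (multi-model PDB or DCD, detected by
#' extension) and concatenates their frames in path order. Each path is
#' treated as one independent simulation run; `run_id` is the path ordinal.
#'
#' @param paths Character vector of trajectory file paths.
#' @param topology The `tn_topology` the frames belong to; every file must
#'   carry exactly this number of atoms.
#' @return A `tn_trajectory`: list with `topology`, `xyz` (frames x 3N
#'   coordinate matrix, bio3d layout, Angstrom), `run_id` and `frame_index`
#'   (1-based within run) vectors, and `n_runs`.
#' @export
read_trajectory <- function(paths, topology) {
  stopifnot(inherits(topology, "tn_topology"))
  nat <- n_atoms(topology)
  mats <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      m <- bio3d::read.dcd(p, verbose = FALSE)
      m <- unclass(m)
    } else {
      m <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz
      m <- unclass(m)
    }
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (ncol(m) != 3L * nat) {
      stop(sprintf("atom count mismatch in %s: file has %d atoms, topology has %d",
                   p, ncol(m) / 3, nat))
    }
    mats[[i]] <- m
  }
  per_run <- vapply(mats, nrow, integer(1))
  new_trajectory(topology,
                 xyz = do.call(rbind, mats),
                 run_id = rep(seq_along(paths), per_run),
                 frame_index = unlist(lapply(per_run, seq_len), use.names = FALSE))
}

new_trajectory <- function(topology, xyz, run_id, frame_index) {
  stopifnot(nrow(xyz) == length(run_id), length(run_id) == length(frame_index))
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  structure(
    list(topology = topology, xyz = xyz,
         run_id = as.integer(run_id), frame_index = as.integer(frame_index),
         n_runs = length(unique(run_id))),
    class = "tn_trajectory"
  )
}

#' Number of frames in a trajectory
#' @param trajectory A `tn_trajectory`.
#' @return Integer frame count (all runs pooled).
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Coordinates of one frame
#' @param trajectory A `tn_trajectory`.
#' @param i Pooled frame number (1-based, runs concatenated).
#' @return N x 3 numeric matrix of coordinates in Angstrom.
#' @export
frame_coords <- function(trajectory, i) {
  stopifnot(i >= 1L, i <= n_frames(trajectory))
  matrix(trajectory$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' @export
print.tn_trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames,", x$n_runs, "run(s),",
      n_atoms(x$topology), "atoms\n")
  tab <- table(x$run_id)
  cat("  frames per run:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write trajectory frames to disk
#'
#' Writes frames as a multi-model PDB (human-readable, the canonical fixture
#' dialect) or as a DCD binary trajectory.
#'
#' @param trajectory A `tn_trajectory`.
#' @param file Output path.
#' @param format `"pdb"` or `"dcd"`; default guessed from the extension.
#' @param frames Optional integer vector of pooled frame numbers to write
#'   (default all).
#' @return Invisibly, the output path.
#' @export
write_frames <- function(trajectory, file,
                         format = c("auto", "pdb", "dcd"), frames = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", file, ignore.case = TRUE)) "dcd" else "pdb"
  }
  xyz <- trajectory$xyz
  if (!is.null(frames)) xyz <- xyz[frames, , drop = FALSE]
  if (format == "dcd") {
    write_dcd(xyz, file)
  } else {
    at <- trajectory$topology$atoms
    bio3d::write.pdb(file = file, xyz = xyz,
                     resno = at$resno, resid = at$resid, eleno = at$eleno,
                     elety = at$elety, chain = at$chain)
  }
  invisible(file)
}

# Minimal X-PLOR-dialect DCD writer (little-endian float32, no unit cell).
write_dcd <- function(xyz, file) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natom <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  con <- file(file, "wb")
  on.exit(close(con))
  rec <- function(raw) {
    writeBin(length(raw), con, size = 4, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  rec(c(charToRaw("CORD"),
        writeBin(icntrl, raw(), size = 4, endian = "little")))
  rec(c(writeBin(1L, raw(), size = 4, endian = "little"),
        charToRaw(formatC("Written by tndyn", width = 80, flag = "-"))))
  rec(writeBin(as.integer(natom), raw(), size = 4, endian = "little"))
  for (i in seq_len(nf)) {
    fr <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    for (d in 1:3) {
      rec(writeBin(as.numeric(fr[, d]), raw(), size = 4, endian = "little"))
    }
  }
  invisible(file)
}

#' Build a trajectory from an in-memory coordinate matrix
#'
#' Mostly useful for constructing small test systems and for the synthetic
#' generator.
#'
#' @param topology A `tn_topology`.
#' @param xyz Frames x 3N coordinate matrix (bio3d layout).
#' @param run_id Integer vector of run labels, one per frame (default: one
#'   run).
#' @return A `tn_trajectory`.
#' @export
as_trajectory <- function(topology, xyz, run_id = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (is.null(run_id)) run_id <- rep(1L, nrow(xyz))
  frame_index <- stats::ave(seq_along(run_id), run_id, FUN = seq_along)
  new_trajectory(topology, xyz, run_id, frame_index)
}
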