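# Rule tables for atom typing. Protein chemistry only: the 20 standard
# amino acids plus phosphoserine (SEP, net charge -2 at physiological pH)
# and the common His protonation-state names (HID/HIE neutral, HIP +1).

.donor_sidechain <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  HID = "ND1", HIE = "NE2", HIP = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG"
)

.acceptor_sidechain <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", MET = "SD",
  HIS = c("ND1", "NE2"), HID = "NE2", HIE = "ND1",
  SEP = c("O1P", "O2P", "O3P", "OG")
)

.pos_group <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIP = c("ND1", "NE2")
)

.neg_group <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), SEP = c("O1P", "O2P", "O3P")
)

.ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HID = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HIE = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HIP = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

.vdw_by_element <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                     S = 1.80, P = 1.80)

.standard_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "SEP", "HID", "HIE", "HIP"
)

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Assign physico-chemical atom types for interaction detection
#'
#' Classifies every atom of a topology as hydrogen-bond donor and/or
#' acceptor, member of a formal charge group (+1 Arg/Lys/His(+) guanidinium,
#' ammonium and imidazolium groups; -1/-2 Asp/Glu carboxylates and the SEP
#' phosphate; charged termini), member of an aromatic ring, and assigns a
#' van der Waals radius by element. Residues outside the rule table are
#' typed van-der-Waals-only with a warning.
#'
#' @param topology A `tn_topology`.
#' @return A `tn_atom_typing` data.frame, one row per atom: `donor`,
#'   `acceptor` (logical), `charge` (+1/-1/0 sign of the group), `charge_group`
#'   (group id or NA), `ring_id` (or NA), `vdw_radius`, `is_h`,
#'   `is_backbone`.
#' @export
assign_atom_types <- function(topology) {
  at <- topology$atoms
  n <- nrow(at)
  resid <- toupper(at$resid)
  unknown <- setdiff(unique(resid), .standard_resnames)
  if (length(unknown)) {
    warning("unknown residue(s) typed van-der-Waals-only: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  known <- resid %in% .standard_resnames
  is_h <- at$element == "H"
  is_bb <- at$elety %in% .backbone_names

  donor <- acceptor <- logical(n)
  # backbone amide N donates (except proline), carbonyl O (and OXT) accepts
  donor[known & at$elety == "N" & resid != "PRO"] <- TRUE
  acceptor[known & at$elety %in% c("O", "OXT")] <- TRUE
  reskey <- paste(at$subunit, at$resno)
  for (i in which(known & !is_bb & !is_h)) {
    r <- resid[i]
    if (at$elety[i] %in% .donor_sidechain[[r]]) donor[i] <- TRUE
    if (at$elety[i] %in% .acceptor_sidechain[[r]]) acceptor[i] <- TRUE
  }

  charge <- integer(n)
  charge_group <- rep(NA_integer_, n)
  gid <- 0L
  for (key in unique(reskey[known])) {
    rows <- which(reskey == key & known)
    r <- resid[rows[1]]
    pos <- rows[at$elety[rows] %in% .pos_group[[r]]]
    if (length(pos)) {
      gid <- gid + 1L
      charge[pos] <- 1L
      charge_group[pos] <- gid
    }
    neg <- rows[at$elety[rows] %in% .neg_group[[r]]]
    if (length(neg)) {
      gid <- gid + 1L
      charge[neg] <- -1L
      charge_group[neg] <- gid
    }
  }
  # charged termini: first residue's N (+), last residue's O/OXT (-)
  for (s in unique(at$subunit)) {
    rows <- which(at$subunit == s & known)
    if (!length(rows)) next
    first <- rows[at$resno[rows] == min(at$resno[rows])]
    nt <- first[at$elety[first] == "N"]
    if (length(nt)) {
      gid <- gid + 1L
      charge[nt] <- 1L
      charge_group[nt] <- gid
    }
    last <- rows[at$resno[rows] == max(at$resno[rows])]
    ct <- last[at$elety[last] %in% c("O", "OXT")]
    if (length(ct)) {
      gid <- gid + 1L
      charge[ct] <- -1L
      charge_group[ct] <- gid
    }
  }

  ring_id <- rep(NA_integer_, n)
  rid <- 0L
  for (key in unique(reskey[known])) {
    rows <- which(reskey == key & known)
    rings <- .ring_atoms[[resid[rows[1]]]]
    for (ring in rings) {
      mem <- rows[at$elety[rows] %in% ring]
      if (length(mem) >= 5L) {
        rid <- rid + 1L
        ring_id[mem] <- rid
      }
    }
  }

  vdw <- unname(.vdw_by_element[at$element])
  vdw[is.na(vdw)] <- 1.70

  structure(
    data.frame(atom_index = at$atom_index, donor = donor, acceptor = acceptor,
               charge = charge, charge_group = charge_group,
               ring_id = ring_id, vdw_radius = vdw, is_h = is_h,
               is_backbone = is_bb),
    subunit = at$subunit, resno = at$resno,
    has_hydrogens = any(is_h),
    class = c("tn_atom_typing", "data.frame")
  )
}

#' Interaction geometry cutoffs
#'
#' Standard geometric criteria for the four interaction classes. Hydrogen
#' bond: donor-heavy-atom to acceptor distance at most `hbond` Angstrom and,
#' when explicit hydrogens are present, a D-H...A angle of at least
#' `hbond_angle` degrees (topologies without hydrogens fall back to the
#' distance criterion alone). Ionic: any atom of a positive group within
#' `ionic` of any atom of a negative group. Aromatic: ring-centroid distance
#' at most `aromatic`. Van der Waals: heavy-atom distance at most
#' r1 + r2 + `vdw_pad`.
#'
#' @param hbond,ionic,aromatic Distance cutoffs, Angstrom.
#' @param hbond_angle Minimum D-H...A angle, degrees.
#' @param vdw_pad Padding added to the summed van der Waals radii, Angstrom.
#' @return A `tn_cutoffs` list.
#' @export
interaction_cutoffs <- function(hbond = 3.5, hbond_angle = 120,
                                ionic = 4.0, aromatic = 5.0, vdw_pad = 0.5) {
  structure(list(hbond = hbond, hbond_angle = hbond_angle, ionic = ionic,
                 aromatic = aromatic, vdw_pad = vdw_pad),
            class = "tn_cutoffs")
}

# All pairs (i from A, j from B) with distance <= cutoff. A, B are index
# vectors into coords; returns two-column index matrix plus distances.
pairs_within <- function(coords, A, B, cutoff) {
  if (!length(A) || !length(B)) {
    return(list(i = integer(0), j = integer(0), d = numeric(0)))
  }
  ca <- coords[A, , drop = FALSE]
  cb <- coords[B, , drop = FALSE]
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * tcrossprod(ca, cb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  list(i = A[hit[, 1]], j = B[hit[, 2]],
       d = sqrt(pmax(d2[hit], 0)))
}

#' Detect atomistic interactions in one frame
#'
#' Classifies hydrogen-bond, ionic, aromatic and van der Waals interactions
#' between residue pairs from atom types and positions, and deduplicates
#' them to residue-pair level: a residue pair either has or does not have
#' each interaction type in a frame. Intra-residue pairs, and
#' backbone-backbone pairs of sequence-adjacent residues, are excluded for
#' the hydrogen-bond and ionic classes. A residue pair already carrying a
#' hydrogen-bond or ionic event in the frame is not additionally counted as
#' van der Waals.
#'
#' @param coords N x 3 coordinate matrix of the frame.
#' @param typing A `tn_atom_typing` for the same topology.
#' @param cutoffs A `tn_cutoffs`.
#' @param frame Frame number recorded in the events (default 1).
#' @return Data.frame of events: `frame`, `sub_a`, `res_a`, `sub_b`,
#'   `res_b`, `type`; the pair is ordered canonically (by subunit label,
#'   then residue number).
#' @export
detect_interactions <- function(coords, typing,
                                cutoffs = interaction_cutoffs(),
                                frame = 1L) {
  sub <- attr(typing, "subunit")
  resno <- attr(typing, "resno")
  has_h <- isTRUE(attr(typing, "has_hydrogens"))
  heavy <- which(!typing$is_h)

  same_res <- function(i, j) sub[i] == sub[j] & resno[i] == resno[j]
  adj_bb <- function(i, j) {
    typing$is_backbone[i] & typing$is_backbone[j] &
      sub[i] == sub[j] & abs(resno[i] - resno[j]) <= 1L
  }

  ev_i <- list(); ev_j <- list(); ev_t <- list(); k <- 0L
  add <- function(i, j, type) {
    if (!length(i)) return()
    k <<- k + 1L
    ev_i[[k]] <<- i; ev_j[[k]] <<- j; ev_t[[k]] <<- rep(type, length(i))
  }

  # hydrogen bonds
  don <- which(typing$donor)
  acc <- which(typing$acceptor)
  hb <- pairs_within(coords, don, acc, cutoffs$hbond)
  keep <- !same_res(hb$i, hb$j) & !adj_bb(hb$i, hb$j)
  hb_i <- hb$i[keep]; hb_j <- hb$j[keep]
  if (has_h && length(hb_i)) {
    hyd <- which(typing$is_h)
    ok <- vapply(seq_along(hb_i), function(p) {
      di <- hb_i[p]
      # hydrogens covalently attached to the donor: same residue, < 1.25 A
      cand <- hyd[sub[hyd] == sub[di] & resno[hyd] == resno[di]]
      if (!length(cand)) return(TRUE)  # donor without explicit H: keep
      hd <- sqrt(rowSums(sweep(coords[cand, , drop = FALSE], 2,
                               coords[di, ])^2))
      cand <- cand[hd < 1.25]
      if (!length(cand)) return(TRUE)
      ang <- vapply(cand, function(h) {
        vec_angle(coords[di, ] - coords[h, ], coords[hb_j[p], ] - coords[h, ])
      }, numeric(1))
      any(ang >= cutoffs$hbond_angle)
    }, logical(1))
    hb_i <- hb_i[ok]; hb_j <- hb_j[ok]
  }
  add(hb_i, hb_j, "hbond")

  # ionic
  pos <- which(typing$charge > 0L)
  neg <- which(typing$charge < 0L)
  io <- pairs_within(coords, pos, neg, cutoffs$ionic)
  keep <- !same_res(io$i, io$j) & !adj_bb(io$i, io$j)
  add(io$i[keep], io$j[keep], "ionic")

  # aromatic: ring-centroid distance
  rings <- sort(unique(typing$ring_id[!is.na(typing$ring_id)]))
  if (length(rings) >= 2L) {
    cent <- t(vapply(rings, function(r) {
      colMeans(coords[which(typing$ring_id == r), , drop = FALSE])
    }, numeric(3)))
    rep_atom <- vapply(rings, function(r) which(typing$ring_id == r)[1],
                       integer(1))
    d2 <- outer(rowSums(cent^2), rowSums(cent^2), `+`) - 2 * tcrossprod(cent)
    hit <- which(d2 <= cutoffs$aromatic^2 & upper.tri(d2), arr.ind = TRUE)
    if (nrow(hit)) {
      i <- rep_atom[hit[, 1]]; j <- rep_atom[hit[, 2]]
      keep <- !same_res(i, j)
      add(i[keep], j[keep], "aromatic")
    }
  }

  # van der Waals between heavy atoms, radius-dependent cutoff: screen at
  # the maximum possible cutoff then filter per pair
  max_cut <- 2 * max(typing$vdw_radius[heavy]) + cutoffs$vdw_pad
  vw <- pairs_within(coords, heavy, heavy, max_cut)
  keep <- vw$i < vw$j & !same_res(vw$i, vw$j) &
    vw$d <= typing$vdw_radius[vw$i] + typing$vdw_radius[vw$j] + cutoffs$vdw_pad
  add(vw$i[keep], vw$j[keep], "vdw")

  if (k == 0L) {
    return(data.frame(frame = integer(0), sub_a = character(0),
                      res_a = integer(0), sub_b = character(0),
                      res_b = integer(0), type = character(0)))
  }
  i <- unlist(ev_i); j <- unlist(ev_j); type <- unlist(ev_t)
  # canonical residue-pair order and residue-level dedup
  swap <- sub[i] > sub[j] | (sub[i] == sub[j] & resno[i] > resno[j])
  a <- ifelse(swap, j, i)
  b <- ifelse(swap, i, j)
  df <- data.frame(frame = frame, sub_a = sub[a], res_a = resno[a],
                   sub_b = sub[b], res_b = resno[b], type = type,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("sub_a", "res_a", "sub_b", "res_b", "type")]), ]
  # a pair with an hbond/ionic event this frame is not also vdw
  key <- paste(df$sub_a, df$res_a, df$sub_b, df$res_b)
  strong <- unique(key[df$type %in% c("hbond", "ionic")])
  df <- df[!(df$type == "vdw" & key %in% strong), ]
  rownames(df) <- NULL
  df
}

#' Profile interactions over a whole trajectory
#'
#' Runs [detect_interactions()] on every frame and aggregates the events to
#' a residue-pair frequency table.
#'
#' @param trajectory A `tn_trajectory`.
#' @param typing Optional precomputed `tn_atom_typing`.
#' @param cutoffs A `tn_cutoffs`.
#' @param frames Optional pooled frame numbers to profile (default all).
#' @return A `tn_freq_table` (see [aggregate_interactions()]).
#' @export
profile_interactions <- function(trajectory, typing = NULL,
                                 cutoffs = interaction_cutoffs(),
                                 frames = NULL) {
  if (is.null(typing)) typing <- assign_atom_types(trajectory$topology)
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  evs <- vector("list", length(frames))
  for (q in seq_along(frames)) {
    evs[[q]] <- detect_interactions(frame_coords(trajectory, frames[q]),
                                    typing, cutoffs, frame = q)
  }
  aggregate_interactions(do.call(rbind, evs), n_frames = length(frames),
                         cutoffs = cutoffs)
}

#' Aggregate per-frame interaction events to frequencies
#'
#' Counts, for every residue pair and interaction type, the number of
#' frames in which the interaction is present, and expresses it as a
#' percentage of all frames (the scale used for interaction heat maps).
#'
#' @param events Event data.frame as returned by [detect_interactions()]
#'   with frame numbers in 1..`n_frames`.
#' @param n_frames Total frame count of the system.
#' @param cutoffs Optional cutoffs recorded in the result.
#' @return A `tn_freq_table` data.frame: `sub_a`, `res_a`, `sub_b`, `res_b`,
#'   `type`, `count`, `percent`, sorted canonically, with attribute
#'   `n_frames`.
#' @export
aggregate_interactions <- function(events, n_frames, cutoffs = NULL) {
  stopifnot(n_frames >= 1L)
  if (nrow(events) && (min(events$frame) < 1L || max(events$frame) > n_frames)) {
    stop("event frame numbers must lie in 1..n_frames")
  }
  if (nrow(events) == 0L) {
    out <- data.frame(sub_a = character(0), res_a = integer(0),
                      sub_b = character(0), res_b = integer(0),
                      type = character(0), count = integer(0),
                      percent = numeric(0))
  } else {
    key <- paste(events$sub_a, events$res_a, events$sub_b, events$res_b,
                 events$type, sep = "\r")
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    out <- data.frame(sub_a = parts[, 1], res_a = as.integer(parts[, 2]),
                      sub_b = parts[, 3], res_b = as.integer(parts[, 4]),
                      type = parts[, 5], count = as.integer(cnt),
                      stringsAsFactors = FALSE)
    out$percent <- 100 * out$count / n_frames
    out <- out[order(out$sub_a, out$res_a, out$sub_b, out$res_b, out$type), ]
    rownames(out) <- NULL
  }
  structure(out, n_frames = n_frames, cutoffs = cutoffs,
            class = c("tn_freq_table", "data.frame"))
}

#' Look up an interaction frequency
#'
#' Percentage of frames in which a residue pair shows an interaction type;
#' 0 for pairs absent from the table. The pair is symmetric: either order
#' may be given.
#'
#' @param table A `tn_freq_table`.
#' @param res_a,res_b Residues as `"subunit:resno"` strings.
#' @param type Interaction type.
#' @return Percentage in [0, 100].
#' @export
interaction_percent <- function(table, res_a, res_b, type) {
  pa <- strsplit(res_a, ":", fixed = TRUE)[[1]]
  pb <- strsplit(res_b, ":", fixed = TRUE)[[1]]
  a <- list(sub = pa[1], res = as.integer(pa[2]))
  b <- list(sub = pb[1], res = as.integer(pb[2]))
  if (a$sub > b$sub || (a$sub == b$sub && a$res > b$res)) {
    tmp <- a; a <- b; b <- tmp
  }
  hit <- table$sub_a == a$sub & table$res_a == a$res &
    table$sub_b == b$sub & table$res_b == b$res & table$type == type
  if (any(hit)) table$percent[hit][1] else 0
}

#' Compare interaction frequencies between two states
#'
#' Percentage-point difference (state B minus state A) for every residue
#' pair and type present in either table; pairs absent from one table are
#' treated as 0%.
#'
#' @param table_a,table_b `tn_freq_table` objects with comparable frame
#'   semantics.
#' @return A `tn_delta_table` data.frame with `percent_a`, `percent_b`,
#'   `delta` (percentage points, in [-100, 100]).
#' @export
compare_states <- function(table_a, table_b) {
  key <- function(t) paste(t$sub_a, t$res_a, t$sub_b, t$res_b, t$type,
                           sep = "\r")
  ka <- key(table_a); kb <- key(table_b)
  all_keys <- union(ka, kb)
  pa <- table_a$percent[match(all_keys, ka)]
  pb <- table_b$percent[match(all_keys, kb)]
  pa[is.na(pa)] <- 0; pb[is.na(pb)] <- 0
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  out <- data.frame(sub_a = parts[, 1], res_a = as.integer(parts[, 2]),
                    sub_b = parts[, 3], res_b = as.integer(parts[, 4]),
                    type = parts[, 5], percent_a = pa, percent_b = pb,
                    delta = pb - pa, stringsAsFactors = FALSE)
  out <- out[order(out$sub_a, out$res_a, out$sub_b, out$res_b, out$type), ]
  rownames(out) <- NULL
  structure(out, class = c("tn_delta_table", "data.frame"))
}

#' Dense residue-by-residue interaction matrix
#'
#' Heat-map-shaped matrix of interaction percentages for one type, rows and
#' columns spanning two residue ranges (e.g. ionic interactions between the
#' TnI N-terminal extension and the TnC N-lobe).
#'
#' @param table A `tn_freq_table` or `tn_delta_table` (uses `delta`).
#' @param rows,cols Range strings `"subunit:lo-hi"`.
#' @param type Interaction type.
#' @return Numeric matrix with `subunit_resno` dimnames.
#' @export
heatmap_matrix <- function(table, rows, cols, type) {
  pr <- parse_selection(paste0(rows, ":all"))
  pc <- parse_selection(paste0(cols, ":all"))
  rr <- seq.int(pr$range[1], pr$range[2])
  cc <- seq.int(pc$range[1], pc$range[2])
  if (!length(rr) || !length(cc)) stop("empty residue range")
  m <- matrix(0, length(rr), length(cc),
              dimnames = list(paste0(pr$subunit, "_", rr),
                              paste0(pc$subunit, "_", cc)))
  val <- if ("delta" %in% names(table)) table$delta else table$percent
  sel <- table$type == type
  for (q in which(sel)) {
    a_in_r <- table$sub_a[q] == pr$subunit && table$res_a[q] %in% rr
    b_in_c <- table$sub_b[q] == pc$subunit && table$res_b[q] %in% cc
    if (a_in_r && b_in_c) {
      m[match(table$res_a[q], rr), match(table$res_b[q], cc)] <- val[q]
    }
    # symmetric orientation
    a_in_c <- table$sub_a[q] == pc$subunit && table$res_a[q] %in% cc
    b_in_r <- table$sub_b[q] == pr$subunit && table$res_b[q] %in% rr
    if (a_in_c && b_in_r) {
      m[match(table$res_b[q], rr), match(table$res_a[q], cc)] <- val[q]
    }
  }
  m
}

#' @export
print.tn_freq_table <- function(x, ...) {
  cat(sprintf("Interaction frequency table: %d residue-pair/type rows over %d frames\n",
              nrow(x), attr(x, "n_frames")))
  if (nrow(x)) {
    tab <- table(x$type)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  }
  invisible(x)
}
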