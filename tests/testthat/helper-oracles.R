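# Independent oracles and fixture builders used across the suite.

# Horn's quaternion absolute-orientation method: RMSD after optimal rigid
# superposition, independent of the SVD/Kabsch route used by the package.
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  N <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P), 0))
}

# angle at vertex b between vectors b->a and b->c, brute-force acos route
brute_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# brute-force unweighted mean by explicit accumulation
brute_centroid <- function(coords, idx) {
  acc <- c(0, 0, 0)
  for (i in idx) acc <- acc + coords[i, ]
  acc / length(idx)
}

# random proper rotation matrix from a seeded draw
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply one global rigid-body transform to every frame of a trajectory
rigid_transform_trajectory <- function(traj, R, t) {
  xyz <- t(apply(traj$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(m %*% t(R), 2, t, `+`)))
  }))
  as_trajectory(traj$topology, xyz, run_id = traj$run_id)
}

# ad-hoc topology from a compact residue table:
# data.frame(subunit, chain, resno, resid, elety, element, x, y, z)
make_topology <- function(df) {
  atoms <- data.frame(
    atom_index = seq_len(nrow(df)), eleno = seq_len(nrow(df)),
    elety = df$elety, element = df$element, resid = df$resid,
    chain = df$chain, subunit = df$subunit, resno = df$resno,
    stringsAsFactors = FALSE
  )
  tndyn:::new_topology(atoms, xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))))
}

ca_residue <- function(subunit, chain, resno, x, y, z, resid = "ALA") {
  data.frame(subunit = subunit, chain = chain, resno = resno, resid = resid,
             elety = "CA", element = "C", x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# one-frame trajectory around a topology's own coordinates
topo_trajectory <- function(top) {
  as_trajectory(top, matrix(top$xyz, nrow = 1))
}

# small hand-written PDB fixtures -------------------------------------------

pdb_line <- function(serial, name, resid, chain, resno, x, y, z, elem) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resid, chain, resno, x, y, z, elem)
}

write_gly_pdb <- function(path) {
  lines <- c(
    pdb_line(1, "N", "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_line(2, "CA", "GLY", "A", 1, 1.458, 0.0, 0.0, "C"),
    pdb_line(3, "C", "GLY", "A", 1, 2.0, 1.4, 0.0, "C"),
    "END"
  )
  writeLines(lines, path)
  path
}

write_sep_pdb <- function(path) {
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 21, 0, 0, 0, "C"),
    pdb_line(2, "CA", "SEP", "A", 22, 3.8, 0, 0, "C"),
    pdb_line(3, "P", "SEP", "A", 22, 5.0, 1.5, 0, "P"),
    pdb_line(4, "O1P", "SEP", "A", 22, 6.2, 0.8, 0.5, "O"),
    pdb_line(5, "O2P", "SEP", "A", 22, 5.2, 2.9, 0.7, "O"),
    pdb_line(6, "O3P", "SEP", "A", 22, 4.9, 1.8, -1.5, "O"),
    pdb_line(7, "CA", "GLY", "B", 1, 10, 0, 0, "C"),
    pdb_line(8, "CA", "GLY", "C", 1, 20, 0, 0, "C"),
    "END"
  )
  writeLines(lines, path)
  path
}
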