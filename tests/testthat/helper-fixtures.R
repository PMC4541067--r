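# fixtures built in code: tiny charge systems and structure files

# canonical Stark parameters of the anionic GFP chromophore (experimental)
p_vac <- stark_params(4.47, -35, 20725)

# a bare point-charge system (no structure file involved)
point_charges <- function(xyz, q, names = sprintf("Q%d", seq_along(q)),
                          selections = list()) {
  charge_system(
    data.frame(name = names, resname = "ION", resid = 1L, chain = "",
               charge = q),
    list(unname(as.matrix(xyz))), selections = selections)
}

# a 5-atom chromophore chain along +x (CE2 at +x end), plus extra charges
chain_system <- function(extra_xyz = NULL, extra_q = NULL, span = 4,
                         frames = 1L, jitter_fun = NULL) {
  chain_names <- c("CE2", "CD2", "CG2", "CB2", "CA2")
  chain_x <- seq(span / 2, -span / 2, length.out = 5)
  n_extra <- length(extra_q)
  atoms <- data.frame(
    name = c(chain_names, if (n_extra) sprintf("X%d", seq_len(n_extra))),
    resname = c(rep("CRO", 5), rep("ENV", n_extra)),
    resid = c(rep(1L, 5), rep(2L, n_extra)),
    chain = "",
    charge = c(rep(0, 5), extra_q))
  base <- rbind(cbind(chain_x, 0, 0),
                if (n_extra) unname(as.matrix(extra_xyz)))
  dimnames(base) <- NULL
  snaps <- lapply(seq_len(frames), function(k) {
    if (is.null(jitter_fun)) base else jitter_fun(base, k)
  })
  charge_system(atoms, snaps, selections = list(chromophore = 1:5))
}

write_pqr_fixture <- function(path) {
  writeLines(c(
    "REMARK synthetic two-atom fixture",
    "ATOM      1  NA  ION A   1       0.000   0.000   0.000  1.0000 1.0000",
    "ATOM      2  CL  ION A   2       2.000   0.000   0.000 -1.0000 1.5000"
  ), path)
  path
}

# minimal 3-model PDB with two atoms per model (fixed-column format)
write_pdb_fixture <- function(path) {
  atom_line <- function(serial, name, resname, resid, x, y, z) {
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resname, resid, x, y, z)
  }
  lines <- unlist(lapply(1:3, function(m) c(
    sprintf("MODEL     %4d", m),
    atom_line(1, "NA", "ION", 1, 0 + 0.1 * (m - 1), 0, 0),
    atom_line(2, "CL", "ION", 2, 2, 0, 0),
    "ENDMDL")))
  writeLines(lines, path)
  path
}

ion_charge_table <- data.frame(resname = c("ION", "ION"),
                               name = c("NA", "CL"),
                               charge = c(1, -1))

# rigid rotation matrix from an axis-angle (deterministic inputs in tests)
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
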