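# Shared fixture builders. Everything is generated in code; no binary data.

kT300 <- poregate::kT_at(300)

flat_potential <- function(domain = c(-15, 15)) {
  poregate::potential_spec(domain = domain)
}

barrier_potential <- function(height, width = 2, domain = c(-15, 15)) {
  poregate::potential_spec(heights = height, centers = 0, widths = width,
                           domain = domain)
}

# Small synthetic protein: n_res residues with N, CA, C, O backbone atoms
# laid out along a gentle helix, plus deterministic jitter.
toy_protein <- function(n_res = 60, chain = "A", seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_res), function(i) {
    base <- c(10 * cos(i / 3), 10 * sin(i / 3), 1.5 * i)
    offs <- matrix(c(0, 0, 0, 1.2, 0.3, 0.1, 2.1, -0.4, 0.3,
                     2.6, 0.8, -0.5), ncol = 3, byrow = TRUE)
    offs <- offs + matrix(rnorm(12, 0, 0.05), ncol = 3)
    data.frame(element = c("N", "C", "C", "O"),
               x = base[1] + offs[, 1], y = base[2] + offs[, 2],
               z = base[3] + offs[, 3], chain = chain, resno = i,
               resid = "ALA", atom_name = c("N", "CA", "C", "O"))
  })
  poregate::structure_model(do.call(rbind, rows), source = "toy_protein")
}

rigid_transform <- function(model, angle = 0.7, axis = c(0, 0, 1),
                            translation = c(3, -2, 5)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- xyz[, 1] + translation[1]
  model$y <- xyz[, 2] + translation[2]
  model$z <- xyz[, 3] + translation[3]
  model
}

# Minimal 3-atom PDB / mmCIF text fixtures written on the fly.
write_mini_pdb <- function(path, altloc = FALSE) {
  fmt <- "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, 1, " N", " ", "ALA", "A", 1, 1.0, 2.0, 3.0, 1.00, 10.0, "N"),
    sprintf(fmt, 2, " CA", " ", "ALA", "A", 1, 2.5, 2.0, 3.0, 1.00, 10.0, "C"),
    sprintf(fmt, 3, " O", " ", "ALA", "A", 1, 4.0, 2.0, 3.0, 1.00, 10.0, "O")
  )
  if (altloc) {
    lines <- c(lines,
      sprintf(fmt, 4, " CB", "A", "ALA", "A", 1, 5.0, 2.0, 3.0, 0.40, 10.0, "C"),
      sprintf(fmt, 5, " CB", "B", "ALA", "A", 1, 6.0, 2.0, 3.0, 0.60, 10.0, "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_mini_cif <- function(path) {
  writeLines(c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.500 2.000 3.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 O O . ALA A 1 1 ? 4.000 2.000 3.000 1.00 10.00 ? 1 ALA A O 1",
    "#"
  ), path)
  path
}
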