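# Synthetic full-backbone fixtures for hydrogen-bond detection tests.
# Two straight strands 3.3 A apart in donor-acceptor geometry; the number of
# residues whose carbonyl points across the gap controls the H-bond count.

backbone_pair_pdb <- function(file, n_res = 4, hbond_donors = n_res,
                              len_a = n_res, len_b = n_res,
                              start_a = 1, start_b = 21) {
  lines <- character(0)
  serial <- 0
  emit <- function(elety, resno, x, y, z) {
    serial <<- serial + 1
    lines[length(lines) + 1] <<- sprintf(
      "ATOM  %5d %-4s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      serial, paste0(" ", elety), resno, x, y, z,
      substr(elety, 1, 1))
  }
  # strand A along +z at x = 0; O atoms of the first `hbond_donors` residues
  # point toward strand B (x = 1.5), the rest away
  for (i in seq_len(len_a)) {
    z <- (i - 1) * 3.4
    emit("N", start_a + i - 1, -0.3, 0, z - 0.5)
    emit("CA", start_a + i - 1, 0, 0, z)
    emit("C", start_a + i - 1, 0.3, 0, z + 0.5)
    ox <- if (i <= hbond_donors) 1.5 else -1.5
    emit("O", start_a + i - 1, ox, 0, z + 0.5)
  }
  # strand B along -z at x = 4.8; its N accepts from A's O (gap 3.3 A)
  for (i in seq_len(len_b)) {
    z <- (len_b - i) * 3.4
    emit("N", start_b + i - 1, 4.8, 0, z + 0.5)
    emit("CA", start_b + i - 1, 5.1, 0, z)
    emit("C", start_b + i - 1, 4.8, 0, z - 0.5)
    emit("O", start_b + i - 1, 6.3, 0, z - 0.5)
  }
  writeLines(c(lines, "TER", "END"), file)
  file
}

# Extended chain built from internal coordinates (for torsion-based strand
# detection): ideal bond geometry with the requested phi/psi.
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

nerf_place <- function(A, B, C, r, theta, tau) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  th <- theta * pi / 180; ta <- -tau * pi / 180  # sign matches the IUPAC reader
  C + (-r * cos(th)) * bc + (r * sin(th) * cos(ta)) * m +
    (r * sin(th) * sin(ta)) * n
}

extended_chain_pdb <- function(file, n_res = 6, phi = -120, psi = 130) {
  N <- list(c(0, 0, 0))
  CA <- list(c(1.46, 0, 0))
  C <- list(nerf_place(c(0, 1, 0), N[[1]], CA[[1]], 1.52, 111, -60))
  O <- list()
  for (i in seq_len(n_res - 1)) {
    N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]], 1.33, 117, psi)
    O[[i]] <- nerf_place(N[[i]], CA[[i]], C[[i]], 1.23, 121, psi - 180)
    CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]], 1.46, 121, 180)
    C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]], 1.52, 111, phi)
  }
  O[[n_res]] <- nerf_place(N[[n_res]], CA[[n_res]], C[[n_res]], 1.23, 121,
                           psi - 180)
  lines <- character(0); serial <- 0
  emit <- function(elety, resno, p) {
    serial <<- serial + 1
    lines[length(lines) + 1] <<- sprintf(
      "ATOM  %5d %-4s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      serial, paste0(" ", elety), resno, p[1], p[2], p[3],
      substr(elety, 1, 1))
  }
  for (i in seq_len(n_res)) {
    emit("N", i, N[[i]]); emit("CA", i, CA[[i]])
    emit("C", i, C[[i]]); emit("O", i, O[[i]])
  }
  writeLines(c(lines, "TER", "END"), file)
  file
}

# Hand-built pairing graph (bypasses coordinates) for sheet-assembly tests.
toy_graph <- function(n_strands, edges, chain = "A", starts = NULL) {
  if (is.null(starts)) starts <- seq_len(n_strands) * 10
  strands <- data.frame(
    chain = chain, start = starts, end = starts + 4,
    id = seq_len(n_strands),
    dir_x = 0, dir_y = 0, dir_z = 1)
  e <- if (length(edges)) do.call(rbind, lapply(edges, function(ed)
    data.frame(a = ed[[1]], b = ed[[2]], nbonds = 4,
               orientation = if (length(ed) > 2) ed[[3]] else "anti",
               stringsAsFactors = FALSE))) else
    data.frame(a = integer(), b = integer(), nbonds = integer(),
               orientation = character(), stringsAsFactors = FALSE)
  structure(list(strands = strands, edges = e), class = "pairing_graph")
}
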