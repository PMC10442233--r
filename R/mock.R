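# Idealized mock coordinates for a topology. Strands are straight CA traces
# on a planar lattice; each chain connection is routed as a polyline whose
# out-of-plane bow is chosen purely geometrically, by the sign of the triple
# product along the path (positive = right-handed). This makes the generator
# both a fixture factory for sheet extraction and an independent oracle for
# the analytic face conventions in rules.R.

#' Idealized mock coordinates for a topology
#'
#' Builds straight CA strand traces on a planar lattice (default spacing
#' 4.8 A between strands, 3.4 A rise per residue) and routes each connection
#' as a right-handed connector: for each candidate face the triple product
#' of (strand direction, approach, departure) along the path is evaluated
#' and the positive (right-handed) bow is kept. Antiparallel jump-0 hairpins
#' are routed in the sheet edge plane and carry face `"none"`.
#'
#' @param t a [sheet_topology()].
#' @param strand_len residues per strand.
#' @param spacing inter-strand spacing in Angstrom.
#' @param rise rise per residue along a strand in Angstrom.
#' @param face_offset out-of-plane bow of a connector in Angstrom.
#' @return An object of class `mock_coordinates`: list with `atoms` (one CA
#'   per strand residue: `strand`, `resno`, `x`, `y`, `z`), `strands`
#'   (`strand`, `position`, `orient`, `start`, `end`), `connectors`
#'   (`index`, `kind`, `jump`, `face`, `mid_x/y/z`) and the lattice
#'   constants.
#' @examples
#' mock_coordinates(parse_topology("1234:udud"))$connectors$face  # all "none"
#' @export
mock_coordinates <- function(t, strand_len = 5L, spacing = 4.8, rise = 3.4,
                             face_offset = 4.0) {
  stopifnot(inherits(t, "sheet_topology"))
  n <- t$n
  L <- as.integer(strand_len)
  pos <- integer(n)
  pos[t$order] <- seq_len(n)
  gap <- 3L  # unmodeled loop residues between strands in the numbering

  atoms <- do.call(rbind, lapply(seq_len(n), function(s) {
    p <- pos[s]
    up <- t$orient[p] == "u"
    z <- if (up) (seq_len(L) - 1L) * rise else (L - seq_len(L)) * rise
    data.frame(strand = s, resno = (s - 1L) * (L + gap) + seq_len(L),
               x = (p - 1L) * spacing, y = 0, z = z)
  }))
  strands <- data.frame(
    strand = seq_len(n), position = pos, orient = t$orient[pos],
    start = (seq_len(n) - 1L) * (L + gap) + 1L,
    end = (seq_len(n) - 1L) * (L + gap) + L)

  connectors <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    a_res <- atoms[atoms$strand == i, ]
    b_res <- atoms[atoms$strand == i + 1L, ]
    A <- unlist(a_res[nrow(a_res), c("x", "y", "z")])
    B <- unlist(b_res[1L, c("x", "y", "z")])
    dirA <- unlist(a_res[nrow(a_res), c("x", "y", "z")]) -
      unlist(a_res[1L, c("x", "y", "z")])
    dirB <- unlist(b_res[nrow(b_res), c("x", "y", "z")]) -
      unlist(b_res[1L, c("x", "y", "z")])
    para <- sum(dirA * dirB) > 0
    jump <- abs(pos[i + 1L] - pos[i]) - 1L
    if (!para && jump == 0L) {
      edge <- if (A[["z"]] > 0) max(A[["z"]], B[["z"]]) + rise else -rise
      M <- c((A[["x"]] + B[["x"]]) / 2, 0, edge)
      face <- "none"
    } else {
      base <- if (para) (A + B) / 2 else {
        edge <- if (A[["z"]] > 0) max(A[["z"]], B[["z"]]) + rise else -rise
        c((A[["x"]] + B[["x"]]) / 2, 0, edge)
      }
      hand <- function(y) {
        M <- base + c(0, y, 0)
        v <- M - A
        w <- B - M
        det3(dirA, v, w)
      }
      y <- if (hand(face_offset) > 0) face_offset else -face_offset
      stopifnot(hand(y) > 0)  # the routing is chiral by construction
      M <- base + c(0, y, 0)
      face <- if (y > 0) "front" else "back"
    }
    data.frame(index = i, kind = if (para) "para" else "anti", jump = jump,
               face = face, mid_x = M[[1L]], mid_y = M[[2L]], mid_z = M[[3L]],
               stringsAsFactors = FALSE)
  }))

  structure(list(atoms = atoms, strands = strands, connectors = connectors,
                 topology = format_topology(t), strand_len = L,
                 spacing = spacing, rise = rise, face_offset = face_offset),
            class = "mock_coordinates")
}

det3 <- function(u, v, w) {
  u[1L] * (v[2L] * w[3L] - v[3L] * w[2L]) -
    u[2L] * (v[1L] * w[3L] - v[3L] * w[1L]) +
    u[3L] * (v[1L] * w[2L] - v[2L] * w[1L])
}

#' Write mock coordinates as a CA-only PDB file
#'
#' Strand residues only; connector routing is metadata, not atoms. The file
#' parses with [parse_structure()] and, together with the `strands` table of
#' the mock, round-trips through the extraction module back to the source
#' topology.
#'
#' @param mock a [mock_coordinates()] result.
#' @param file output path.
#' @param chain chain identifier.
#' @return `file`, invisibly.
#' @export
write_mock_pdb <- function(mock, file, chain = "A") {
  stopifnot(inherits(mock, "mock_coordinates"))
  at <- mock$atoms
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(at)), chain, at$resno, at$x, at$y, at$z)
  writeLines(c(lines, "TER", "END"), file)
  invisible(file)
}

#' Strand table of a mock, in the extraction module's format
#'
#' @param mock a [mock_coordinates()] result.
#' @param chain chain identifier matching [write_mock_pdb()].
#' @return Data frame `chain`, `start`, `end`.
#' @export
mock_strand_table <- function(mock, chain = "A") {
  data.frame(chain = chain, start = mock$strands$start,
             end = mock$strands$end, stringsAsFactors = FALSE)
}
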