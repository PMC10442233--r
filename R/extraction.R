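# Sheet topology extraction from coordinates. PDB parsing rides on bio3d;
# the strand/pairing/sheet logic implements the open-sheet criteria:
# (1) strands longer than 2 residues, (2) at least 3 strands per sheet,
# (3) neighboring strands joined by at least 2 main-chain hydrogen bonds,
# (4) no insertion of a strand from another sheet in the sequence intervals
# between a sheet's consecutive strands; branched and cyclic (barrel)
# pairing graphs are discarded.

HBOND_DIST_MAX <- 3.5    # N...O distance cut-off, Angstrom
HBOND_ANGLE_MIN <- 100   # CA-N...O angle cut-off, degrees
CA_CONTACT_MAX <- 5.5    # CA-CA rung cut-off for CA-only models, Angstrom

#' Parse a PDB file into a residue-level structure model
#'
#' Reads the first model, prefers altloc `A`, and collects per-residue
#' backbone coordinates (N, CA, C, O where present). CA-only files are
#' accepted with a warning; hydrogen-bond detection is then unavailable and
#' strand pairing falls back to CA contacts.
#'
#' @param file path to a PDB file.
#' @return An object of class `sheet_structure`: list with `residues` (one
#'   row per residue: `chain`, `resno`, backbone coordinates) and
#'   `has_backbone`.
#' @export
parse_structure <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(at) == 0L || !any(at$elety == "CA"))
    fail_validation("file", "no protein chains with CA atoms found")
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, at$ins, sep = "|")
  ord <- !duplicated(key)
  res <- data.frame(chain = at$chain[ord], resno = at$resno[ord],
                    ins = at$ins[ord], stringsAsFactors = FALSE)
  for (el in c("N", "CA", "C", "O")) {
    sel <- at[at$elety == el, , drop = FALSE]
    sel <- sel[!duplicated(paste(sel$chain, sel$resno, sel$ins, sep = "|")), ]
    idx <- match(paste(res$chain, res$resno, res$ins, sep = "|"),
                 paste(sel$chain, sel$resno, sel$ins, sep = "|"))
    low <- tolower(el)
    res[[paste0(low, "_x")]] <- sel$x[idx]
    res[[paste0(low, "_y")]] <- sel$y[idx]
    res[[paste0(low, "_z")]] <- sel$z[idx]
  }
  has_backbone <- mean(!is.na(res$n_x) & !is.na(res$c_x) & !is.na(res$o_x)) > 0.5
  if (!has_backbone)
    warning("CA-only model: hydrogen-bond detection disabled, ",
            "strand pairing will use CA contacts", call. = FALSE)
  structure(list(residues = res, has_backbone = has_backbone),
            class = "sheet_structure")
}

#' Read an external strand-assignment table
#'
#' @param file TSV with columns `chain`, `start`, `end` (inclusive residue
#'   ranges in the file's author numbering).
#' @return Data frame of strand segments.
#' @export
read_strand_table <- function(file) {
  df <- read_tsv(file)
  if (!all(c("chain", "start", "end") %in% names(df)))
    fail_validation("file", "needs columns chain, start, end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Crude torsion-based strand detection: residues in the beta region of the
# Ramachandran map (phi < 0, psi extended), in runs of length >= 3. External
# assignments are the bit-reproducible path; this is a convenience.
detect_strands <- function(model) {
  if (!model$has_backbone)
    fail_validation("model", "internal strand detection needs backbone atoms")
  out <- list()
  res <- model$residues
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, , drop = FALSE]
    r <- r[order(r$resno), , drop = FALSE]
    k <- nrow(r)
    isb <- rep(FALSE, k)
    for (i in seq_len(k)) {
      if (i == 1L || i == k) next
      prev_ok <- r$resno[i - 1L] == r$resno[i] - 1L
      next_ok <- r$resno[i + 1L] == r$resno[i] + 1L
      if (!prev_ok || !next_ok) next
      xyz <- function(j, el) unlist(r[j, paste0(el, c("_x", "_y", "_z"))])
      if (anyNA(c(xyz(i - 1L, "c"), xyz(i, "n"), xyz(i, "ca"), xyz(i, "c"),
                  xyz(i + 1L, "n")))) next
      phi <- dihedral(xyz(i - 1L, "c"), xyz(i, "n"), xyz(i, "ca"), xyz(i, "c"))
      psi <- dihedral(xyz(i, "n"), xyz(i, "ca"), xyz(i, "c"), xyz(i + 1L, "n"))
      isb[i] <- phi < 0 && (psi >= 100 || psi <= -150)
    }
    runs <- rle(isb)
    stop_at <- cumsum(runs$lengths)
    start_at <- stop_at - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      if (runs$values[j] && runs$lengths[j] >= 3L)
        out[[length(out) + 1L]] <- data.frame(
          chain = ch, start = r$resno[start_at[j]], end = r$resno[stop_at[j]],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chain = character(), start = integer(), end = integer())
}

strand_residues <- function(model, chain, start, end) {
  r <- model$residues
  r <- r[r$chain == chain & r$resno >= start & r$resno <= end, , drop = FALSE]
  r[order(r$resno), , drop = FALSE]
}

count_hbonds <- function(ra, rb) {
  count <- 0L
  for (swap in c(FALSE, TRUE)) {
    don <- if (swap) rb else ra
    acc <- if (swap) ra else rb
    for (i in seq_len(nrow(don))) {
      N <- unlist(don[i, c("n_x", "n_y", "n_z")])
      CA <- unlist(don[i, c("ca_x", "ca_y", "ca_z")])
      if (anyNA(N) || anyNA(CA)) next
      for (j in seq_len(nrow(acc))) {
        O <- unlist(acc[j, c("o_x", "o_y", "o_z")])
        if (anyNA(O)) next
        d <- sqrt(sum((N - O)^2))
        if (d > HBOND_DIST_MAX) next
        v1 <- CA - N; v2 <- O - N
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        if (ang >= HBOND_ANGLE_MIN) count <- count + 1L
      }
    }
  }
  count
}

count_ca_contacts <- function(ra, rb) {
  count <- 0L
  for (i in seq_len(nrow(ra))) {
    A <- unlist(ra[i, c("ca_x", "ca_y", "ca_z")])
    if (anyNA(A)) next
    for (j in seq_len(nrow(rb))) {
      B <- unlist(rb[j, c("ca_x", "ca_y", "ca_z")])
      if (anyNA(B)) next
      if (sqrt(sum((A - B)^2)) <= CA_CONTACT_MAX) count <- count + 1L
    }
  }
  count
}

#' Build the strand-pairing graph of a structure
#'
#' Strand segments come from an external assignment table (the reproducible
#' path) or from internal torsion-based detection. Segments of 2 residues or
#' fewer are dropped before graph assembly. Edges join strand pairs with at
#' least 2 main-chain hydrogen bonds (N...O <= 3.5 A, CA-N...O angle >=
#' 100 degrees); for CA-only models, pairs with at least 2 CA-CA rungs
#' within 5.5 A. Each edge carries the relative orientation (sign of the
#' strand direction-vector dot product).
#'
#' @param model a [parse_structure()] result.
#' @param strands optional data frame `chain`, `start`, `end`
#'   (see [read_strand_table()]); detected internally when omitted.
#' @return An object of class `pairing_graph`: list with `strands` (with
#'   direction vectors) and `edges` (`a`, `b`, `nbonds`, `orientation`).
#' @export
build_pairing_graph <- function(model, strands = NULL) {
  stopifnot(inherits(model, "sheet_structure"))
  if (is.null(strands)) strands <- detect_strands(model)
  strands <- strands[strands$end - strands$start + 1L > 2L, , drop = FALSE]
  k <- nrow(strands)
  if (k > 0L) {
    strands$id <- seq_len(k)
    dirs <- matrix(NA_real_, k, 3L)
    for (i in seq_len(k)) {
      r <- strand_residues(model, strands$chain[i], strands$start[i],
                           strands$end[i])
      if (nrow(r) < 3L)
        fail_validation("strands", sprintf(
          "strand %s:%d-%d has %d resolved residues (need > 2)",
          strands$chain[i], strands$start[i], strands$end[i], nrow(r)))
      dirs[i, ] <- unlist(r[nrow(r), c("ca_x", "ca_y", "ca_z")]) -
        unlist(r[1L, c("ca_x", "ca_y", "ca_z")])
    }
    strands$dir_x <- dirs[, 1L]; strands$dir_y <- dirs[, 2L]
    strands$dir_z <- dirs[, 3L]
  }
  edges <- data.frame(a = integer(), b = integer(), nbonds = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ra <- strand_residues(model, strands$chain[i], strands$start[i], strands$end[i])
    rb <- strand_residues(model, strands$chain[j], strands$start[j], strands$end[j])
    nb <- if (model$has_backbone) count_hbonds(ra, rb) else
      count_ca_contacts(ra, rb)
    if (nb >= 2L) {
      dot <- sum(strands[i, c("dir_x", "dir_y", "dir_z")] *
                   strands[j, c("dir_x", "dir_y", "dir_z")])
      edges <- rbind(edges, data.frame(
        a = i, b = j, nbonds = nb,
        orientation = if (dot >= 0) "para" else "anti",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(strands = strands, edges = edges), class = "pairing_graph")
}

#' Assemble open sheets from a pairing graph
#'
#' Keeps connected components that are simple paths of at least 3 strands:
#' components containing a strand with 3 or more neighbors (branched sheets)
#' or a cycle (barrels) are discarded, as are multi-chain components. A
#' sheet is also discarded when a sequence interval between two of its
#' consecutive strands contains a strand belonging to another sheet of more
#' than 2 strands (the no-insertion criterion).
#'
#' @param graph a [build_pairing_graph()] result.
#' @return A list of sheets; each is a data frame of the sheet's strands in
#'   path order with an `edge_orient` attribute (`"para"`/`"anti"` per
#'   adjacent pair).
#' @export
assemble_sheets <- function(graph) {
  stopifnot(inherits(graph, "pairing_graph"))
  k <- nrow(graph$strands)
  if (k == 0L) return(list())
  adj <- vector("list", k)
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[e]; b <- graph$edges$b[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(k)
  paths <- list()
  for (s in seq_len(k)) {
    if (seen[s]) next
    comp <- s; frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), comp)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    deg <- lengths(adj[comp])
    n_edges <- sum(graph$edges$a %in% comp & graph$edges$b %in% comp)
    if (length(comp) < 3L) next
    if (any(deg >= 3L)) next                      # branched
    if (n_edges != length(comp) - 1L) next        # cycle (barrel)
    if (length(unique(graph$strands$chain[comp])) != 1L) next
    end <- comp[which(deg == 1L)[1L]]
    path <- end; cur <- end; prev <- 0L
    while (length(path) < length(comp)) {
      nxt <- setdiff(adj[[cur]], prev)[1L]
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    paths[[length(paths) + 1L]] <- path
  }
  edge_key <- paste(graph$edges$a, graph$edges$b)
  orient_of <- function(a, b) {
    i <- match(paste(min(a, b), max(a, b)), edge_key)
    graph$edges$orientation[i]
  }
  # no-insertion criterion, checked against all other candidate sheets
  keep <- rep(TRUE, length(paths))
  for (i in seq_along(paths)) {
    st <- graph$strands[paths[[i]], ]
    st <- st[order(st$start), ]
    others <- setdiff(seq_along(paths), i)
    for (q in seq_len(nrow(st) - 1L)) {
      lo <- st$end[q]; hi <- st$start[q + 1L]
      for (o in others) {
        ot <- graph$strands[paths[[o]], ]
        if (any(ot$start > lo & ot$end < hi)) keep[i] <- FALSE
      }
    }
  }
  lapply(which(keep), function(i) {
    path <- paths[[i]]
    sheet <- graph$strands[path, , drop = FALSE]
    rownames(sheet) <- NULL
    attr(sheet, "edge_orient") <- vapply(seq_len(length(path) - 1L),
      function(q) orient_of(path[q], path[q + 1L]), character(1L))
    class(sheet) <- c("sheet_path", "data.frame")
    sheet
  })
}

#' Canonical topology of an assembled sheet
#'
#' Strands are numbered by their order along the sequence; sheet positions
#' follow the path order (either traversal direction gives the same result
#' after canonicalization); orientations are propagated along the path from
#' the para/anti edge labels.
#'
#' @param sheet one element of [assemble_sheets()]'s result.
#' @return A canonical [sheet_topology()].
#' @export
sheet_to_topology <- function(sheet) {
  stopifnot(inherits(sheet, "sheet_path"))
  n <- nrow(sheet)
  if (n < 3L) fail_validation("sheet", "need at least 3 strands")
  if (length(unique(sheet$chain)) != 1L)
    fail_validation("sheet", "sheet spans more than one chain")
  eo <- attr(sheet, "edge_orient")
  if (anyNA(eo)) fail_validation("sheet", "missing pairing orientation label")
  seq_rank <- rank(sheet$start)        # strand number along the sequence
  orient <- character(n)
  orient[1L] <- "u"
  for (p in 2:n)
    orient[p] <- if (eo[p - 1L] == "para") orient[p - 1L] else
      if (orient[p - 1L] == "u") "d" else "u"
  canonicalize(sheet_topology(as.integer(seq_rank), orient))
}

#' Extract canonical sheet topologies from a PDB file
#'
#' Convenience wrapper: [parse_structure()], [build_pairing_graph()],
#' [assemble_sheets()], [sheet_to_topology()].
#'
#' @param file PDB path.
#' @param strands optional strand table (data frame or TSV path).
#' @return Character vector of canonical topology strings (possibly empty).
#' @export
extract_topologies <- function(file, strands = NULL) {
  if (is.character(strands)) strands <- read_strand_table(strands)
  model <- parse_structure(file)
  graph <- build_pairing_graph(model, strands)
  sheets <- assemble_sheets(graph)
  vapply(sheets, function(s) format_topology(sheet_to_topology(s)),
         character(1L))
}
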