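# beta-X-beta connection extraction and the frustration rules.
#
# Geometry conventions (fixed once, validated against the mock-coordinate
# oracle and the published three- and four-strand classification counts):
#
# * A connection crosses the "front" or "back" face of the sheet. With
#   positions increasing to the right and "u" strands pointing up, a
#   right-handed connector (parallel crossover, or the right-handed bend of an
#   antiparallel connection with jump >= 1) lies on the BACK face exactly when
#   the departing strand points up and the connection travels rightward, or
#   points down and travels leftward. Antiparallel hairpins (jump 0) turn in
#   the sheet edge plane and have no face.
# * The ending side of a parallel connection -- the face from which its loop
#   enters the second strand -- equals the connection face for even jump
#   distances and the opposite face for odd ones (the crossover gains half a
#   pleat of phase per intervening strand).
#
# Only relative faces matter to the rules; flipping the global front/back
# labels everywhere changes no verdict.

GREEK_KEY_WINDOW_PATTERNS <- c("4123", "3412", "2341", "3214", "2143", "1432")

face_label <- function(kind, travel_right, orient_start_up) {
  if (kind == "anti" && is.na(travel_right)) return("none")
  if (orient_start_up == travel_right) "back" else "front"
}

opposite_face <- function(face) {
  ifelse(face == "front", "back", ifelse(face == "back", "front", "none"))
}

#' Extract the beta-X-beta connections of a topology
#'
#' Every pair of sequence-consecutive strands of the sheet is linked by one
#' chain connection (a beta-X-beta motif, X being whatever backbone lies
#' between them). For strand `i` at position `p_start` and strand `i+1` at
#' `p_end`, the connection is parallel (`para`) when both strands share an
#' orientation and antiparallel (`anti`) otherwise; the jump distance is the
#' number of sheet positions strictly between them.
#'
#' @param t a [sheet_topology()].
#' @return A data frame with one row per connection (`n - 1` rows): `index`,
#'   `strand_from`, `strand_to`, `p_start`, `p_end`, `kind`, `jump`,
#'   `span_lo`, `span_hi`, `face`, `ending_side`.
#' @examples
#' connections_of(parse_topology("1342:uddd"))
#' @export
connections_of <- function(t) {
  stopifnot(inherits(t, "sheet_topology"))
  n <- t$n
  pos <- integer(n)
  pos[t$order] <- seq_len(n)
  up <- t$orient == "u"
  idx <- seq_len(n - 1L)
  ps <- pos[idx]
  pe <- pos[idx + 1L]
  kind <- ifelse(up[ps] == up[pe], "para", "anti")
  jump <- abs(pe - ps) - 1L
  face <- character(n - 1L)
  eside <- character(n - 1L)
  for (i in idx) {
    if (kind[i] == "anti" && jump[i] == 0L) {
      face[i] <- "none"
      eside[i] <- "none"
    } else {
      face[i] <- face_label(kind[i], pe[i] > ps[i], up[ps[i]])
      eside[i] <- if (kind[i] == "para") {
        if (jump[i] %% 2L == 1L) opposite_face(face[i]) else face[i]
      } else "none"
    }
  }
  data.frame(
    index = idx, strand_from = idx, strand_to = idx + 1L,
    p_start = ps, p_end = pe, kind = kind, jump = jump,
    span_lo = pmin(ps, pe), span_hi = pmax(ps, pe),
    face = face, ending_side = eside,
    stringsAsFactors = FALSE
  )
}

#' Face crossed by one connection
#'
#' @param t a [sheet_topology()].
#' @param index connection index in `1..n-1`.
#' @return `"front"`, `"back"`, or `"none"` (antiparallel hairpins).
#' @export
connection_face <- function(t, index) {
  conns <- connections_of(t)
  if (!index %in% conns$index) fail_validation("index", "no such connection")
  conns$face[[index]]
}

#' Ending side of a parallel connection
#'
#' The face from which the connection arrives at its second strand. Defined
#' for parallel connections only; antiparallel connections answer `"none"`.
#'
#' @inheritParams connection_face
#' @return `"front"`, `"back"`, or `"none"`.
#' @export
ending_side <- function(t, index) {
  conns <- connections_of(t)
  if (!index %in% conns$index) fail_validation("index", "no such connection")
  conns$ending_side[[index]]
}

#' Greek-key exemption for an antiparallel jump-2 connection
#'
#' An antiparallel connection with two intervening strands is exempt from the
#' jump-distance rule when it is part of a Greek-key motif: the four-position
#' window it spans is fully antiparallel (alternating orientations) and the
#' four strands, relabeled by their order in the sequence, trace the Greek
#' key or one of its circular permutations (the chain re-started at each
#' strand; reading the window from either end is equivalent).
#'
#' @inheritParams connection_face
#' @return `TRUE` or `FALSE`; always `FALSE` for connections that are not
#'   antiparallel with jump 2.
#' @examples
#' greek_key_exempt(parse_topology("4123:dudu"), 3)  # TRUE
#' @export
greek_key_exempt <- function(t, index) {
  conns <- connections_of(t)
  if (!index %in% conns$index) fail_validation("index", "no such connection")
  c_ <- conns[index, ]
  if (c_$kind != "anti" || c_$jump != 2L) return(FALSE)
  w <- c_$span_lo + 0:3
  up <- t$orient[w] == "u"
  if (!all(up[-1L] != up[-4L])) return(FALSE)
  pattern <- paste0(rank(t$order[w]), collapse = "")
  pattern %in% GREEK_KEY_WINDOW_PATTERNS
}

violation_frame <- function(rule = character(), conn_i = integer(),
                            conn_j = integer()) {
  data.frame(rule = rule, conn_i = as.integer(conn_i),
             conn_j = as.integer(conn_j), stringsAsFactors = FALSE)
}

#' Jump-distance rule
#'
#' Long jumps are disfavored: a parallel connection violates the rule when its
#' jump distance reaches 4, an antiparallel one when it reaches 2, except for
#' antiparallel jump-2 connections covered by the Greek-key exemption
#' ([greek_key_exempt()]).
#'
#' @param t a [sheet_topology()].
#' @return A violation data frame (`rule`, `conn_i`, `conn_j`); `conn_j` is
#'   `NA` for this single-connection rule.
#' @export
check_jump_rule <- function(t) {
  conns <- connections_of(t)
  bad <- integer(0)
  for (i in conns$index) {
    if (conns$kind[i] == "para" && conns$jump[i] >= 4L)
      bad <- c(bad, i)
    if (conns$kind[i] == "anti" && conns$jump[i] >= 2L &&
        !greek_key_exempt(t, i))
      bad <- c(bad, i)
  }
  violation_frame(rep("jump_distance", length(bad)), bad, rep(NA_integer_, length(bad)))
}

# Overlap applicability: two connections clash when both cross the same face
# and either share a strand (consecutive chain links) or one span contains
# the other (the outer connector must pass over the inner one). Same-face
# spans that merely cross are offset parallel diagonals and do not clash;
# hairpins (face "none") never participate.
overlap_pair_applies <- function(a, b) {
  if (a$face == "none" || b$face == "none" || a$face != b$face) return(FALSE)
  if (abs(a$index - b$index) == 1L) return(TRUE)
  (a$span_lo <= b$span_lo && b$span_hi <= a$span_hi) ||
    (b$span_lo <= a$span_lo && a$span_hi <= b$span_hi)
}

#' Connection-overlap rule
#'
#' Two connections on the same sheet face (S-type) are disfavored when they
#' share a strand or when one connection's span nests inside the other's.
#'
#' @param t a [sheet_topology()].
#' @return A violation data frame with one row per offending pair.
#' @export
check_overlap_rule <- function(t) {
  conns <- connections_of(t)
  out <- violation_frame()
  m <- nrow(conns)
  if (m < 2L) return(out)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (overlap_pair_applies(conns[i, ], conns[j, ]))
      out <- rbind(out, violation_frame("overlap", i, j))
  }
  out
}

#' Connection-ending rule
#'
#' For two parallel connections whose second strands occupy adjacent sheet
#' positions with equal orientations, endings on the same face (S-type) are
#' preferred; a pair ending on different faces (D-type) is a violation.
#'
#' @param t a [sheet_topology()].
#' @return A violation data frame with one row per offending pair.
#' @export
check_ending_rule <- function(t) {
  conns <- connections_of(t)
  out <- violation_frame()
  m <- nrow(conns)
  if (m < 2L) return(out)
  up <- t$orient == "u"
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (conns$kind[i] != "para" || conns$kind[j] != "para") next
    if (abs(conns$p_end[i] - conns$p_end[j]) != 1L) next
    if (up[conns$p_end[i]] != up[conns$p_end[j]]) next
    if (conns$ending_side[i] != conns$ending_side[j])
      out <- rbind(out, violation_frame("ending", i, j))
  }
  out
}

#' Classify one topology as frustration-free or frustrated
#'
#' Unions the jump-distance, connection-overlap and connection-ending rule
#' checks. A topology with no violation is frustration-free (a possible
#' fold); violations are never cancelled by other rules. The verdict is
#' invariant across the four symmetry images of the topology.
#'
#' @param t a [sheet_topology()] (canonical or raw).
#' @return An object of class `topology_classification`: list with
#'   `topology`, `violations` (data frame `rule`, `conn_i`, `conn_j`) and
#'   `frustration_free`.
#' @examples
#' classify_topology(parse_topology("1234:udud"))$frustration_free  # TRUE
#' classify_topology(parse_topology("1342:uddd"))$violations
#' @export
classify_topology <- function(t) {
  stopifnot(inherits(t, "sheet_topology"))
  v <- rbind(check_jump_rule(t), check_overlap_rule(t), check_ending_rule(t))
  structure(list(topology = t, violations = v,
                 frustration_free = nrow(v) == 0L),
            class = "topology_classification")
}

#' @export
print.topology_classification <- function(x, ...) {
  cat(sprintf("<classification> %s: %s\n", format_topology(x$topology),
              if (x$frustration_free) "frustration-free" else "frustrated"))
  if (nrow(x$violations) > 0L)
    cat(paste0("  ", violation_strings(x$violations), collapse = "\n"), "\n")
  invisible(x)
}

violation_strings <- function(v) {
  ifelse(is.na(v$conn_j),
         sprintf("%s(%d)", v$rule, v$conn_i),
         sprintf("%s(%d,%d)", v$rule, v$conn_i, v$conn_j))
}
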