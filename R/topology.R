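#' Construct a sheet topology
#'
#' A `sheet_topology` describes an open (non-barrel) beta-sheet abstractly by
#' the order in which the sequence-numbered strands are aligned across the
#' sheet and the up/down orientation of the strand at each sheet position.
#' Positions are numbered 1..n from left to right; `order[p]` is the sequence
#' index of the strand occupying position `p`, and `orient[p]` is the
#' direction ("u" or "d") of that strand.
#'
#' @param order integer permutation of `1:n`; strand sequence index per sheet
#'   position, left to right.
#' @param orient character vector of `"u"`/`"d"` per sheet position
#'   (the arrow glyphs `"↑"`/`"↓"` are accepted and normalized).
#' @return An object of class `sheet_topology` with fields `n`, `order`,
#'   `orient`.
#' @seealso [parse_topology()], [canonicalize()], [enumerate_topologies()]
#' @examples
#' sheet_topology(c(1, 2, 3, 4), c("u", "d", "u", "d"))  # the meander
#' @export
sheet_topology <- function(order, orient) {
  order <- as.integer(order)
  orient <- normalize_orient(orient)
  n <- length(order)
  if (n < 2L) fail_validation("order", "at least 2 strands are required")
  if (anyNA(order) || !setequal(order, seq_len(n)))
    fail_validation("order", sprintf("must be a permutation of 1..%d", n))
  if (length(orient) != n)
    fail_validation("orient", sprintf(
      "length %d does not match %d strands", length(orient), n))
  if (!all(orient %in% c("u", "d")))
    fail_validation("orient", "letters must be 'u' or 'd'")
  structure(list(n = n, order = order, orient = orient),
            class = "sheet_topology")
}

normalize_orient <- function(orient) {
  orient <- as.character(orient)
  orient[orient == "↑"] <- "u"
  orient[orient == "↓"] <- "d"
  orient
}

#' Parse a topology string
#'
#' The string dialect is `<order>:<orient>`, e.g. `"1342:uddd"`: the digits
#' give the strand order across sheet positions and the letters the per-
#' position orientations (`u`p or `d`own). Arrows are accepted on input.
#'
#' @param text a single topology string.
#' @return A [sheet_topology()].
#' @examples
#' parse_topology("1234:udud")
#' format_topology(parse_topology("1342:uddd"))
#' @export
parse_topology <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    fail_validation("text", "must be a single topology string")
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    fail_validation("text", "expected '<digits>:<u/d letters>'")
  digits <- strsplit(parts[[1L]], "")[[1L]]
  if (!all(grepl("^[0-9]$", digits)))
    fail_validation("order", "order part must be digits")
  order <- as.integer(digits)
  n <- length(order)
  if (n < 3L || n > 9L)
    fail_validation("order", sprintf("%d strands outside supported 3..9", n))
  orient <- normalize_orient(strsplit(parts[[2L]], "")[[1L]])
  if (length(orient) != n)
    fail_validation("orient", sprintf(
      "length %d does not match %d strands", length(orient), n))
  sheet_topology(order, orient)
}

#' Format a sheet topology as a topology string
#'
#' @param t a [sheet_topology()].
#' @return The `"order:orient"` string; `format(parse_topology(x))`
#'   round-trips exactly.
#' @export
format_topology <- function(t) {
  stopifnot(inherits(t, "sheet_topology"))
  paste0(paste0(t$order, collapse = ""), ":", paste0(t$orient, collapse = ""))
}

#' @export
format.sheet_topology <- function(x, ...) format_topology(x)

#' @export
print.sheet_topology <- function(x, ...) {
  cat(sprintf("<sheet_topology> %s  (n = %d)\n", format_topology(x), x$n))
  invisible(x)
}

#' @export
as.character.sheet_topology <- function(x, ...) format_topology(x)

#' Symmetry images of a topology
#'
#' The same physical sheet can be written on the position grid in four ways,
#' related by the three 180-degree rigid rotations of the sheet: `Rz`
#' reverses the positions (left-right), `Rx` flips every strand orientation
#' (top-bottom), and `Ry = Rz Rx` does both. Mirror reflections are excluded:
#' they invert the chirality on which the connection rules rest, so
#' enantiomeric sheets are distinct objects.
#'
#' @param t a [sheet_topology()].
#' @return A named list of 4 `sheet_topology` objects
#'   (`identity`, `Rz`, `Rx`, `Ry`); always 4 distinct images since strand
#'   labels are distinct.
#' @export
symmetry_images <- function(t) {
  stopifnot(inherits(t, "sheet_topology"))
  flip <- function(o) c("u" = "d", "d" = "u")[o]
  list(
    identity = t,
    Rz = sheet_topology(rev(t$order), rev(t$orient)),
    Rx = sheet_topology(t$order, unname(flip(t$orient))),
    Ry = sheet_topology(rev(t$order), unname(flip(rev(t$orient))))
  )
}

#' Canonical form of a topology
#'
#' Returns the lexicographically smallest of the four symmetry images,
#' comparing the order vector first and then the orientation vector with
#' `u < d`. The result is idempotent and constant on each symmetry orbit,
#' making it the unique representative used by [enumerate_topologies()] and
#' for aggregation keys. Because strand labels are distinct, the minimum
#' reduces to two local choices: reverse the positions if `order[1] >
#' order[n]`, then flip all orientations if `orient[1] == "d"`.
#'
#' @param t a [sheet_topology()].
#' @return The canonical `sheet_topology` of the orbit of `t`.
#' @examples
#' format_topology(canonicalize(parse_topology("4321:uuuu")))  # "1234:uuuu"
#' @export
canonicalize <- function(t) {
  stopifnot(inherits(t, "sheet_topology"))
  order <- t$order
  orient <- t$orient
  if (order[1L] > order[t$n]) {
    order <- rev(order)
    orient <- rev(orient)
  }
  if (orient[1L] == "d")
    orient <- unname(c("u" = "d", "d" = "u")[orient])
  sheet_topology(order, orient)
}

canonical_string <- function(text) format_topology(canonicalize(parse_topology(text)))

is_canonical <- function(t) identical(format_topology(canonicalize(t)), format_topology(t))

#' Convert per-strand orientations to per-position orientations
#'
#' Orientation vectors in this package are indexed by sheet position (left to
#' right). Input that lists the direction of each strand by its sequence
#' number can be converted with this helper.
#'
#' @param order integer permutation; strand per position.
#' @param strand_orient character `"u"`/`"d"` per strand (sequence index).
#' @return Orientation vector indexed by position, usable with
#'   [sheet_topology()].
#' @export
orient_by_position <- function(order, strand_orient) {
  strand_orient <- normalize_orient(strand_orient)
  if (length(strand_orient) != length(order))
    fail_validation("strand_orient", "length must match order")
  strand_orient[as.integer(order)]
}

#' Enumerate all canonical open-sheet topologies
#'
#' All `n! * 2^n` raw (order, orientation) grids collapse under the three
#' rigid rotations of the sheet into exactly `n! * 2^(n-2)` symmetry-distinct
#' topologies. The canonical representatives are precisely the grids with
#' `order[1] < order[n]` and `orient[1] == "u"`, enumerated here in the
#' canonical total order (order tuple, then orientations with `u < d`).
#'
#' @param n strand count; 3..8 supported, larger values work but emit a
#'   warning (the table grows as `n! * 2^(n-2)`).
#' @return A data frame with columns `topology`, `n`, `order`, `orient`,
#'   one row per canonical topology, sorted.
#' @examples
#' nrow(enumerate_topologies(4))  # 96
#' @export
enumerate_topologies <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) fail_validation("n", "need at least 2 strands")
  if (n > 8L) warning(sprintf("n = %d is beyond the supported 3..8 range; ",
                              n), "expect a very large table")
  P <- perms_lex(n)
  P <- P[P[, 1L] < P[, n], , drop = FALSE]
  ostr <- orient_strings(n)
  pstr <- apply(P, 1L, paste0, collapse = "")
  data.frame(
    topology = paste0(rep(pstr, each = length(ostr)), ":",
                      rep.int(ostr, length(pstr))),
    n = n,
    order = rep(pstr, each = length(ostr)),
    orient = rep.int(ostr, length(pstr)),
    stringsAsFactors = FALSE
  )
}

#' Write an enumeration (or any topology table) to TSV
#'
#' @param df data frame from [enumerate_topologies()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_topology_tsv <- function(df, file) {
  stopifnot(all(c("topology", "n", "order", "orient") %in% names(df)))
  write_tsv(df[, c("topology", "n", "order", "orient")], file)
  invisible(file)
}
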