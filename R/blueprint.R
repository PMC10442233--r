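# Design blueprints: per-residue secondary structure (H/E/L) plus ABEGO
# torsion letters compiled from a topology. Parallel connections carry their
# X region as a helix; antiparallel jump-0 connections become beta-hairpins;
# antiparallel connections with jump >= 1 get a helix or, optionally, an
# alpha-turn (helix-loop-helix). The allowed loop ABEGO patterns per
# connection unit are fixed; the first entry of each set is the default.

LOOP_PATTERNS <- list(
  "para-alphabeta" = c("GB", "GBA", "BAAB", "GABA", "BA"),  # helix -> strand
  "para-betaalpha" = c("AB"),                               # strand -> helix
  "anti-alphabeta" = c("GBB"),
  "anti-betaalpha" = c("BAB", "GBB", "AAAB"),
  "betabeta-R"     = c("BAAGB"),                            # R-chirality hairpin
  "betabeta-L"     = c("GG")
)

ALPHA_TURN_LOOP <- "GBB"  # helix-to-helix connector inside an alpha-turn

#' Allowed loop ABEGO patterns for a connection unit
#'
#' @param unit one of `"para-alphabeta"`, `"para-betaalpha"`,
#'   `"anti-alphabeta"`, `"anti-betaalpha"`, `"betabeta-R"`, `"betabeta-L"`.
#' @return Character vector of allowed ABEGO strings; the first element is
#'   the deterministic default used by [build_blueprint()].
#' @examples
#' loop_pattern_for("para-betaalpha")  # "AB"
#' @export
loop_pattern_for <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L ||
      is.na(match(unit, names(LOOP_PATTERNS))))
    fail_validation("unit", sprintf(
      "unknown unit '%s'; expected one of %s", as.character(unit)[1L],
      paste(names(LOOP_PATTERNS), collapse = ", ")))
  LOOP_PATTERNS[[unit]]
}

bp_element <- function(ss, abego) {
  data.frame(ss = rep(ss, nchar(abego)),
             abego = strsplit(abego, "")[[1L]],
             stringsAsFactors = FALSE)
}

bp_strand <- function(len) data.frame(ss = rep("E", len), abego = rep("B", len),
                                      stringsAsFactors = FALSE)
bp_helix <- function(len) data.frame(ss = rep("H", len), abego = rep("A", len),
                                     stringsAsFactors = FALSE)
bp_loop <- function(pattern) bp_element("L", pattern)

check_length <- function(value, lo, hi, what) {
  if (value < lo || value > hi)
    warning(sprintf("%s length %d outside the usual %d..%d range",
                    what, value, lo, hi), call. = FALSE)
  value
}

#' Compile a topology into a design blueprint
#'
#' Lays the chain out as strand-connector-...-strand. Strand lengths default
#' to 5 residues (usual range 4..7) and helix lengths to 13 (usual 11..17);
#' values outside those ranges warn but are accepted. Loop patterns come from
#' [loop_pattern_for()] defaults unless overridden per connection.
#'
#' @param t a [sheet_topology()].
#' @param strand_len strand length in residues (scalar or per-strand vector).
#' @param helix_len helix length in residues.
#' @param hairpin_chirality `"R"` (default, BAAGB loop) or `"L"` (GG) for
#'   antiparallel jump-0 hairpins; scalar or one per connection.
#' @param alpha_turn build a helix-loop-helix alpha-turn (GBB connector) in
#'   the X region of antiparallel connections with jump >= 1 instead of a
#'   single helix.
#' @param terminal_helices append helices (with default loops) to both
#'   termini.
#' @param loop_overrides optional named list `connection index -> ABEGO
#'   string`; the string must belong to the allowed set of that connection's
#'   unit type.
#' @return An object of class `blueprint`: data frame with one row per
#'   residue (`index`, `residue`, `ss`, `abego`) plus attributes `topology`
#'   and `elements`.
#' @examples
#' bp <- build_blueprint(parse_topology("1234:udud"))
#' nrow(bp)  # 4 strands x 5 residues + 3 BAAGB hairpin loops = 35
#' @export
build_blueprint <- function(t, strand_len = 5L, helix_len = 13L,
                            hairpin_chirality = "R", alpha_turn = FALSE,
                            terminal_helices = FALSE, loop_overrides = NULL) {
  stopifnot(inherits(t, "sheet_topology"))
  conns <- connections_of(t)
  m <- nrow(conns)
  strand_len <- rep_len(as.integer(strand_len), t$n)
  for (L in unique(strand_len)) check_length(L, 4L, 7L, "strand")
  helix_len <- check_length(as.integer(helix_len), 11L, 17L, "helix")
  chir <- rep_len(hairpin_chirality, m)
  if (!all(chir %in% c("R", "L")))
    fail_validation("hairpin_chirality", "must be 'R' or 'L'")

  # An override keyed by connection index applies to whichever of that
  # connection's loops accepts the pattern; an override no loop accepts is an
  # error (checked after the layout is built).
  override_used <- new.env(parent = emptyenv())
  pick_loop <- function(i, unit) {
    allowed <- loop_pattern_for(unit)
    key <- as.character(i)
    o <- loop_overrides[[key]]
    if (!is.null(o) && !isTRUE(override_used[[key]]) && o %in% allowed) {
      override_used[[key]] <- TRUE
      return(o)
    }
    allowed[[1L]]
  }

  parts <- list()
  add <- function(x) parts[[length(parts) + 1L]] <<- x
  if (terminal_helices) {
    add(bp_helix(helix_len))
    add(bp_loop(pick_loop("nterm", "para-alphabeta")))
  }
  for (s in seq_len(t$n)) {
    add(bp_strand(strand_len[s]))
    if (s > m) break
    kind <- conns$kind[s]
    if (kind == "para") {
      add(bp_loop(pick_loop(s, "para-betaalpha")))
      add(bp_helix(helix_len))
      add(bp_loop(pick_loop(s, "para-alphabeta")))
    } else if (conns$jump[s] == 0L) {
      add(bp_loop(if (chir[s] == "R") LOOP_PATTERNS[["betabeta-R"]][[1L]]
                  else LOOP_PATTERNS[["betabeta-L"]][[1L]]))
    } else {
      add(bp_loop(pick_loop(s, "anti-betaalpha")))
      add(bp_helix(helix_len))
      if (alpha_turn) {
        add(bp_loop(ALPHA_TURN_LOOP))
        add(bp_helix(helix_len))
      }
      add(bp_loop(pick_loop(s, "anti-alphabeta")))
    }
  }
  if (terminal_helices) {
    add(bp_loop(pick_loop("cterm", "para-betaalpha")))
    add(bp_helix(helix_len))
  }
  unused <- setdiff(names(loop_overrides), ls(override_used))
  if (length(unused))
    fail_validation("loop_overrides", sprintf(
      "pattern '%s' not allowed for any loop of connection %s",
      loop_overrides[[unused[[1L]]]], unused[[1L]]))
  bp <- do.call(rbind, parts)
  bp <- data.frame(index = seq_len(nrow(bp)), residue = "V",
                   ss = bp$ss, abego = bp$abego, stringsAsFactors = FALSE)
  attr(bp, "topology") <- format_topology(t)
  class(bp) <- c("blueprint", "data.frame")
  bp
}

#' Write a blueprint file
#'
#' One line per residue: `index residue SS+ABEGO R` (e.g. `7 V HA R` for a
#' helix residue, `1 V EB R` for a strand residue). Round-trips exactly
#' through [read_blueprint()].
#'
#' @param bp a [build_blueprint()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_blueprint <- function(bp, file) {
  stopifnot(inherits(bp, "blueprint"))
  lines <- sprintf("%d  %s  %s%s  R", bp$index, bp$residue, bp$ss, bp$abego)
  writeLines(lines, file)
  invisible(file)
}

#' Read a blueprint file
#'
#' @param file path written by [write_blueprint()].
#' @return A `blueprint` data frame (without the source-topology attribute).
#' @export
read_blueprint <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(fields, length, integer(1L)) != 4L)
  if (length(bad))
    fail_validation("file", sprintf("line %d: expected 4 fields", bad[1L]))
  ssab <- vapply(fields, `[[`, character(1L), 3L)
  bp <- data.frame(
    index = as.integer(vapply(fields, `[[`, character(1L), 1L)),
    residue = vapply(fields, `[[`, character(1L), 2L),
    ss = substr(ssab, 1L, 1L),
    abego = substr(ssab, 2L, 2L),
    stringsAsFactors = FALSE)
  class(bp) <- c("blueprint", "data.frame")
  bp
}
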