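# Observation frequencies over an ECOD-style Family/Homology hierarchy.
#
# A domain table lists protein domains with their family and homology group
# (homology ~ superfamily) and the canonical topology of their qualifying
# sheet, if any. The occupation ratio of a topology in one homology group is
# the mean over the group's families of the fraction of family domains
# carrying the topology; the observation frequency is the sum of occupation
# ratios across homology groups. Topologies below a threshold frequency
# (default the rational 1/4, compared strictly) count as unobserved.

DOMAIN_TABLE_COLUMNS <- c("domain_id", "homology_id", "family_id", "topology")

#' Read and validate a domain table
#'
#' Expects a TSV with header `domain_id homology_id family_id topology`.
#' Topology strings are canonicalized on ingest so that symmetry images of
#' the same sheet aggregate under one key; an empty topology field marks a
#' domain without a qualifying sheet. A domain may appear in several rows
#' with distinct topologies (multiple qualifying sheets); exact
#' `(domain_id, topology)` duplicates are rejected, as is a `family_id`
#' listed under two homology groups.
#'
#' @param file path to the TSV.
#' @return A validated data frame (class `observation_table`) with the four
#'   columns above, topologies canonical.
#' @export
read_domain_table <- function(file) {
  df <- read_tsv(file)
  missing <- setdiff(DOMAIN_TABLE_COLUMNS, names(df))
  if (length(missing))
    fail_validation("file", paste("missing columns:",
                                  paste(missing, collapse = ", ")))
  df <- df[, DOMAIN_TABLE_COLUMNS]
  df$topology[is.na(df$topology)] <- ""
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$topology[i])) next
    df$topology[i] <- tryCatch(canonical_string(df$topology[i]),
      sheetfolds_validation_error = function(e)
        fail_validation("topology", sprintf("row %d: %s", i, conditionMessage(e))))
  }
  dup <- duplicated(df[, c("domain_id", "topology")])
  if (any(dup))
    fail_validation("domain_id", sprintf(
      "row %d: duplicate (domain_id, topology) pair '%s'",
      which(dup)[1L], df$domain_id[which(dup)[1L]]))
  fam2hom <- unique(df[, c("family_id", "homology_id")])
  bad <- fam2hom$family_id[duplicated(fam2hom$family_id)]
  if (length(bad))
    fail_validation("family_id", sprintf(
      "family '%s' appears under more than one homology group", bad[1L]))
  class(df) <- c("observation_table", "data.frame")
  df
}

as_observation_table <- function(df) {
  stopifnot(all(DOMAIN_TABLE_COLUMNS %in% names(df)))
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Occupation ratio of a topology in one homology group
#'
#' For the records of a single homology group, computes the mean over its
#' family groups of the fraction of each family's domains whose canonical
#' topology equals the query.
#'
#' @param records rows of a domain table belonging to one homology group.
#' @param topology topology string (canonicalized internally).
#' @return A ratio in `[0, 1]`.
#' @examples
#' tab <- make_domain_table_fixture(data.frame(
#'   topology = "1234:udud", homologies = 1, families = 2, fraction = "1,1/2"))
#' occupation_ratio(tab, "1234:udud")  # (1 + 0.5) / 2 = 0.75
#' @export
occupation_ratio <- function(records, topology) {
  if (nrow(records) == 0L) fail_validation("records", "empty homology group")
  if (length(unique(records$homology_id)) != 1L)
    fail_validation("records", "records span more than one homology group")
  key <- canonical_string(topology)
  fams <- split(records, records$family_id)
  mean(vapply(fams, function(f) {
    doms <- split(f$topology, f$domain_id)
    mean(vapply(doms, function(tp) any(tp == key), logical(1L)))
  }, numeric(1L)))
}

#' Observation frequency of a topology
#'
#' Sum of the occupation ratios of the topology across all homology groups of
#' the table.
#'
#' @param table an `observation_table` (see [read_domain_table()]).
#' @param topology topology string.
#' @return Non-negative frequency (0 for an empty table).
#' @export
observation_frequency <- function(table, topology) {
  if (is.null(table) || nrow(table) == 0L) return(0)
  groups <- split(as.data.frame(table), table$homology_id)
  sum(vapply(groups, occupation_ratio, numeric(1L), topology = topology))
}

#' Observed/unobserved label for a frequency
#'
#' @param frequency numeric vector of observation frequencies.
#' @param threshold strict cut-off; frequencies `< threshold` are unobserved.
#'   Defaults to the rational 1/4.
#' @return Character vector `"observed"`/`"unobserved"`.
#' @export
label_observed <- function(frequency, threshold = 1 / 4) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    fail_validation("threshold", "must be a single non-negative number")
  ifelse(frequency < threshold, "unobserved", "observed")
}

parse_threshold <- function(text) {
  if (is.numeric(text)) return(text)
  if (grepl("^\\s*\\d+\\s*/\\s*\\d+\\s*$", text)) {
    parts <- as.numeric(strsplit(text, "/", fixed = TRUE)[[1L]])
    return(parts[1L] / parts[2L])
  }
  out <- suppressWarnings(as.numeric(text))
  if (is.na(out)) fail_validation("threshold", sprintf("cannot parse '%s'", text))
  out
}

#' Observation frequencies for a set of topologies
#'
#' @param table an `observation_table` (may be `NULL` or empty).
#' @param topologies character vector of topology strings.
#' @param threshold see [label_observed()].
#' @return Data frame `topology` (canonical), `frequency`, `status`.
#' @export
observation_frequencies <- function(table, topologies, threshold = 1 / 4) {
  keys <- vapply(topologies, canonical_string, character(1L), USE.NAMES = FALSE)
  freq <- vapply(keys, function(k) observation_frequency(table, k),
                 numeric(1L), USE.NAMES = FALSE)
  data.frame(topology = keys, frequency = freq,
             status = label_observed(freq, threshold),
             stringsAsFactors = FALSE)
}

#' Predict novel folds
#'
#' Nominates the candidate novel folds for an `n`-stranded sheet: the
#' topologies that are frustration-free under the connection rules yet
#' unobserved (observation frequency strictly below the threshold) in the
#' supplied domain table. With no table, every frustration-free topology is
#' returned.
#'
#' @param n strand count.
#' @param table an `observation_table`, or `NULL`.
#' @param threshold see [label_observed()].
#' @return Data frame `topology`, `frequency`, `status`, `frustration_free`
#'   restricted to frustration-free, unobserved topologies, sorted by
#'   frequency then topology.
#' @export
predict_novel_folds <- function(n, table = NULL, threshold = 1 / 4) {
  cls <- classify_all(n, detail = FALSE)
  free <- cls$topology[cls$frustration_free]
  res <- observation_frequencies(table, free, threshold)
  res$frustration_free <- TRUE
  res <- res[res$status == "unobserved", , drop = FALSE]
  res <- res[order(res$frequency, res$topology), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Score all topologies of a fold space against a domain table
#'
#' @inheritParams predict_novel_folds
#' @return Data frame `topology`, `frequency`, `status`, `frustration_free`
#'   for every canonical topology with `n` strands.
#' @export
score_observed <- function(n, table = NULL, threshold = 1 / 4) {
  cls <- classify_all(n, detail = FALSE)
  res <- observation_frequencies(table, cls$topology, threshold)
  res$frustration_free <- cls$frustration_free
  res
}

#' Write a frequency table to TSV
#'
#' @param df data frame from [score_observed()] or [predict_novel_folds()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_frequency_tsv <- function(df, file) {
  cols <- intersect(c("topology", "frequency", "status", "frustration_free"),
                    names(df))
  write_tsv(df[, cols], file)
  invisible(file)
}
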