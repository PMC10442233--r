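# Synthetic domain-table construction. Stands in for an ECOD snapshot in
# tests and examples: the generated table realizes requested occupation
# ratios and observation frequencies exactly, by construction.

parse_fraction <- function(text) {
  if (is.numeric(text)) return(text)
  vapply(strsplit(as.character(text), ",", fixed = TRUE)[[1L]],
         parse_threshold, numeric(1L), USE.NAMES = FALSE)
}

# Smallest denominator q <= 64 with fraction * q integral.
fraction_counts <- function(fraction) {
  for (q in 1:64) {
    p <- fraction * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  fail_validation("fraction", sprintf(
    "%g has no exact denominator up to 64", fraction))
}

#' Build a deterministic synthetic domain table
#'
#' Each spec row requests that a topology appear in `homologies` homology
#' groups, each with `families` family groups, where family `j` has the
#' match fraction given by the (recycled) comma-separated `fraction` list.
#' Non-matching domains carry an empty topology. Domain counts per family are
#' the smallest realizing the fraction exactly, so occupation ratios and
#' observation frequencies of the result equal the requested values by
#' construction.
#'
#' @param spec data frame with columns `topology`, `homologies`, `families`,
#'   `fraction` (numeric, or strings like `"1,1/2"`). An empty spec yields a
#'   valid empty table.
#' @param seed integer; fixes the (cosmetic) shuffling of row order so the
#'   table is reproducible yet not sorted by construction group.
#' @return An `observation_table` data frame.
#' @examples
#' tab <- make_domain_table_fixture(data.frame(
#'   topology = "1234:udud", homologies = 1, families = 2, fraction = "1,1/2"))
#' observation_frequency(tab, "1234:udud")  # 0.75
#' @export
make_domain_table_fixture <- function(spec, seed = 1L) {
  cols <- c("topology", "homologies", "families", "fraction")
  if (nrow(spec) > 0L && !all(cols %in% names(spec)))
    fail_validation("spec", paste("needs columns:", paste(cols, collapse = ", ")))
  rows <- list()
  dom <- 0L
  for (k in seq_len(nrow(spec))) {
    topo <- canonical_string(spec$topology[k])
    fracs <- parse_fraction(spec$fraction[k])
    if (any(fracs < 0 | fracs > 1))
      fail_validation("fraction", sprintf("row %d: fractions must lie in [0,1]", k))
    for (h in seq_len(as.integer(spec$homologies[k]))) {
      hid <- sprintf("H%03d.%d", k, h)
      for (f in seq_len(as.integer(spec$families[k]))) {
        frac <- fracs[(f - 1L) %% length(fracs) + 1L]
        pq <- fraction_counts(frac)
        tp <- c(rep(topo, pq[1L]), rep("", pq[2L] - pq[1L]))
        ids <- sprintf("D%06d", dom + seq_along(tp))
        dom <- dom + length(tp)
        rows[[length(rows) + 1L]] <- data.frame(
          domain_id = ids, homology_id = hid,
          family_id = sprintf("%s.F%d", hid, f), topology = tp,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain_id = character(), homology_id = character(),
               family_id = character(), topology = character(),
               stringsAsFactors = FALSE)
  if (nrow(out) > 1L) out <- shuffle_rows(out, seed)
  rownames(out) <- NULL
  as_observation_table(out)
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

shuffle_rows <- function(df, seed) {
  idx <- sample_with_seed(nrow(df), seed)
  df[idx, , drop = FALSE]
}

# Local-seed sampling that leaves the global RNG stream untouched.
sample_with_seed <- function(n, seed) {
  had <- .Random.seed_exists()
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (.Random.seed_exists())
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(n)
}
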