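# Whole-fold-space classification. The per-topology functions in rules.R are
# the readable reference; this file re-expresses the same rules as vectorized
# arithmetic over blocks of topologies so that the full eight-strand space
# (2,580,480 topologies) classifies in minutes. Agreement between the two
# paths is enforced by tests.

# Classify a block of raw grids. P: k x n permutation matrix (strand per
# position); V: r x n logical orientation matrix (TRUE = up). All k * r
# combinations are classified; returns integer matrix (k*r) x 3 of violation
# counts (jump, overlap, ending), rows ordered perm-major.
classify_block <- function(P, V) {
  n <- ncol(P)
  k <- nrow(P)
  r <- nrow(V)
  N <- k * r
  m <- n - 1L

  posP <- matrix(0L, k, n)
  for (p in seq_len(n)) posP[cbind(seq_len(k), P[, p])] <- p
  rowp <- rep(seq_len(k), each = r)
  rowv <- rep.int(seq_len(r), k)

  PS <- matrix(0L, N, m); PE <- matrix(0L, N, m)
  PARA <- matrix(FALSE, N, m); JUMP <- matrix(0L, N, m)
  FACE <- matrix(0L, N, m)    # 0 none, 1 front, 2 back
  ESIDE <- matrix(0L, N, m)
  for (i in seq_len(m)) {
    ps <- posP[rowp, i]
    pe <- posP[rowp, i + 1L]
    os <- V[cbind(rowv, ps)]
    oe <- V[cbind(rowv, pe)]
    para <- os == oe
    jump <- abs(pe - ps) - 1L
    hairpin <- !para & jump == 0L
    back <- os == (pe > ps)
    face <- ifelse(hairpin, 0L, ifelse(back, 2L, 1L))
    PS[, i] <- ps; PE[, i] <- pe
    PARA[, i] <- para; JUMP[, i] <- jump; FACE[, i] <- face
    ESIDE[, i] <- ifelse(para & jump %% 2L == 1L, 3L - face, face)
  }

  vjump <- integer(N); vover <- integer(N); vend <- integer(N)
  for (i in seq_len(m)) {
    viol <- (PARA[, i] & JUMP[, i] >= 4L)
    anti2 <- !PARA[, i] & JUMP[, i] >= 2L
    if (any(anti2)) {
      exempt <- logical(N)
      cand <- which(!PARA[, i] & JUMP[, i] == 2L)
      if (length(cand)) {
        w0 <- pmin(PS[cand, i], PE[cand, i])
        o1 <- V[cbind(rowv[cand], w0)]
        o2 <- V[cbind(rowv[cand], w0 + 1L)]
        o3 <- V[cbind(rowv[cand], w0 + 2L)]
        o4 <- V[cbind(rowv[cand], w0 + 3L)]
        alt <- (o1 != o2) & (o2 != o3) & (o3 != o4)
        s1 <- P[cbind(rowp[cand], w0)]
        s2 <- P[cbind(rowp[cand], w0 + 1L)]
        s3 <- P[cbind(rowp[cand], w0 + 2L)]
        s4 <- P[cbind(rowp[cand], w0 + 3L)]
        r1 <- 1L + (s1 > s2) + (s1 > s3) + (s1 > s4)
        r2 <- 1L + (s2 > s1) + (s2 > s3) + (s2 > s4)
        r3 <- 1L + (s3 > s1) + (s3 > s2) + (s3 > s4)
        r4 <- 1L + (s4 > s1) + (s4 > s2) + (s4 > s3)
        code <- r1 * 1000L + r2 * 100L + r3 * 10L + r4
        exempt[cand] <- alt &
          code %in% c(4123L, 3412L, 2341L, 3214L, 2143L, 1432L)
      }
      viol <- viol | (anti2 & !exempt)
    }
    vjump <- vjump + viol
  }

  if (m >= 2L) {
    LO <- pmin(PS, PE); HI <- pmax(PS, PE)
    up_end <- matrix(FALSE, N, m)
    for (i in seq_len(m)) up_end[, i] <- V[cbind(rowv, PE[, i])]
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      sameface <- FACE[, i] != 0L & FACE[, i] == FACE[, j]
      nested <- (LO[, i] <= LO[, j] & HI[, j] <= HI[, i]) |
                (LO[, j] <= LO[, i] & HI[, i] <= HI[, j])
      vover <- vover + (sameface & (j == i + 1L | nested))
      vend <- vend + (PARA[, i] & PARA[, j] &
                        abs(PE[, i] - PE[, j]) == 1L &
                        up_end[, i] == up_end[, j] &
                        ESIDE[, i] != ESIDE[, j])
    }
  }
  cbind(jump = vjump, overlap = vover, ending = vend)
}

#' Classify every canonical topology with a given strand count
#'
#' Runs the jump-distance, connection-overlap and connection-ending rules over
#' the full enumerated fold space for `n` strands.
#'
#' @param n strand count (3..8; larger values work but are expensive).
#' @param detail if `TRUE` (default for `n <= 5`), include a `violations`
#'   column listing each violation as `rule(conn_i[,conn_j])`, joined with
#'   semicolons. Building the strings dominates runtime for large `n`.
#' @return A data frame with one row per canonical topology: `topology`, `n`,
#'   `frustration_free`, per-rule violation counts (`jump`, `overlap`,
#'   `ending`) and, with `detail`, `violations`.
#' @examples
#' cls <- classify_all(4)
#' table(cls$frustration_free)  # 53 frustrated, 43 frustration-free
#' @export
classify_all <- function(n, detail = n <= 5L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) fail_validation("n", "need at least 3 strands")
  P <- perms_lex(n)
  P <- P[P[, 1L] < P[, n], , drop = FALSE]
  V <- orient_logical(n)
  ostr <- orient_strings(n)

  block_rows <- max(1L, min(nrow(P), 250000L %/% nrow(V)))
  starts <- seq(1L, nrow(P), by = block_rows)
  counts <- do.call(rbind, lapply(starts, function(s) {
    e <- min(s + block_rows - 1L, nrow(P))
    classify_block(P[s:e, , drop = FALSE], V)
  }))

  pstr <- apply(P, 1L, paste0, collapse = "")
  out <- data.frame(
    topology = paste0(rep(pstr, each = length(ostr)), ":",
                      rep.int(ostr, length(pstr))),
    n = n,
    frustration_free = rowSums(counts) == 0L,
    jump = counts[, "jump"], overlap = counts[, "overlap"],
    ending = counts[, "ending"],
    stringsAsFactors = FALSE
  )
  if (detail) {
    out$violations <- vapply(seq_len(nrow(out)), function(i) {
      if (out$frustration_free[i]) return("")
      v <- classify_topology(parse_topology(out$topology[i]))$violations
      paste0(violation_strings(v), collapse = ";")
    }, character(1L))
  }
  out
}

#' Summary counts for a classification table
#'
#' @param cls data frame from [classify_all()].
#' @return Named integer vector `total`, `frustration_free`, `frustrated`.
#' @export
classification_counts <- function(cls) {
  c(total = nrow(cls),
    frustration_free = sum(cls$frustration_free),
    frustrated = sum(!cls$frustration_free))
}

#' Write a classification table to TSV
#'
#' Columns `topology`, `n`, `frustration_free`, `violations` (semicolon-joined
#' `rule(conn_i[,conn_j])` entries).
#'
#' @param cls data frame from [classify_all()] (with `detail = TRUE`), or any
#'   frame with those columns.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_classification_tsv <- function(cls, file) {
  if (is.null(cls$violations))
    fail_validation("cls", "needs a 'violations' column (classify_all(detail = TRUE))")
  write_tsv(cls[, c("topology", "n", "frustration_free", "violations")], file)
  invisible(file)
}
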