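# Internal helpers shared across modules.

# Validation failures carry a dedicated condition class so the command-line
# wrapper can map them to exit status 2.
fail_validation <- function(field, msg) {
  stop(structure(
    class = c("sheetfolds_validation_error", "error", "condition"),
    list(message = sprintf("%s: %s", field, msg), call = sys.call(-1))
  ))
}

is_validation_error <- function(e) inherits(e, "sheetfolds_validation_error")

# All permutations of 1..n in lexicographic order, one per row.
perms_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    q <- sub
    q[q >= k] <- q[q >= k] + 1L
    cbind(rep.int(k, nrow(q)), q)
  }))
}

# Orientation strings of length n starting with "u", in lexicographic order
# under u < d (ascending binary integers, u = 0, d = 1).
orient_strings <- function(n) {
  m <- n - 1L
  if (m == 0L) return("u")
  ints <- 0:(2L^m - 1L)
  bits <- outer(ints, 2L^((m - 1L):0L), function(x, p) (x %/% p) %% 2L)
  chars <- matrix(c("u", "d")[bits + 1L], nrow = length(ints))
  paste0("u", apply(chars, 1L, paste0, collapse = ""))
}

# Orientation matrix (TRUE = up) matching orient_strings(n), row i = string i.
orient_logical <- function(n) {
  m <- n - 1L
  ints <- if (m == 0L) 0L else 0:(2L^m - 1L)
  bits <- if (m == 0L) matrix(integer(0), 1L, 0L) else
    outer(ints, 2L^((m - 1L):0L), function(x, p) (x %/% p) %% 2L)
  cbind(TRUE, bits == 0L)
}

write_tsv <- function(df, file) {
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
}
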