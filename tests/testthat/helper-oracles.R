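# Independent oracles used across the suite. These re-derive symmetry and
# orbit structure from explicit 3D coordinates so they share no code with the
# package's lookup-table implementations.

# Realize a raw (order, orient) grid as labeled vectors: strand at position p
# sits at x = p with direction dz = +1 (u) / -1 (d).
grid_to_coords <- function(order, orient) {
  data.frame(label = order, x = seq_along(order),
             dz = ifelse(orient == "u", 1, -1))
}

coords_to_string <- function(co) {
  co <- co[order(co$x), ]
  paste0(paste0(co$label, collapse = ""), ":",
         paste0(ifelse(co$dz > 0, "u", "d"), collapse = ""))
}

# 180-degree rotations about the three axes of the sheet plane
# (x: strand-order axis, y: face normal, z: strand axis).
rotate_grid <- function(co, axis) {
  out <- co
  if (axis == "z") {            # (x,y,z) -> (-x,-y,z): mirror positions
    out$x <- -co$x
  } else if (axis == "x") {     # (x,y,z) -> (x,-y,-z): flip directions
    out$dz <- -co$dz
  } else if (axis == "y") {     # (x,y,z) -> (-x,y,-z): both
    out$x <- -co$x
    out$dz <- -co$dz
  }
  out
}

# Orbit representative by brute force: lexicographically smallest string
# (orders as digit strings, u < d) over the identity and three rotations.
oracle_orbit_rep <- function(order, orient) {
  co <- grid_to_coords(order, orient)
  imgs <- c(coords_to_string(co),
            vapply(c("x", "y", "z"), function(ax)
              coords_to_string(rotate_grid(co, ax)), character(1)))
  key <- vapply(strsplit(imgs, ":"), function(p)
    paste0(p[1], chartr("ud", "01", p[2])), character(1))
  imgs[order(key)[1]]
}

# All raw grids for n strands (n! * 2^n of them) as a data frame of strings
# plus their oracle orbit representatives.
oracle_all_grids <- function(n) {
  perms <- all_perms(n)
  orient_sets <- as.matrix(expand.grid(rep(list(c("u", "d")), n),
                                       stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(orient_sets))) {
    ord <- perms[i, ]
    ori <- orient_sets[j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      grid = paste0(paste0(ord, collapse = ""), ":", paste0(ori, collapse = "")),
      rep = oracle_orbit_rep(ord, ori), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    q <- sub
    q[q >= k] <- q[q >= k] + 1L
    cbind(rep(k, nrow(q)), q)
  }))
}

# Random valid topology under a local RNG stream.
random_topology <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sheet_topology(sample(n), sample(c("u", "d"), n, replace = TRUE))
}

violation_set <- function(cls) {
  v <- cls$violations
  sort(paste(v$rule, v$conn_i, ifelse(is.na(v$conn_j), "", v$conn_j)))
}
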