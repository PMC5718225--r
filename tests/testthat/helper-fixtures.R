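# Shared fixtures and independent oracles.

small_header <- function(shape = c(12, 10, 8), spacing = c(1, 1, 2.5),
                         origin = c(0, 0, 0)) {
  grid_header(shape, spacing, origin)
}

random_field <- function(header, seed) {
  h <- header_of(header)
  n <- prod(h$shape)
  set.seed(seed)
  vector_field(array(rnorm(n), h$shape), array(rnorm(n), h$shape),
               array(rnorm(n), h$shape), h$spacing, h$origin, h$direction)
}

# Independent oracle: per-voxel triple-loop evaluation of
# curl = (dw/dy - dv/dz, du/dz - dw/dx, dv/dx - du/dy) with the same
# discretisation contract (central interior, one-sided edges), written as
# scalar index arithmetic with no shared code with the implementation.
naive_curl <- function(field) {
  d <- dim(field$u); s <- field$spacing
  dd <- function(g, i, j, k, ax) {
    idx <- c(i, j, k)
    n <- d[ax]; h <- s[ax]
    at <- function(p) { q <- idx; q[ax] <- p; g[q[1], q[2], q[3]] }
    if (idx[ax] == 1L) (at(2L) - at(1L)) / h
    else if (idx[ax] == n) (at(n) - at(n - 1L)) / h
    else (at(idx[ax] + 1L) - at(idx[ax] - 1L)) / (2 * h)
  }
  cx <- cy <- cz <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cx[i, j, k] <- dd(field$w, i, j, k, 2L) - dd(field$v, i, j, k, 3L)
    cy[i, j, k] <- dd(field$u, i, j, k, 3L) - dd(field$w, i, j, k, 1L)
    cz[i, j, k] <- dd(field$v, i, j, k, 1L) - dd(field$u, i, j, k, 2L)
  }
  list(cx = cx, cy = cy, cz = cz)
}

zero_field <- function(header) {
  h <- header_of(header)
  z <- array(0, h$shape)
  vector_field(z, z, z, h$spacing, h$origin, h$direction)
}

# Interior-voxel logical mask (strips `margin` voxels from every face).
interior_mask <- function(shape, margin = 1L) {
  m <- array(FALSE, shape)
  m[(1 + margin):(shape[1] - margin), (1 + margin):(shape[2] - margin),
    (1 + margin):(shape[3] - margin)] <- TRUE
  m
}
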