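# Independent brute-force persistence oracle: full dense GF(2) boundary
# matrix over ALL simplices of dimension <= 2 (no union-find, no clearing,
# no column pruning) with the textbook left-to-right reduction. Only
# feasible for tiny point sets; used to validate the package implementation.

oracle_barcode <- function(xy, keep_zero = FALSE) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))

  verts <- lapply(seq_len(n), function(i) list(v = i, val = 0, dim = 0L))
  edges <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      edges[[length(edges) + 1]] <- list(v = c(i, j), val = D[i, j] / 2,
                                         dim = 1L)
  }
  tris <- list()
  if (n >= 3) {
    cmb <- utils::combn(n, 3)
    for (c_i in seq_len(ncol(cmb))) {
      v <- cmb[, c_i]
      tris[[length(tris) + 1]] <- list(
        v = v, val = max(D[v[1], v[2]], D[v[1], v[3]], D[v[2], v[3]]) / 2,
        dim = 2L)
    }
  }
  simp <- c(verts, edges, tris)
  vals <- vapply(simp, `[[`, numeric(1), "val")
  dims <- vapply(simp, `[[`, integer(1), "dim")
  lexkey <- vapply(simp, function(s)
    paste(formatC(s$v, width = 6, flag = "0"), collapse = ""), character(1))
  ord <- order(vals, dims, lexkey)
  simp <- simp[ord]
  vals <- vals[ord]
  dims <- dims[ord]
  m <- length(simp)

  # position lookup for a vertex set
  keys <- vapply(simp, function(s) paste(sort(s$v), collapse = "-"),
                 character(1))
  pos <- function(v) match(paste(sort(v), collapse = "-"), keys)

  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0L) next
    faces <- utils::combn(s$v, s$dim)  # each column drops one vertex
    for (f in seq_len(ncol(faces))) B[pos(faces[, f]), j] <- TRUE
  }

  low <- function(col) { w <- which(col); if (length(w)) max(w) else 0L }
  lows <- integer(m)   # lows[i] = column with low i, 0 if none
  pair_of <- integer(m)
  for (j in seq_len(m)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L || lows[l] == 0L) break
      B[, j] <- xor(B[, j], B[, lows[l]])
    }
    l <- low(B[, j])
    if (l > 0L) {
      lows[l] <- j
      pair_of[l] <- j
    }
  }

  bars <- data.frame(dimension = integer(), birth = numeric(),
                     death = numeric())
  for (i in seq_len(m)) {
    if (low(B[, i]) > 0L) next          # negative simplex: not a birth
    death <- if (pair_of[i] > 0L) vals[pair_of[i]] else Inf
    if (dims[i] <= 1L)
      bars <- rbind(bars, data.frame(dimension = dims[i], birth = vals[i],
                                     death = death))
  }
  if (!keep_zero) bars <- bars[bars$birth != bars$death, , drop = FALSE]
  bars[order(bars$dimension, bars$birth, bars$death), , drop = FALSE]
}

# canonical form for comparing bar sets
bar_matrix <- function(bars) {
  b <- as.data.frame(bars)[c("dimension", "birth", "death")]
  b <- b[order(b$dimension, b$birth, b$death), , drop = FALSE]
  rownames(b) <- NULL
  as.matrix(b)
}

expect_same_bars <- function(actual, expected, tol = 1e-12) {
  a <- bar_matrix(actual)
  e <- bar_matrix(expected)
  expect_equal(dim(a), dim(e))
  expect_true(all(abs(a - e) < tol | (is.infinite(a) & is.infinite(e))))
}
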