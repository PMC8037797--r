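# small geometric fixtures used across tests

unit_square <- function(s = 1) rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))

regular_polygon <- function(k, r = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

rigid_transform <- function(xy, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(xy %*% t(R), 2, shift, "+")
}

# all permutations of 1:n as a matrix (one per row), for matching oracles
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# cluster object directly from member coordinates (bypasses detection)
make_cluster_fixture <- function(xy) {
  smlmtopo:::make_cluster(1L, seq_len(nrow(xy)), as.matrix(xy))
}

# barcode built directly from bars, for similarity tests
manual_barcode <- function(bars_df, n_points = 10L, unit = "um") {
  smlmtopo:::new_barcode(as.data.frame(bars_df), n_points = n_points,
                         unit = unit)
}
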