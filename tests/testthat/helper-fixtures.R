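# Shared fixtures, built in code.

# canonical worked example: 8-sigma-ish separation, unit spreads
fixture_cg <- function() control_groups(c(9, 10, 11), c(1, 2, 3))

# Brute-force two-sample KS: maximize |F_a - F_b| over a dense grid of
# candidate points.  Independent of the pooled-unique-values route used
# by ks_stat().
ks_brute <- function(a, b, grid_n = 4000) {
  lo <- min(a, b) - 1
  hi <- max(a, b) + 1
  grid <- sort(c(seq(lo, hi, length.out = grid_n), a, b))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(fa - fb))
}

# write an 8x12 grid CSV filled with `value`; cells named in `drop`
# (e.g. "B3") are left empty
write_grid_csv <- function(path, value = 0.5, drop = character(0)) {
  grid <- matrix(format(value), nrow = 8, ncol = 12)
  rownames(grid) <- LETTERS[1:8]
  for (w in drop) {
    addr <- parse_well_label(w)
    grid[addr$row, addr$column] <- ""
  }
  df <- data.frame(row = LETTERS[1:8], grid, check.names = FALSE)
  names(df) <- c("", as.character(1:12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

all_negative_role_map <- function() {
  stats::setNames(rep("negative", 96), well_labels())
}

half_plate_role_map <- function() {
  stats::setNames(rep(c("positive", "negative"), each = 48), well_labels())
}
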