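# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: naive loops and closed forms only.

# brute-force double-loop box counter, zero or explicit offset
brute_box_count <- function(px, s, off = c(0L, 0L)) {
  nr <- nrow(px); nc <- ncol(px)
  count <- 0L
  r0 <- -(off[1] %% s)
  c0 <- -(off[2] %% s)
  for (br in seq(r0, nr - 1L, by = s)) {
    for (bc in seq(c0, nc - 1L, by = s)) {
      rows <- max(1L, br + 1L):min(nr, br + s)
      cols <- max(1L, bc + 1L):min(nc, bc + s)
      if (any(px[rows, cols])) count <- count + 1L
    }
  }
  count
}

# closed-form paired t
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# closed-form pooled two-sample t
oracle_unpaired_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Mann-Whitney U for the first sample plus exact two-sided p by full
# enumeration of rank assignments (no ties assumed for the exact branch)
oracle_mwu <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  n1 <- length(x); n2 <- length(y)
  combs <- combn(n1 + n2, n1)
  r <- rank(c(x, y))
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # two-sided: double the smaller tail of the symmetric U distribution
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = U, p = min(1, p))
}

# closed-form Pearson r and t-transform p
oracle_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Spearman rho by explicit ranking (mean ranks for ties)
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# shared dose-response phantom settings (0.3 mm voxels; fixed grid so all
# amplitudes share one canvas)
phantom_grid <- c(240L, 200L, 150L)
make_phantom <- function(amplitude, seed, frequency = 12) {
  generate_organ_phantom(base_radii = c(25, 20, 15),
                         serration_amplitude = amplitude,
                         serration_frequency = frequency,
                         voxel_spacing = rep(0.3, 3),
                         grid_shape = phantom_grid, seed = seed)
}

# square axis-aligned polygon covering an n x n block of pixel centres
# with corner pixel (0, 0)
square_poly <- function(n) {
  rbind(c(-0.5, -0.5), c(n - 0.5, -0.5), c(n - 0.5, n - 0.5),
        c(-0.5, n - 0.5))
}
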