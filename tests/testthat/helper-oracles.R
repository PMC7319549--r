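# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Affine-gap local alignment score by direct dynamic programming (three
# state matrices, no traceback). Gap of length L costs open + L * ext.
sw_score_oracle <- function(qs, ts, mat, open, ext) {
  q <- strsplit(qs, "")[[1]]; t <- strsplit(ts, "")[[1]]
  n <- length(q); m <- length(t)
  NEG <- -1e18
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    M[i + 1, j + 1] <- max(0, mat[q[i], t[j]] +
                             max(M[i, j], X[i, j], Y[i, j]))
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Best achievable RMSD over rigid motions, by dense random-rotation search
# plus Nelder-Mead polish on an axis-angle parameterisation.
rmsd_for_rotation <- function(R, moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  fit <- sweep(sweep(moving, 2, cm) %*% t(R), 2, cf, "+")
  sqrt(mean(rowSums((fit - fixed)^2)))
}

axis_angle_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

brute_force_min_rmsd <- function(moving, fixed, n_grid = 4000) {
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  qs <- qs / sqrt(rowSums(qs^2))
  best <- Inf; best_v <- c(0, 0, 0)
  for (i in seq_len(n_grid)) {
    w <- qs[i, 1]; x <- qs[i, 2]; y <- qs[i, 3]; z <- qs[i, 4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    r <- rmsd_for_rotation(R, moving, fixed)
    if (r < best) {
      best <- r
      th <- 2 * acos(max(-1, min(1, w)))
      s <- sqrt(max(1 - w^2, 1e-12))
      best_v <- th * c(x, y, z) / s
    }
  }
  opt <- optim(best_v, function(v) rmsd_for_rotation(axis_angle_rotation(v),
                                                     moving, fixed),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

# Maximum one-to-one matching count under a distance cutoff, by exhaustive
# recursion over assignments (feasible for <= ~6 waters).
optimal_match_count <- function(original, placed, cutoff) {
  m <- nrow(original); n <- nrow(placed)
  if (m == 0 || n == 0) return(0L)
  d <- as.matrix(dist(rbind(original, placed)))[seq_len(m), m + seq_len(n),
                                                drop = FALSE]
  feas <- d < cutoff
  rec <- function(i, used) {
    if (i > m) return(0L)
    best <- rec(i + 1L, used)  # leave original i unmatched
    for (j in which(feas[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1L, rep(FALSE, n))
}

# Fixed-width PDB line, for hand-built text fixtures.
pdb_line <- function(type, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = substr(name, 1, 1),
                     altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, altloc, resname, chain, resno, x, y, z, occ, b,
          elem)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A random rigid motion (rotation + translation), seeded by the caller.
random_motion <- function(shift = 20) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = runif(3, -shift, shift))
}

move_model <- function(model, motion) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$t, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

strip_waters_ions <- function(model) {
  model$atoms <- model$atoms[!model$atoms$resid %in% c("HOH", "WAT", "DOD", "NA"), ]
  model$metadata$water_truth <- NULL
  model
}

# Brute-force circular variance, written independently of the package.
cv_oracle <- function(o, nb, radius = 10) {
  s <- c(0, 0, 0); n <- 0
  for (i in seq_len(nrow(nb))) {
    v <- nb[i, ] - o
    d <- sqrt(sum(v^2))
    if (d > 0 && d <= radius) { s <- s + v / d; n <- n + 1 }
  }
  if (n == 0) return(0)
  1 - sqrt(sum(s^2)) / n
}

.coords_of <- function(df) as.matrix(df[, c("x", "y", "z")])
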