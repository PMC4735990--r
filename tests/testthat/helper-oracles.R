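# Independent oracles used against the package implementations.

# brute-force truncated-window mean
brute_window_mean <- function(vals, window) {
  k <- (window - 1) / 2
  n <- length(vals)
  vapply(seq_len(n), function(i) {
    mean(vals[max(1, i - k):min(n, i + k)])
  }, 0)
}

# brute-force average pairwise identity (pairwise-deletion denominator)
brute_identity <- function(rows) {
  mat <- do.call(rbind, strsplit(chartr(".", "-", rows), ""))
  vals <- c()
  for (i in seq_len(nrow(mat) - 1)) {
    for (j in (i + 1):nrow(mat)) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(both)) next
      vals <- c(vals, sum(mat[i, both] == mat[j, both]) / sum(both))
    }
  }
  mean(vals)
}

# random unit-sphere directions (independent of the package's lattice)
random_sphere_points <- function(n) {
  z <- stats::runif(n, -1, 1)
  t <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(t), r * sin(t), z)
}

# dense deterministic lattice, randomly rotated (uses the ambient RNG) so
# it shares no alignment with the implementation's point set
rotated_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  pts %*% q
}

# Shrake-Rupley-style dense-sampling SASA oracle
sr_sasa_oracle <- function(structure, probe = 1.4, n_points = 10000L,
                           include = NULL) {
  a <- structure$atoms
  if (is.null(include)) include <- rep(TRUE, nrow(a))
  a <- a[include, , drop = FALSE]
  R <- a$vdw_radius + probe
  areas <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    pts <- sweep(random_sphere_points(n_points) * R[i], 2,
                 c(a$x[i], a$y[i], a$z[i]), `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      acc <- acc & ((pts[, 1] - a$x[j])^2 + (pts[, 2] - a$y[j])^2 +
                    (pts[, 3] - a$z[j])^2 >= R[j]^2)
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  areas
}

# dense-sampling nearest-owner contact oracle: per ligand atom, estimate
# buried area and its legitimate/illegitimate split purely from sampled
# surface-point fractions (no Lee-Richards involvement)
contact_oracle <- function(complex, classes, probe = 1.4,
                           n_points = 24001L,
                           legit = phspec::legitimacy_matrix()) {
  a <- complex$atoms
  lig <- which(a$is_hetero)
  prot <- which(!a$is_hetero)
  R <- a$vdw_radius + probe
  lattice <- rotated_lattice(n_points)
  out <- data.frame(atom = lig, buried = 0, S_legit = 0, S_illegit = 0)
  for (k in seq_along(lig)) {
    i <- lig[k]
    pts <- sweep(lattice * R[i], 2,
                 c(a$x[i], a$y[i], a$z[i]), `+`)
    acc <- rep(TRUE, n_points)
    for (j in setdiff(lig, i)) {
      acc <- acc & ((pts[, 1] - a$x[j])^2 + (pts[, 2] - a$y[j])^2 +
                    (pts[, 3] - a$z[j])^2 >= R[j]^2)
    }
    d2 <- outer(pts[, 1], a$x[prot], `-`)^2 +
          outer(pts[, 2], a$y[prot], `-`)^2 +
          outer(pts[, 3], a$z[prot], `-`)^2
    covered <- rowSums(sweep(d2, 2, R[prot]^2, `<`)) > 0
    buried <- acc & covered
    if (!any(buried)) next
    surf_d <- sweep(sqrt(d2[buried, , drop = FALSE]), 2, R[prot], `-`)
    owner <- prot[max.col(-surf_d, ties.method = "first")]
    ok <- legit[classes[i], classes[owner]] == 1
    patch <- 4 * pi * R[i]^2 / n_points
    out$buried[k] <- sum(buried) * patch
    out$S_legit[k] <- sum(ok) * patch
    out$S_illegit[k] <- sum(!ok) * patch
  }
  out
}

# spherical-cap closed form: exposed area of one of two equal intersecting
# spheres of expanded radius r at centre distance d
two_sphere_cap_area <- function(r, d) 2 * pi * r * (r + d / 2)

# random packed atom cluster for SASA fixtures
random_cluster <- function(n, spread = 6, seed = 1,
                           elements = c("C", "N", "O", "S")) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
  el <- sample(elements, n, replace = TRUE)
  make_structure(xyz, element = el,
                 atom_name = paste0(el, seq_len(n)),
                 residue_seq_id = rep(seq_len(ceiling(n / 4)), each = 4,
                                      length.out = n))
}
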