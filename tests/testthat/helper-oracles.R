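# Brute-force oracles and small fixture builders, independent of the
# package's implementation paths.

# SISI by direct loop over the definition
oracle_sisi <- function(samples, delta_d, d_tb, d_min, dense_hu = 1000) {
  if (d_tb <= d_min) return(0)
  n <- 0L
  ns <- 0L
  for (k in seq_along(samples)) {
    depth <- (k - 1L) * delta_d
    if (depth <= d_min + 1e-9) {
      n <- n + 1L
      if (samples[k] >= dense_hu) ns <- ns + 1L
    }
  }
  if (n == 0L) 0 else 100 * ns / n
}

# CODI by direct loop: clamp HU, linear map, /1000, times delta_d
oracle_codi <- function(samples, delta_d, d_tb, slope, intercept = 0,
                        bound = Inf) {
  total <- 0
  for (k in seq_along(samples)) {
    depth <- (k - 1L) * delta_d
    if (depth > min(d_tb, 18) + 1e-9 || depth > bound + 1e-9) next
    hu <- max(samples[k], 0)
    bmd <- max((hu - intercept) / slope, 0) / 1000
    total <- total + bmd * delta_d
  }
  total
}

# cortical density by direct loop
oracle_cortical <- function(samples, delta_d, onset_hu = 1000,
                            window_mm = 1.5) {
  onset <- NA_integer_
  for (k in seq_along(samples))
    if (samples[k] >= onset_hu) { onset <- k; break }
  if (is.na(onset)) return(NA_real_)
  acc <- c()
  for (k in onset:length(samples)) {
    if ((k - onset) * delta_d <= window_mm + 1e-9) acc <- c(acc, samples[k])
  }
  mean(acc)
}

# connected components by plain R flood fill (26-connectivity)
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      k0 <- (cur - 1L) %/% (d[1] * d[2])
      j0 <- ((cur - 1L) %% (d[1] * d[2])) %/% d[1]
      i0 <- (cur - 1L) %% d[1]
      for (r in seq_len(nrow(offs))) {
        i <- i0 + offs[r, 1]; j <- j0 + offs[r, 2]; k <- k0 + offs[r, 3]
        if (i < 0 || j < 0 || k < 0 || i >= d[1] || j >= d[2] || k >= d[3])
          next
        idx <- 1L + i + d[1] * (j + d[2] * k)
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

# random synthetic profile: random mixture of air / soft tissue / bone
random_profile <- function(delta_d = 0.15) {
  n <- sample(5:121, 1)
  samples <- sample(c(-1000, -800, 0, 300, 500, 999, 1000, 1100, 1500, 2000),
                    n, replace = TRUE) + round(runif(n, -50, 50))
  d_tb <- (n - 1) * delta_d
  synthetic_profile(samples, delta_d, d_tb)
}

# uniform slab in air as a ct_volume, slab normal along z
make_slab_volume <- function(thickness = 10, hu = 1500,
                             lateral = c(12, 12), spacing = c(0.2, 0.2, 0.2),
                             air_below = 3, air_above = 3) {
  nz <- round((air_below + thickness + air_above) / spacing[3])
  nx <- round(lateral[1] / spacing[1])
  ny <- round(lateral[2] / spacing[2])
  zc <- (seq_len(nz) - 1L) * spacing[3]
  z0 <- (round(air_below / spacing[3]) - 0.5) * spacing[3]
  z1 <- z0 + round(thickness / spacing[3]) * spacing[3]
  col <- ifelse(zc > z0 & zc < z1, hu, -1000)
  ct_volume(array(rep(col, each = nx * ny), dim = c(nx, ny, nz)),
            spacing = spacing)
}

# analytic axis-aligned box mesh (12 triangles, outward normals)
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  # corners indexed by bits (x fastest)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = hi, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = lo, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = hi, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = lo, normal -x
    c(2, 4, 6), c(4, 8, 6))   # x = hi, normal +x
  bone_mesh(v, f)
}

# rotate a mesh by matrix R about a center point
rotate_mesh <- function(mesh, R, center = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2L, center, "-") %*% t(R)
  bone_mesh(sweep(v, 2L, center, "+"), mesh$faces)
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# frame looking down +z onto a slab: x = +x, y = +y (scanner), z lateral +z
downward_frame <- function(origin = c(0, 0, 0)) {
  build_frame(origin, origin + c(-10, 0, 0), origin + c(-20, 0, 0),
              axial_normal = c(0, 1, 0), side = "right",
              posterior_hint = c(1, 0, 0))
}
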