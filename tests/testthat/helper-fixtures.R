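# fixture builders and independent reference implementations used across tests

# logical (z, y, x) array with TRUE inside a sphere (um geometry)
make_sphere_mask <- function(dim, spacing, centre_um, radius_um) {
  co <- expand.grid(z = seq_len(dim[1]) - 1L, y = seq_len(dim[2]) - 1L,
                    x = seq_len(dim[3]) - 1L)
  d2 <- (co$z * spacing[1] - centre_um[1])^2 +
    (co$y * spacing[2] - centre_um[2])^2 +
    (co$x * spacing[3] - centre_um[3])^2
  array(d2 <= radius_um^2, dim = dim)
}

# tube of given radius around the straight segment from `from` (um) along
# unit direction `dir` for `len` um
make_tube_mask <- function(dim, spacing, from, dir, len, radius_um) {
  dir <- dir / sqrt(sum(dir^2))
  pts <- t(sapply(seq(0, len, by = min(spacing) / 2), function(s) from + dir * s))
  m <- array(FALSE, dim = dim)
  m[phagoglia:::cpp_ball_indices(as.integer(dim), spacing, pts, radius_um)] <- TRUE
  m
}

# exhaustive flood-fill connected-component reference (BFS, pure R)
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  labels <- array(0L, dim = d)
  nxt <- 0L
  for (i in which(mask)) {
    if (labels[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    labels[i] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (cur - 1L) %% d[1] + 1L
      y <- ((cur - 1L) %/% d[1]) %% d[2] + 1L
      x <- (cur - 1L) %/% (d[1] * d[2]) + 1L
      for (k in seq_len(nrow(offs))) {
        zz <- z + offs$dz[k]; yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
        j <- zz + d[1] * (yy - 1L) + d[1] * d[2] * (xx - 1L)
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
enum_mw_p <- function(a, b) {
  x <- c(a, b)
  stopifnot(!anyDuplicated(x))
  n1 <- length(a); n <- length(x)
  r <- rank(x)
  u_from <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_from(seq_len(n1))
  mu <- n1 * (length(b)) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_from)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# tiny two-channel stack with hand-placed signal
toy_stack <- function() {
  vox <- array(10L, dim = c(2, 6, 12, 12))
  vox[1, 2:4, 3:5, 3:5] <- 200L       # TH blob
  vox[2, 2:5, 2:7, 2:7] <- 200L       # glial blob containing part of TH
  image_stack(vox, spacing = c(1, 0.5, 0.5),
              channel_roles = c("TH", "GLIA_IBA1"))
}
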