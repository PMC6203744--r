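# Independent oracles used by the metric and statistics tests. These are
# deliberately implemented from first principles (dense subdivision,
# brute-force enumeration) and share no code with the package's exact
# geometric or rank-based routines.

# dense-subdivision corridor percentage: split every segment into k pieces
# and score each piece by its midpoint's membership in the capped band
oracle_corridor_percent <- function(traj, start, platform, width_cm = 20,
                                    k = 400) {
  d <- platform - start
  L <- sqrt(sum(d^2))
  u <- d / L
  tot <- 0; inside <- 0
  for (i in seq_len(nrow(traj) - 1)) {
    p0 <- c(traj$x[i], traj$y[i]); p1 <- c(traj$x[i + 1], traj$y[i + 1])
    seg <- sqrt(sum((p1 - p0)^2))
    if (seg == 0) next
    mids <- (seq_len(k) - 0.5) / k
    for (m in mids) {
      pm <- p0 + m * (p1 - p0)
      rel <- pm - start
      along <- sum(rel * u)
      perp <- abs(rel[1] * u[2] - rel[2] * u[1])
      tot <- tot + seg / k
      if (along >= 0 && along <= L && perp <= width_cm / 2)
        inside <- inside + seg / k
    }
  }
  100 * inside / tot
}

# dense-time quadrant occupancy: midpoint quadrant of fine time slices
oracle_quadrant_occupancy <- function(traj, k = 200) {
  occ <- numeric(4)
  for (i in seq_len(nrow(traj) - 1)) {
    dt <- traj$t[i + 1] - traj$t[i]
    for (m in (seq_len(k) - 0.5) / k) {
      x <- traj$x[i] + m * (traj$x[i + 1] - traj$x[i])
      y <- traj$y[i] + m * (traj$y[i + 1] - traj$y[i])
      deg <- (atan2(y, x) * 180 / pi) %% 360
      q <- floor(deg / 90) + 1
      occ[q] <- occ[q] + dt / k
    }
  }
  100 * occ / sum(occ)
}

# dense-subdivision path length inside a disk
oracle_disk_path <- function(traj, center, r, k = 400) {
  inside <- 0
  for (i in seq_len(nrow(traj) - 1)) {
    p0 <- c(traj$x[i], traj$y[i]); p1 <- c(traj$x[i + 1], traj$y[i + 1])
    seg <- sqrt(sum((p1 - p0)^2))
    if (seg == 0) next
    for (m in (seq_len(k) - 0.5) / k) {
      pm <- p0 + m * (p1 - p0)
      if (sqrt(sum((pm - center)^2)) <= r) inside <- inside + seg / k
    }
  }
  inside
}

# first time the path enters the platform disk, by dense subdivision
oracle_first_crossing <- function(traj, center, r, k = 2000) {
  for (i in seq_len(nrow(traj) - 1)) {
    for (m in seq(0, 1, length.out = k)) {
      x <- traj$x[i] + m * (traj$x[i + 1] - traj$x[i])
      y <- traj$y[i] + m * (traj$y[i + 1] - traj$y[i])
      if (sqrt((x - center[1])^2 + (y - center[2])^2) <= r)
        return(traj$t[i] + m * (traj$t[i + 1] - traj$t[i]) - traj$t[1])
    }
  }
  NA_real_
}

# brute-force Mann-Whitney: U from rank sums and exact two-sided p over all
# group labelings
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_null <- apply(combs, 2, function(idx)
    sum(rk[idx]) - n1 * (n1 + 1) / 2)
  nm2 <- n1 * n2 / 2
  p <- if (u1 > nm2) mean(u_null >= u1) else mean(u_null <= u1)
  list(u = min(u1, n1 * n2 - u1), p = min(1, 2 * p))
}

# tie-corrected Kruskal-Wallis H from the defining formula
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  tie <- table(x)
  h / (1 - sum(tie^3 - tie) / (N^3 - N))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force Spearman: midrank rho and exact two-sided p over all n!
# orderings, two-sided by |rho|
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r0 <- stats::cor(rx, ry)
  P <- all_permutations(length(x))
  rs <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
  list(rho = r0, p = mean(abs(rs) >= abs(r0) - 1e-12))
}

# simple trajectory constructors ---------------------------------------

straight_trajectory <- function(from, to, speed_cmps = 20, dt = 0.1,
                                arena = pool_arena(), ...) {
  d <- sqrt(sum((to - from)^2))
  dur <- d / speed_cmps
  tt <- seq(0, dur, by = dt)
  if (tt[length(tt)] < dur) tt <- c(tt, dur)
  frac <- tt / dur
  trajectory(tt, from[1] + frac * (to[1] - from[1]),
             from[2] + frac * (to[2] - from[2]), arena = arena, ...)
}

circle_trajectory <- function(r, n = 361, period_s = 36, arena = pool_arena(),
                              phase = 0, ...) {
  a <- phase + seq(0, 2 * pi, length.out = n)
  trajectory(seq(0, period_s, length.out = n), r * cos(a), r * sin(a),
             arena = arena, ...)
}
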