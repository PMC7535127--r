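## Independent brute-force oracles used across the suite. All are written
## as straight per-voxel loops, deliberately sharing no code with the
## package internals they check.

## One explicit Euler step of the monodomain Fenton-Karma model, looped
## voxel by voxel. `state` is a list(u, v, w) of 3-D arrays; `D` an array;
## faces use the arithmetic mean with no-flux at missing/zero-D faces.
bruteEulerStep <- function(state, mask, D, dx, params, dt,
                           reaction = TRUE) {
  dm <- dim(mask)
  u <- state$u; v <- state$v; w <- state$w
  un <- u; vn <- v; wn <- w
  sig <- function(x) if (x <= -6) 0 else if (x >= 6) 1 else 1 / (1 + exp(-2 * x))
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!mask[i, j, k]) next
    ui <- u[i, j, k]
    acc <- 0
    for (f in 1:6) {
      ii <- i + offs[f, 1]; jj <- j + offs[f, 2]; kk <- k + offs[f, 3]
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]) next
      if (!mask[ii, jj, kk]) next
      Di <- D[i, j, k]; Dj <- D[ii, jj, kk]
      if (Di == 0 || Dj == 0) next
      acc <- acc + (Di + Dj) / 2 * (u[ii, jj, kk] - ui)
    }
    du <- acc * (1 / (dx * dx))
    if (reaction) {
      p <- params
      if (ui >= p@u_c) {
        dv <- -v[i, j, k] / p@tau_v_plus
        dw <- -w[i, j, k] / p@tau_w_plus
        Jfi <- -v[i, j, k] * (1 - ui) * (ui - p@u_c) / p@tau_d
        Jso <- 1 / p@tau_r
      } else {
        tvm <- if (ui >= p@u_v) p@tau_v1_minus else p@tau_v2_minus
        dv <- (1 - v[i, j, k]) / tvm
        dw <- (1 - w[i, j, k]) / p@tau_w_minus
        Jfi <- 0
        Jso <- ui / p@tau_0
      }
      Jsi <- -w[i, j, k] * sig(p@k * (ui - p@u_c_si)) / p@tau_si
      vn[i, j, k] <- min(max(v[i, j, k] + dt * dv, 0), 1)
      wn[i, j, k] <- min(max(w[i, j, k] + dt * dw, 0), 1)
      du <- du + (-(Jfi + Jso + Jsi))
    }
    un[i, j, k] <- ui + dt * du
  }
  list(u = un, v = vn, w = wn)
}

## Face-by-face flux sum for the heterogeneous Laplacian (same boundary
## rules, loop form).
bruteLaplacian <- function(u, mask, D, dx) {
  st <- bruteEulerStep(list(u = u, v = u * 0 + 1, w = u * 0 + 1),
                       mask, D, dx, afkParams(), dt = 1, reaction = FALSE)
  (st$u - u)  # dt = 1, so the increment is the Laplacian itself
}

## Brute-force per-plaquette winding count on one 2-D layer.
bruteWindingTips <- function(uNow, uDelayed, mask2d, dx, uStar = 0.5) {
  nx <- nrow(uNow); ny <- ncol(uNow)
  wrap <- function(x) { while (x > pi) x <- x - 2 * pi
                        while (x < -pi) x <- x + 2 * pi; x }
  th <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) for (i in seq_len(nx))
    if (mask2d[i, j]) th[i, j] <- atan2(uDelayed[i, j] - uStar,
                                        uNow[i, j] - uStar)
  out <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    c4 <- c(th[i, j], th[i + 1, j], th[i + 1, j + 1], th[i, j + 1])
    if (any(is.na(c4))) next
    wind <- wrap(c4[2] - c4[1]) + wrap(c4[3] - c4[2]) +
            wrap(c4[4] - c4[3]) + wrap(c4[1] - c4[4])
    if (abs(wind) > pi)
      out <- rbind(out, c(i * dx, j * dx, sign(wind)))
  }
  out
}

## Flood-fill 26-connected labelling (BFS with an explicit queue).
bruteFloodFill <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      co <- arrayInd(q, dm)
      for (r in seq_len(nrow(offs))) {
        ii <- co[1] + offs[r, 1]; jj <- co[2] + offs[r, 2]
        kk <- co[3] + offs[r, 3]
        if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
            kk < 1 || kk > dm[3]) next
        if (mask[ii, jj, kk] && lab[ii, jj, kk] == 0L) {
          lab[ii, jj, kk] <- cur
          queue <- c(queue, (kk - 1L) * dm[1] * dm[2] + (jj - 1L) * dm[1] + ii)
        }
      }
    }
  }
  lab
}

## Analytic Archimedean-spiral snapshot pair: a rotating phase field
## phi = atan2(y - y0, x - x0) - r / pitch, sampled at two times a quarter
## period apart. chir = +1 or -1 sets the rotation sense.
spiralFrames <- function(nx, ny, dx, center, pitch = 4, chir = 1) {
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dx
  gx <- matrix(xs, nx, ny); gy <- matrix(ys, nx, ny, byrow = TRUE)
  r <- sqrt((gx - center[1])^2 + (gy - center[2])^2)
  phi <- chir * atan2(gy - center[2], gx - center[1]) - r / pitch
  uNow <- array(0.5 + 0.45 * cos(phi), c(nx, ny, 1))
  uDel <- array(0.5 + 0.45 * cos(phi - pi / 2), c(nx, ny, 1))
  list(now = uNow, delayed = uDel)
}
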