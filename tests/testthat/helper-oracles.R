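# Independent brute-force oracles used across the suite. These deliberately
# use naive nested loops so they share no code path with the implementation.

oracle_correlate_same <- function(image, kernel) {
  H <- nrow(image); W <- ncol(image)
  kh <- nrow(kernel); half <- (kh - 1) / 2
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in 1:kh) for (dj in 1:kh) {
      ii <- i + di - 1 - half; jj <- j + dj - 1 - half
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + kernel[di, dj] * image[ii, jj]
      }
    }
    out[i, j] <- acc
  }
  out
}

# same rectify/rescale/cutoff post-processing as the filter front end,
# applied to an oracle correlation
oracle_filter_channel <- function(image, kernel, cutoff) {
  resp <- oracle_correlate_same(image, kernel)
  resp[resp < 0] <- 0
  if (max(resp) > 1e-6) resp <- resp * 255 / max(resp) else resp[] <- 0
  resp[resp < cutoff] <- 0
  resp
}

oracle_box_mean <- function(ch, radius) {
  H <- nrow(ch); W <- ncol(ch)
  out <- matrix(0, H, W)
  k <- 2 * radius + 1
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) acc <- acc + ch[ii, jj]
    }
    out[i, j] <- acc / (k * k)
  }
  out
}

oracle_conv_potentials <- function(s, w) {
  d <- dim(s); tm <- d[1]; fin <- d[2]; H <- d[3]; W <- d[4]
  fout <- dim(w)[1]; kh <- dim(w)[3]; kw <- dim(w)[4]
  ho <- H - kh + 1; wo <- W - kw + 1
  v <- array(0, dim = c(tm, fout, ho, wo))
  for (t in 1:tm) for (fo in 1:fout) for (i in 1:ho) for (j in 1:wo) {
    acc <- 0
    for (fi in 1:fin) for (di in 1:kh) for (dj in 1:kw) {
      acc <- acc + w[fo, fi, di, dj] * s[t, fi, i + di - 1, j + dj - 1]
    }
    v[t, fo, i, j] <- acc
  }
  v
}

oracle_pool_max <- function(x, window, stride, padding) {
  d <- dim(x)
  hp <- d[3] + 2 * padding; wp <- d[4] + 2 * padding
  ho <- (hp - window) %/% stride + 1
  wo <- (wp - window) %/% stride + 1
  out <- array(0, dim = c(d[1], d[2], ho, wo))
  for (t in 1:d[1]) for (f in 1:d[2]) {
    pad <- matrix(0, hp, wp)
    pad[(padding + 1):(padding + d[3]), (padding + 1):(padding + d[4])] <- x[t, f, , ]
    for (i in 1:ho) for (j in 1:wo) {
      r0 <- (i - 1) * stride + 1; c0 <- (j - 1) * stride + 1
      out[t, f, i, j] <- max(pad[r0:(r0 + window - 1), c0:(c0 + window - 1)])
    }
  }
  out
}

# first spike time per (f,h,w): 1-based, Inf if never (direct scan, not the
# cumulative-count shortcut)
oracle_first_spike <- function(s) {
  d <- dim(s)
  tf <- array(Inf, dim = d[-1])
  for (f in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4]) {
    hit <- which(s[, f, h, w] > 0)
    if (length(hit) > 0) tf[f, h, w] <- hit[1]
  }
  tf
}

# exhaustive WTA re-scan: after every pick rebuild eligibility and rescan
oracle_k_winners <- function(tp, spikes, kwta, r) {
  d <- dim(spikes)
  tf <- oracle_first_spike(spikes)
  pot <- array(-Inf, dim = d[-1])
  for (f in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4]) {
    if (is.finite(tf[f, h, w])) pot[f, h, w] <- tp[tf[f, h, w], f, h, w]
  }
  banned_f <- integer(0)
  banned_px <- matrix(numeric(0), ncol = 2)
  winners <- matrix(integer(0), ncol = 3)
  for (k in 1:kwta) {
    best <- NULL
    for (f in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4]) {
      if (!is.finite(tf[f, h, w])) next
      if (f %in% banned_f) next
      if (nrow(banned_px) > 0 &&
          any(pmax(abs(banned_px[, 1] - h), abs(banned_px[, 2] - w)) <= r) && r > 0) next
      cand <- c(tf[f, h, w], -pot[f, h, w], f, h, w)
      if (is.null(best)) { best <- cand; next }
      for (z in 1:5) {
        if (cand[z] < best[z]) { best <- cand; break }
        if (cand[z] > best[z]) break
      }
    }
    if (is.null(best)) break
    winners <- rbind(winners, best[3:5])
    banned_f <- c(banned_f, best[3])
    banned_px <- rbind(banned_px, best[4:5])
  }
  winners
}

oracle_chi2 <- function(x, y) {
  x <- as.matrix(x); y <- as.factor(y)
  classes <- levels(y); n <- nrow(x)
  scores <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    total <- sum(x[, j])
    s <- 0
    for (cl in classes) {
      O <- sum(x[y == cl, j])
      E <- sum(y == cl) / n * total
      if (E > 0) s <- s + (O - E)^2 / E
    }
    scores[j] <- s
  }
  scores
}

# EER by dense grid sweep (independent of the interpolated implementation)
oracle_eer_grid <- function(genuine, impostor, n_grid = 20000) {
  grid <- seq(min(c(genuine, impostor)) - 1e-9,
              max(c(genuine, impostor)) + 1e-9, length.out = n_grid)
  far <- vapply(grid, function(th) mean(impostor >= th), numeric(1))
  frr <- vapply(grid, function(th) mean(genuine < th), numeric(1))
  100 * far[which.min(abs(far - frr))]
}

# random cumulative spike wave built from random latencies
random_spike_wave <- function(tm, nf, H, W, p_never = 0.3) {
  tf <- array(sample(c(NA_integer_, 0:(tm - 1)), nf * H * W, replace = TRUE,
                     prob = c(p_never, rep((1 - p_never) / tm, tm))),
              dim = c(nf, H, W))
  s <- array(0, dim = c(tm, nf, H, W))
  for (t in 1:tm) s[t, , , ] <- as.numeric(!is.na(tf) & tf <= t - 1)
  spike_wave(s, tf)
}

# small random synthetic image set for encoder properties
random_image <- function(H = 24, W = 24) {
  matrix(runif(H * W, 0, 255), H, W)
}
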