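test_that("lateral inhibition keeps the earliest-then-strongest channel per pixel", {
  # single channel: identity
  set.seed(41)
  sw1 <- random_spike_wave(4, 1, 5, 5)
  tp1 <- conv_potentials(sw1, array(1, c(1, 1, 1, 1)))
  out1 <- lateral_inhibit_potentials(tp1, spike_wave((tp1 >= 1) * 1))
  expect_equal(out1$potentials, tp1)
  # hand case: spike times 1 vs 2, later channel has the larger potential
  tp <- array(0, c(3, 2, 1, 1)); sp <- array(0, c(3, 2, 1, 1))
  sp[1:3, 1, 1, 1] <- 1; tp[1:3, 1, 1, 1] <- c(1, 1, 1)      # fires at t=1
  sp[2:3, 2, 1, 1] <- 1; tp[2:3, 2, 1, 1] <- c(9, 9)         # fires at t=2
  out <- lateral_inhibit_potentials(tp, spike_wave(sp))
  expect_true(all(out$wave$s[, 2, 1, 1] == 0))
  expect_equal(out$wave$s[, 1, 1, 1], sp[, 1, 1, 1])
})

test_that("lateral inhibition matches the lexicographic-min oracle", {
  set.seed(42)
  for (rep in 1:5) {
    sw <- random_spike_wave(4, 5, 6, 6)
    tp <- array(runif(length(sw$s), 0.1, 2), dim(sw$s)) * sw$s
    out <- lateral_inhibit_potentials(tp, sw)
    tf <- oracle_first_spike(sw$s)
    for (h in 1:6) for (w in 1:6) {
      fired <- which(is.finite(tf[, h, w]))
      if (length(fired) == 0) next
      key <- cbind(tf[fired, h, w],
                   -vapply(fired, function(f) tp[tf[f, h, w], f, h, w], numeric(1)),
                   fired)
      best <- fired[order(key[, 1], key[, 2], key[, 3])[1]]
      for (f in 1:5) {
        if (f == best) {
          expect_equal(out$wave$s[, f, h, w], sw$s[, f, h, w])
        } else {
          expect_true(all(out$wave$s[, f, h, w] == 0))
          expect_true(all(out$potentials[, f, h, w] == 0))
        }
      }
    }
  }
})

test_that("spike inhibition only removes spikes and leaves one channel per pixel", {
  z <- spike_wave(array(0, c(3, 4, 5, 5)))
  expect_true(all(pointwise_spike_inhibition(z, array(0, dim(z$s)))$s == 0))
  set.seed(43)
  sw <- random_spike_wave(4, 4, 6, 6)
  tp <- array(runif(length(sw$s)), dim(sw$s)) * sw$s
  out <- pointwise_spike_inhibition(sw, tp)
  expect_true(all(out$s <= sw$s))           # removal only
  per_pixel <- apply(out$s[4, , , ], c(2, 3), function(col) sum(col > 0))
  expect_true(all(per_pixel <= 1))
  validate_spike_wave(out)
})

test_that("winner-take-all agrees with the exhaustive re-scan oracle", {
  set.seed(44)
  for (rep in 1:40) {
    sw <- random_spike_wave(4, 5, 6, 6, p_never = runif(1, 0.2, 0.9))
    tp <- array(round(runif(length(sw$s), 0.1, 3), 3), dim(sw$s)) * sw$s
    kwta <- sample(1:4, 1); r <- sample(0:2, 1)
    got <- get_k_winners(tp, competition_config(kwta, r), sw)
    want <- oracle_k_winners(tp, sw$s, kwta, r)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(unname(as.matrix(got)), unname(want))
    }
  }
})

test_that("winner lists are structurally valid and empty for silent tensors", {
  silent <- spike_wave(array(0, c(3, 4, 6, 6)))
  got <- get_k_winners(array(0, c(3, 4, 6, 6)), competition_config(3, 1), silent)
  expect_equal(nrow(got), 0)
  set.seed(45)
  sw <- random_spike_wave(5, 6, 8, 8, p_never = 0.4)
  tp <- array(runif(length(sw$s), 0.1, 1), dim(sw$s)) * sw$s
  got <- get_k_winners(tp, competition_config(4, 2), sw)
  expect_equal(anyDuplicated(got$f), 0)     # feature-map inhibition
  if (nrow(got) > 1) {
    for (i in 2:nrow(got)) for (j in 1:(i - 1)) {
      cheb <- max(abs(got$h[i] - got$h[j]), abs(got$w[i] - got$w[j]))
      expect_gt(cheb, 2)
    }
  }
})

test_that("STDP reproduces the stabilized update arithmetic", {
  # pre fires at t=1, post at t=2: pairing -> potentiation
  input <- spike_wave(array(c(0, 1, 1), c(3, 1, 1, 1)))
  output <- spike_wave(array(c(0, 0, 1), c(3, 1, 1, 1)))
  w <- array(0.5, c(1, 1, 1, 1))
  cfg <- plasticity_config(a_plus = 0.004, a_minus = -0.003)
  winners <- tibble::tibble(f = 1L, h = 1L, w = 1L)
  w2 <- stdp_update(input, output, winners, w, cfg)
  expect_equal(as.vector(w2 - w), 0.004 * 0.5 * 0.5)   # 0.001
  # at the bounds the stabilizer freezes the weight exactly
  for (wb in c(0, 1)) {
    wbnd <- array(wb, c(1, 1, 1, 1))
    expect_equal(stdp_update(input, output, winners, wbnd, cfg), wbnd)
  }
  # pre never fires while post does: depression
  input0 <- spike_wave(array(0, c(3, 1, 1, 1)))
  w3 <- stdp_update(input0, output, winners, w, cfg)
  expect_lt(as.vector(w3), 0.5)
  expect_equal(as.vector(w3 - w), -0.003 * 0.5 * 0.5)
})

test_that("only winning feature maps change and weights stay bounded", {
  set.seed(46)
  cfg <- plasticity_config()
  input <- random_spike_wave(5, 3, 8, 8)
  w <- init_weights(c(6, 3, 3, 3), seed = 5)
  v <- conv_potentials(input, w)
  out <- fire(v, sample_threshold(v))
  winners <- get_k_winners(out$potentials, competition_config(3, 1), out$wave)
  w2 <- stdp_update(input, out$wave, winners, w, cfg)
  unchanged <- setdiff(1:6, winners$f)
  for (f in unchanged) expect_identical(w2[f, , , ], w[f, , , ])
  for (f in winners$f) expect_false(identical(w2[f, , , ], w[f, , , ]))
  expect_true(all(w2 >= 0 & w2 <= 1))
})

test_that("the count-based pairing rule equals the spike-order rule", {
  # exhaustive over all cumulative pre/post latency patterns for small Tmax
  for (tm in 1:6) {
    for (pre_t in c(0:(tm - 1), NA)) for (post_t in c(0:(tm - 1), NA)) {
      pre_count <- if (is.na(pre_t)) 0 else tm - pre_t
      post_count <- if (is.na(post_t)) 0 else tm - post_t
      count_rule <- pre_count >= post_count
      order_rule <- (if (is.na(pre_t)) Inf else pre_t) <=
        (if (is.na(post_t)) Inf else post_t)
      expect_identical(count_rule, order_rule)
    }
  }
})

test_that("the learning-rate schedule doubles below the cap, keeping the ratio", {
  cfg <- plasticity_config(a_plus = 0.004, a_minus = -0.003, double_every = 500)
  cfg2 <- lr_schedule_step(cfg, 500)
  expect_equal(cfg2$a_plus, 0.008)
  expect_equal(cfg2$a_minus, -0.006)
  # not at a boundary: unchanged
  expect_equal(lr_schedule_step(cfg, 499)$a_plus, 0.004)
  expect_equal(lr_schedule_step(cfg, 0)$a_plus, 0.004)
  # above the cap: unchanged
  capped <- plasticity_config(a_plus = 0.16, a_minus = -0.12, double_every = 500)
  expect_equal(lr_schedule_step(capped, 500)$a_plus, 0.16)
  # ratio invariant over many doublings
  c3 <- cfg
  for (k in 1:6) c3 <- lr_schedule_step(c3, 500 * k)
  expect_equal(c3$a_minus / c3$a_plus, -0.75, tolerance = 1e-12)
  # disabled schedule never changes rates
  off <- plasticity_config(double_every = 0)
  expect_equal(lr_schedule_step(off, 500)$a_plus, off$a_plus)
})
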