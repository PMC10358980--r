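# helper: synthetic upstroke train, 50 mV/ms rise over 2 ms then slow decay
make_trace <- function(upstroke_times, n = 400) {
  x <- rep(-80, n)
  for (t0 in upstroke_times) {
    idx <- (t0 + 1):n
    shape <- pmax(0, 100 - 2 * (seq_along(idx) - 1))
    rise <- pmin(1, pmax(0, (seq_along(idx) - 1) / 2))
    x[idx] <- pmax(x[idx], -80 + rise[seq_along(idx)] * shape)
  }
  x
}

test_that("the AcT detector follows threshold, episode and refractory rules", {
  expect_length(detect_activations(rep(-80, 50)), 0)

  tr <- make_trace(c(100, 150))
  expect_equal(detect_activations(tr, detector_params(alpha = 0.2, beta = 100)),
               100)
  expect_equal(detect_activations(tr, detector_params(alpha = 0.2, beta = 25)),
               c(100, 150))
  # brute-force scan oracle agrees on randomized trains
  set.seed(21)
  for (rep_i in 1:20) {
    times <- sort(sample(20:350, sample(1:5, 1)))
    times <- times[c(TRUE, diff(times) > 10)]
    tr <- make_trace(times)
    for (beta in c(25, 60, 100)) {
      got <- detect_activations(tr, detector_params(alpha = 0.2, beta = beta))
      want <- detector_oracle(tr, alpha = 0.2, beta = beta)
      expect_equal(got, want)
    }
  }
})

test_that("the detector is idempotent and polarity-aware", {
  tr <- make_trace(c(80, 220))
  p <- detector_params(alpha = 0.2, beta = 100)
  expect_identical(detect_activations(tr, p), detect_activations(tr, p))
  # a negated trace is invisible to the positive detector (at a threshold
  # above the slow repolarization slope) but found by the negative one
  p5 <- detector_params(alpha = 5, beta = 100)
  expect_length(detect_activations(-tr - 160, p5), 0)
  pneg <- detector_params(alpha = 5, beta = 100, polarity = "negative")
  expect_equal(detect_activations(-tr, pneg), c(80, 220))
})

test_that("AcTs are insensitive to alpha and beta in the plateau range", {
  # seven sites from the paced-sheet fixture (analog of the sensitivity
  # analysis sites); identical AcT lists for alpha in 0.1..0.3 mV/ms and
  # beta in 100..150 ms
  f <- fixture_paced_sheet()
  sites <- c(200, 1500, 2800, 3280, 4100, 5400, 6400)
  for (s in sites) {
    ref <- detect_activations(f$record$vm[s, ],
                              detector_params(alpha = 0.2, beta = 100))
    for (alpha in c(0.1, 0.2, 0.3)) {
      for (beta in c(100, 150)) {
        expect_equal(detect_activations(
          f$record$vm[s, ], detector_params(alpha = alpha, beta = beta)), ref)
      }
    }
  }
})

test_that("state-space phase winds once per cycle and flags degeneracy", {
  # constant at the offset voltage: both atan2 arguments vanish
  rec <- list(vm = matrix(-30, 1, 100), times = 0:99, geometry = NULL)
  ph <- compute_phase(rec)
  expect_true(all(is.na(ph$theta)))

  # delay-embedded sinusoid around the offset: exactly 2*pi per 200 ms cycle
  t <- 0:999
  rec2 <- list(vm = matrix(-30 + 50 * sin(2 * pi * t / 200), 1),
               times = t, geometry = NULL)
  ph2 <- compute_phase(rec2)
  # winding over an integer number of periods (samples at t = 100..900)
  th <- ph2$theta[1, 101:901]
  wind <- sum(mapeval:::wrap_angle(diff(th)))
  expect_equal(abs(wind) / (2 * pi), 4, tolerance = 1e-6)

  # an action-potential-like periodic trace winds once per detected beat
  f <- fixture_paced_sheet()
  ph3 <- compute_phase(f$record)
  v <- f$record$vm[3280, ]
  beats <- length(detect_activations(v))
  th3 <- ph3$theta[3280, !is.na(ph3$theta[3280, ])]
  wind3 <- sum(mapeval:::wrap_angle(diff(th3)))
  expect_equal(round(abs(wind3) / (2 * pi)), beats)
})

test_that("phase singularities are located with correct charges", {
  g <- build_sheet_geometry(41, 41, 0.05)
  n <- nrow(g$nodes)
  # single synthetic rotor field at (1.03, 0.97)
  th1 <- atan2(g$nodes[, 2] - 0.97, g$nodes[, 1] - 1.03)
  ph <- list(theta = matrix(th1, n, 1), times = 0, delay = 0, offset = 30,
             geometry = g)
  class(ph) <- "phase_record"
  ps <- detect_surface_ps(ph, g, t = 0)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$charge, 1)
  d <- sqrt(sum((g$nodes[ps$node, 1:2] - c(1.03, 0.97))^2))
  expect_lt(d, 0.075)  # within ~1.5 mesh edges of the true core

  # planar phase ramp: no singularities
  ramp <- matrix(mapeval:::wrap_angle(4 * g$nodes[, 1]), n, 1)
  ph$theta <- ramp
  expect_equal(nrow(detect_surface_ps(ph, g, t = 0)), 0)

  # two-rotor field: charges +1 and -1, net zero
  th2 <- atan2(g$nodes[, 2] - 1, g$nodes[, 1] - 1.5) -
    atan2(g$nodes[, 2] - 1, g$nodes[, 1] - 0.5)
  ph$theta <- matrix(mapeval:::wrap_angle(th2), n, 1)
  ps2 <- detect_surface_ps(ph, g, t = 0)
  expect_equal(nrow(ps2), 2)
  expect_setequal(ps2$charge, c(-1, 1))
  expect_equal(sum(ps2$charge), 0)
})

test_that("total charge on a closed shell is zero for smooth fields", {
  sh <- build_shell_geometry(1, 3)
  n <- nrow(sh$nodes)
  # dipole-like smooth phase pattern (azimuth around z): +1 and -1 at poles
  th <- atan2(sh$nodes[, 2], sh$nodes[, 1])
  ph <- list(theta = matrix(th, n, 1), times = 0, delay = 0, offset = 30,
             geometry = sh)
  class(ph) <- "phase_record"
  ps <- detect_surface_ps(ph, sh, t = 0)
  expect_equal(sum(ps$charge), 0)
})

test_that("PS density counts are conserved", {
  g <- build_sheet_geometry(21, 21, 0.1)
  # pinned PS at node 150 for 40 frames
  series <- replicate(40, data.frame(node = 150L, charge = 1L),
                      simplify = FALSE)
  names(series) <- as.character(seq(1000, 1039))
  dens <- ps_density(series, nrow(g$nodes))
  expect_equal(dens[150], 40L)
  expect_equal(sum(dens), 40L)

  # meandering synthetic trace: counts sum to total occurrences
  set.seed(4)
  nodes <- sample(seq_len(nrow(g$nodes)), 60, replace = TRUE)
  series2 <- lapply(seq_along(nodes), function(i)
    data.frame(node = nodes[i], charge = sample(c(-1L, 1L), 1)))
  names(series2) <- as.character(seq_along(nodes))
  expect_equal(sum(ps_density(series2, nrow(g$nodes))), 60L)
  expect_error(ps_density(list(), 10), "empty")

  # empty frames give an all-zero map
  series3 <- list(`1` = data.frame(node = integer(0), charge = integer(0)))
  expect_true(all(ps_density(series3, nrow(g$nodes)) == 0))
})

test_that("k-means source clustering recovers seeded synthetic clusters", {
  set.seed(33)
  sd_j <- 0.05
  c1 <- c(0.5, 0.5, 0); c2 <- c(1.6, 1.4, 0)
  occ <- data.frame(
    t = seq_len(200), node = seq_len(200),
    charge = rep(c(1L, -1L), each = 100),
    x = c(rnorm(100, c1[1], sd_j), rnorm(100, c2[1], sd_j)),
    y = c(rnorm(100, c1[2], sd_j), rnorm(100, c2[2], sd_j)),
    z = 0)
  src <- cluster_reentry_sources(occ, seed = 7)
  expect_setequal(names(src), c("R+", "R-"))
  expect_lt(sqrt(sum((src[["R+"]]$location - c1)^2)), 2 * sd_j)
  expect_lt(sqrt(sum((src[["R-"]]$location - c2)^2)), 2 * sd_j)
  # two exact point clusters: centers equal the per-cluster means exactly
  occ2 <- occ
  occ2$x <- rep(c(c1[1], c2[1]), each = 100)
  occ2$y <- rep(c(c1[2], c2[2]), each = 100)
  src2 <- cluster_reentry_sources(occ2, seed = 7)
  expect_equal(unname(src2[["R+"]]$location), c1)
  expect_equal(unname(src2[["R-"]]$location), c2)
  # all occurrences at one point is degenerate
  occ3 <- occ2; occ3$x <- 1; occ3$y <- 1
  expect_error(cluster_reentry_sources(occ3, seed = 1), "degenerate")
})
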