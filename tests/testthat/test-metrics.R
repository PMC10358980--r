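test_that("performance-metric arithmetic reproduces the published integers", {
  expect_equal(actpm(1, 0), 100)
  expect_equal(actpm(0.5, 0.5), 25)
  expect_equal(actpm(0, 0.7), 0)
  expect_error(actpm(1.2, 0), "0, 1")

  expect_equal(round(acppm(4 / 6, 0, 0)), 67)
  expect_equal(round(acppm(5 / 6, 0, 0)), 83)
  expect_equal(round(acppm(2 / 6, 0, 0)), 33)
  expect_equal(round(acppm(1 / 6, 0, 0)), 17)
  expect_equal(acppm(1, 0, 0), 100)
  expect_equal(acppm(5 / 6, 0, 1 / 6), 500 / 6 * 5 / 6, tolerance = 1e-12)
  expect_error(acppm(0.5, 0.5, 2), "0, 1")
})

test_that("compare_act handles the worked examples exactly", {
  truth <- list(`1` = c(100, 300))
  r1 <- compare_act(list(e1 = c(100, 300)), truth, 1, tol = 5)
  expect_equal(r1$fC, 1); expect_equal(r1$fS, 0)
  expect_equal(r1$rms, 0); expect_equal(r1$actpm, 100)

  r2 <- compare_act(list(e1 = c(100.5, 299)), truth, 1, tol = 2)
  expect_equal(r2$fC, 1); expect_equal(r2$fS, 0)
  expect_equal(r2$rms, sqrt((0.25 + 1) / 2))

  r3 <- compare_act(list(e1 = c(100.5, 299)), truth, 1, tol = 0.4)
  expect_equal(r3$fC, 0); expect_equal(r3$fS, 1)
  expect_equal(r3$actpm, 0)

  expect_error(compare_act(list(e1 = 1), truth, 1, tol = -1), ">= 0")
})

test_that("fS is capped at one and fractions stay within bounds", {
  truth <- list(`1` = 100)
  r <- compare_act(list(e1 = c(10, 20, 30, 40)), truth, 1, tol = 1)
  expect_equal(r$fS, 1)
  expect_equal(r$fC, 0)
  expect_gte(r$actpm, 0); expect_lte(r$actpm, 100)
})

test_that("greedy matching achieves the optimal match count on small instances", {
  set.seed(17)
  for (case in 1:60) {
    nm <- sample(0:6, 1); nt <- sample(1:6, 1)
    measured <- sort(round(runif(nm, 0, 100), 1))
    truth <- sort(round(runif(nt, 0, 100), 1))
    tol <- sample(c(1, 5, 20), 1)
    m <- mapeval:::match_act_times(measured, truth, tol)
    expect_equal(nrow(m), optimal_match_count(measured, truth, tol))
    # one-to-one
    expect_equal(anyDuplicated(m$truth), 0)
    expect_equal(anyDuplicated(m$measured), 0)
  }
})

test_that("AcTPM is monotone and the spurious rate anti-monotone in Tol", {
  set.seed(29)
  truth <- list(`1` = c(100, 300, 500), `2` = c(120, 320, 520))
  egm <- list(e1 = c(101.5, 298, 430, 503), e2 = c(118, 326, 519))
  sw <- tolerance_sweep(egm, truth, c(1, 2), tol_values = c(0, 1, 2, 5, 10, 30))
  expect_true(all(diff(sw$actpm) >= 0))
  expect_true(all(diff(sw$pS) <= 0))
  # perfect data: flat at 100
  sw0 <- tolerance_sweep(list(e1 = c(100, 300, 500)), truth["1"], 1,
                         tol_values = c(0, 1, 5))
  expect_true(all(sw0$actpm == 100))
  # 1-ms jitter reaches its plateau by tol = 2
  jit <- list(e1 = c(101, 299, 501), e2 = c(119, 321, 519))
  swj <- tolerance_sweep(jit, truth, c(1, 2), tol_values = c(2, 5, 50))
  expect_equal(swj$actpm, rep(100, 3))
  expect_error(tolerance_sweep(egm, truth, c(1, 2), numeric(0)), "non-empty")
})

test_that("a pure time shift keeps matching intact and sets RMS to the shift", {
  truth <- list(`1` = c(100, 300, 500))
  shift <- 1.5
  r <- compare_act(list(e1 = c(100, 300, 500) + shift), truth, 1, tol = 2)
  expect_equal(r$fC, 1); expect_equal(r$fS, 0)
  expect_equal(r$rms, shift)
})

test_that("pattern comparison applies both matching windows and Eq-6 counts", {
  arr <- electrode_array(c("a", "b", "c"),
                         rbind(c(0, 0, 0), c(0.5, 0, 0), c(3, 0, 0)),
                         c(1, 3))
  truth <- data.frame(type = rep("R+", 6), beat = 1:6,
                      x = 0.2, y = 0, z = 0,
                      ref_time = seq(100, 1100, by = 200))
  # 4 of 6 beats detected at a nearby electrode, nothing spurious
  det <- data.frame(electrode = "a", time = truth$ref_time[1:4] + 10,
                    type = "R+", stringsAsFactors = FALSE)
  rep1 <- compare_patterns(det, truth, arr)
  row <- rep1$per_type[rep1$per_type$type == "R+", ]
  expect_equal(row$n_correct, 4)
  expect_equal(round(row$acppm), 67)
  expect_lte(row$E_X, 1)

  # a detection 1.2 cm away from the source is outside the spatial window
  det2 <- data.frame(electrode = "c", time = 110, type = "R+",
                     stringsAsFactors = FALSE)
  rep2 <- compare_patterns(det2, truth, arr)
  row2 <- rep2$per_type[rep2$per_type$type == "R+", ]
  expect_equal(row2$n_correct, 0)
  expect_equal(row2$n_spurious, 1)

  # 5 correct and 1 misclassified (detected with the wrong chirality)
  det3 <- rbind(
    data.frame(electrode = "a", time = truth$ref_time[1:5] + 5, type = "R+"),
    data.frame(electrode = "a", time = truth$ref_time[6] + 5, type = "R-"))
  rep3 <- compare_patterns(det3, truth, arr)
  row3 <- rep3$per_type[rep3$per_type$type == "R+", ]
  expect_equal(row3$n_correct, 5)
  expect_equal(row3$n_misclassified, 1)
  expect_equal(row3$acppm, (5 / 6) * (5 / 6) * 100, tolerance = 1e-9)

  # temporal localization error reported for paced/focal beats only
  truth_f <- data.frame(type = "F+", beat = 1, x = 0.2, y = 0, z = 0,
                        ref_time = 250)
  det_f <- data.frame(electrode = "b", time = 257, type = "F+",
                      stringsAsFactors = FALSE)
  rep_f <- compare_patterns(det_f, truth_f, arr)
  expect_equal(rep_f$per_type$E_T, 7)
  expect_equal(rep_f$per_type$E_X, 0.3)
})

test_that("duplicate same-type detections are neither correct nor spurious", {
  arr <- electrode_array(c("a", "b"), rbind(c(0, 0, 0), c(0.3, 0, 0)),
                         c(1, 2))
  truth <- data.frame(type = "F+", beat = 1, x = 0.1, y = 0, z = 0,
                      ref_time = 100)
  det <- data.frame(electrode = c("a", "b"), time = c(102, 104),
                    type = "F+", stringsAsFactors = FALSE)
  rep <- compare_patterns(det, truth, arr)
  row <- rep$per_type
  expect_equal(row$n_correct, 1)
  expect_equal(row$n_spurious, 0)
  expect_equal(sum(rep$detections$role == "duplicate"), 1)
  # the spatially nearest detection is the one credited
  expect_equal(rep$detections$electrode[rep$detections$role == "correct"], "a")
})
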