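test_that("spin-echo signal follows the closed form and rejects bad input", {
  expect_equal(spin_echo_signal(0, 1000, 100, 5000, 23), 0)
  expect_equal(spin_echo_signal(1, 1000, 100, 1e12, 0), 1)
  expect_equal(spin_echo_signal(1, 1000, 100, 5000, 23),
               (1 - exp(-5)) * exp(-0.23))
  expect_error(spin_echo_signal(1, -5, 100, 5000, 23), "positive")
  expect_error(spin_echo_signal(1, 1000, 0, 5000, 23), "positive")
})

test_that("kinetic model matches the numerical convolution oracle", {
  for (scheme in c("PCASL", "PASL")) {
    p <- asl_protocol(scheme)
    for (f in c(20, 50, 250)) {
      for (att in c(0, 500, 1123, 1141, 2000, 3500)) {
        closed <- gkm_delta_m(f, 1, p, att)
        oracle <- gkm_convolution_oracle(f, 1, p, att)
        expect_equal(closed, oracle, tolerance = 1e-10,
                     label = sprintf("%s f=%g att=%g", scheme, f, att))
      }
    }
  }
})

test_that("PCASL difference signal magnitude and transit-time independence", {
  p <- asl_protocol("PCASL")
  expect_equal(gkm_delta_m(250, 1, p, 1141), 0.034, tolerance = 0.02)
  vals <- vapply(c(0, 500, 1141), function(att) gkm_delta_m(250, 1, p, att),
                 numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
  # beyond the post-labeling delay the signal decreases
  expect_lt(gkm_delta_m(250, 1, p, 2000), vals[1])
})

test_that("difference signal is monotone in f and alpha and linear in m0", {
  p <- asl_protocol("PCASL")
  f <- seq(0, 400, by = 50)
  dm <- gkm_delta_m(f, 1, p, 1141)
  expect_true(all(diff(dm) > 0))
  expect_equal(gkm_delta_m(250, 3, p, 1141), 3 * gkm_delta_m(250, 1, p, 1141))
  p2 <- asl_protocol("PCASL", alpha = 0.95)
  expect_gt(gkm_delta_m(250, 1, p2, 1141), gkm_delta_m(250, 1, p, 1141))
  expect_equal(gkm_delta_m(0, 1, p, 1141), 0)
  expect_error(gkm_delta_m(-5, 1, p, 0), ">= 0")
})

test_that("control, label and M0 images obey the suppression contract", {
  tab <- default_tissue_table()
  p <- asl_protocol("PCASL")
  lab <- matrix(c(0, 1, 4, 5), 2, 2)  # background, body, cortex_l, medulla_l
  perf <- matrix(c(0, 0, 250, 50), 2, 2)
  att <- matrix(c(0, 0, 1141, 1123), 2, 2)
  img <- make_control_label_m0(lab, tab, p, perf, att)
  nz <- img$m0 > 0
  expect_true(all(abs(img$control[nz] / img$m0[nz] - 0.2) < 1e-12))
  # no perfusion -> control equals label exactly
  img0 <- make_control_label_m0(lab, tab, p, matrix(0, 2, 2), att)
  expect_identical(img0$control, img0$label)
  # cortex carries more difference signal than medulla (f ratio 5)
  dm <- img$control - img$label
  expect_gt(dm[lab == 4] / img$m0[lab == 4], dm[lab == 5] / img$m0[lab == 5])
  expect_error(make_control_label_m0(lab, tab, p, matrix(0, 3, 3), att),
               "grid")
})

test_that("negative label intensities are clipped with a warning", {
  tab <- default_tissue_table()
  tab$perfusion[tab$name == "cortex_left"] <- 0
  tab$perfusion <- tab$perfusion  # keep table valid
  p <- asl_protocol("PCASL")
  lab <- matrix(4, 12, 12)
  perf <- matrix(50000, 12, 12)   # absurd perfusion forces label < 0
  att <- matrix(0, 12, 12)
  expect_warning(make_control_label_m0(lab, default_tissue_table(), p,
                                       perf, att), "clipped")
})

test_that("scheme-specific protocol timing access is guarded", {
  p <- asl_protocol("PCASL")
  expect_equal(protocol_timing(p, "pld_ms"), 1200)
  expect_error(protocol_timing(p, "ti_ms"), "not defined for scheme")
  expect_error(asl_protocol("PASL", pld_ms = 100), "do not apply")
  expect_error(asl_protocol("PCASL", alpha = 1.5), "alpha")
})
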