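linear_series <- function(slope, t = seq(0, 120, 3), intercept = 10) {
  data.frame(time_h = t, confluence_pct = intercept + slope * t)
}

delta_curves <- function(deltas_by_dose, doses = 10^(0:4), n_reps = 3,
                         vehicle_delta = 32) {
  # straight-line series whose 40-72 h (and 96-120 h) change equals the
  # requested per-dose delta
  conds <- c(0, doses)
  slopes <- c(vehicle_delta, deltas_by_dose) / 32
  do.call(rbind, lapply(seq_along(conds), function(i) {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      s <- linear_series(slopes[i])
      data.frame(cell_line = "L", compound = "C", concentration_nM = conds[i],
                 replicate = r, time_h = s$time_h,
                 confluence_pct = s$confluence_pct)
    }))
  }))
}

test_that("window deltas interpolate linearly between 3-hourly samples", {
  flat <- linear_series(0)
  expect_equal(window_delta(flat, 40, 72), 0)
  lin <- linear_series(1)
  expect_equal(window_delta(lin, 40, 72), 32)
  # 40 h is between the 39 h and 42 h samples
  s <- data.frame(time_h = seq(0, 120, 3),
                  confluence_pct = c(rep(10, 14), seq(13, 91, 3)))
  v39 <- s$confluence_pct[s$time_h == 39]
  v42 <- s$confluence_pct[s$time_h == 42]
  expect_equal(window_delta(s, 40, 42),
               v42 - (v39 + (v42 - v39) / 3))
  expect_error(window_delta(lin, 100, 130), "outside")
})

test_that("growth-reducing concentration is the lowest dose with a significant decrease", {
  cv <- delta_curves(c(32, 32, 10, 10, 10))
  expect_equal(growth_reducing_concentration(cv), 100)
  # identical groups: nothing to call
  expect_true(is.na(growth_reducing_concentration(
    delta_curves(rep(32, 5)))))
  # effect only at the top dose
  expect_equal(growth_reducing_concentration(
    delta_curves(c(32, 32, 32, 32, 5))), 1e4)
})

test_that("growth-reducing call requires a vehicle arm and replicates", {
  cv <- delta_curves(c(32, 32, 10, 10, 10))
  expect_error(growth_reducing_concentration(cv[cv$concentration_nM > 0, ]),
               "vehicle")
  one_rep <- cv[cv$replicate == 1, ]
  expect_error(growth_reducing_concentration(one_rep), "replicates")
})

test_that("growth-arresting concentration is the minimal dose with < 3 points gain", {
  cv <- delta_curves(c(8, 6, 2.9, 0.5, 0.1) * 32 / 24)
  # 96-120 h delta of a line with slope s/32*... : slope * 24
  d <- vapply(split(cv[cv$concentration_nM > 0, ],
                    cv$concentration_nM[cv$concentration_nM > 0]),
              window_delta, numeric(1), t0 = 96, t1 = 120)
  expect_equal(unname(d[order(as.numeric(names(d)))]),
               c(8, 6, 2.9, 0.5, 0.1), tolerance = 1e-9)
  expect_equal(growth_arresting_concentration(cv), 100)
  expect_true(is.na(growth_arresting_concentration(
    delta_curves(rep(32, 5)))))
})

test_that("planted kinetic thresholds are recovered exactly without noise", {
  for (mult in list(c(1, 1, 0.5, 0, 0), c(1, 1, 1, 0.5, 0),
                    c(1, 0.5, 0.5, 0, 0), c(1, 1, 1, 1, 0))) {
    tr <- make_growth_fixture(multipliers = mult)
    cv <- gen_growth_curves(tr, n_reps = 2, noise_sd = 0, seed = 1)
    expect_equal(growth_reducing_concentration(cv), planted_reducing(mult))
    expect_equal(growth_arresting_concentration(cv), planted_arrest(mult))
    # arrest never precedes reduction on monotone dose-effect truths
    expect_gte(growth_arresting_concentration(cv),
               growth_reducing_concentration(cv))
  }
})

test_that("kinetic calls ignore replicate order and duplicated sample rows", {
  tr <- make_growth_fixture()
  cv <- gen_growth_curves(tr, n_reps = 3, noise_sd = 1, seed = 21)
  shuffled <- cv[sample(nrow(cv)), ]
  dup <- rbind(cv, cv)
  expect_equal(growth_arresting_concentration(shuffled),
               growth_arresting_concentration(cv))
  expect_equal(growth_arresting_concentration(dup),
               growth_arresting_concentration(cv))
  expect_equal(growth_reducing_concentration(shuffled),
               growth_reducing_concentration(cv))
})

test_that("reversibility is judged on post-withdrawal regrowth", {
  flat <- data.frame(cell_line = "L", compound = "C", concentration_nM = 10,
                     replicate = 1, time_h = seq(0, 192, 3),
                     confluence_pct = 30, withdrawal_at = 120)
  expect_false(classify_reversibility(flat))
  grow <- flat
  grow$confluence_pct <- ifelse(grow$time_h <= 120, 30,
                                30 + 20 * (grow$time_h - 120) / 72)
  expect_true(classify_reversibility(grow))
  expect_error(classify_reversibility(flat[flat$time_h <= 150, ]),
               "72 h past withdrawal")

  trR <- make_growth_fixture(multipliers = rep(0, 5), reversible = TRUE)
  cvR <- gen_growth_curves(trR, t_grid = seq(0, 192, 3), n_reps = 3,
                           withdrawal_at = 120, noise_sd = 1, seed = 4)
  expect_true(classify_reversibility(cvR[cvR$concentration_nM == 100, ]))
  trI <- make_growth_fixture(multipliers = rep(0, 5), reversible = FALSE)
  cvI <- gen_growth_curves(trI, t_grid = seq(0, 192, 3), n_reps = 3,
                           withdrawal_at = 120, noise_sd = 1, seed = 4)
  expect_false(classify_reversibility(cvI[cvI$concentration_nM == 100, ]))
})

test_that("apoptosis categories use the 5 and 15 point thresholds strictly", {
  expect_identical(as.character(classify_apoptosis(c(16, 5, 7, 15, 5.01, -2))),
                   c("strong", "none", "moderate", "moderate", "moderate",
                     "none"))
})

test_that("cell-cycle filter keeps only shifts above 5 points in some phase", {
  s <- data.frame(cell_line = c("A", "B", "C"), compound = "X",
                  G1 = c(6, 5, 0), S = c(0, 2, 5), G2 = c(0, 1, 4.9))
  kept <- cell_cycle_shift_filter(s)
  expect_identical(kept$cell_line, "A")
  empty <- cell_cycle_shift_filter(s[0, ])
  expect_identical(nrow(empty), 0L)
})
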