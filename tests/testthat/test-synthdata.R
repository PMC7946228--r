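test_that("plate generator reproduces control anchors for a noise-free step response", {
  # infinitely steep curve with full kill: low doses at the DMSO level,
  # high doses at the BzCl floor
  tr <- screen_truth("L1", "C1", e_inf = 0, ec50 = 100, hill = 50)
  w <- gen_plate(list(tr), noise_cv = 0, neg_level = 1000, pos_frac = 0.01,
                 seed = 1)
  drug <- w[w$role == "drug", ]
  drug <- drug[order(drug$concentration_nM), ]
  neg_mean <- mean(w$signal[w$role == "neg_ctrl"])
  pos_mean <- mean(w$signal[w$role == "pos_ctrl"])
  expect_equal(drug$signal[1:2], rep(neg_mean, 2), tolerance = 1e-9)
  expect_equal(drug$signal[4:5], rep(pos_mean, 2), tolerance = 1e-9)
})

test_that("generators are deterministic given the seed and layouts are validated", {
  tr <- screen_truth("L1", "C1", e_inf = 0.2, ec50 = 50, hill = 1)
  w1 <- gen_plate(list(tr), noise_cv = 0.1, seed = 42)
  w2 <- gen_plate(list(tr), noise_cv = 0.1, seed = 42)
  expect_identical(w1, w2)
  w3 <- gen_plate(list(tr), noise_cv = 0.1, seed = 43)
  expect_false(identical(w1$signal, w3$signal))

  many <- lapply(1:80, function(i)
    screen_truth("L1", paste0("C", i), 0, 100, 1))
  expect_error(gen_plate(many), "384")

  tr_g <- make_growth_fixture()
  expect_identical(gen_growth_curves(tr_g, seed = 7),
                   gen_growth_curves(tr_g, seed = 7))
  expect_error(gen_growth_curves(tr_g, t_grid = c(0, 3, 3, 6)),
               "strictly increasing")
})

test_that("DMSO wells realize the requested noise level", {
  tr <- screen_truth("L1", "C1", 0, 100, 1)
  w <- gen_plate(list(tr), n_neg = 32, n_pos = 16, noise_cv = 0.05,
                 neg_level = 1000, seed = 11)
  neg <- w$signal[w$role == "neg_ctrl"]
  cv <- sd(neg) / mean(neg)
  expect_gt(cv, 0.03)
  expect_lt(cv, 0.07)
})

test_that("growth generator honours arrest, vehicle growth and withdrawal", {
  tr <- make_growth_fixture(multipliers = c(1, 1, 1, 1, 0))
  cv <- gen_growth_curves(tr, n_reps = 1, noise_sd = 0, seed = 1)
  top <- cv[cv$concentration_nM == 1e4, ]
  expect_equal(window_delta(top, 96, 120), 0, tolerance = 1e-9)

  veh <- cv[cv$concentration_nM == 0, ]
  expect_true(all(diff(veh$confluence_pct) > 0))
  expect_true(all(veh$confluence_pct <= tr$carrying_capacity))

  trR <- make_growth_fixture(multipliers = c(0, 0, 0, 0, 0),
                             reversible = TRUE)
  cvR <- gen_growth_curves(trR, t_grid = seq(0, 192, 3), n_reps = 1,
                           withdrawal_at = 120, noise_sd = 0, seed = 1)
  one <- cvR[cvR$concentration_nM == 10, ]
  gain_arrested <- window_delta(one, 48, 120)
  gain_after <- window_delta(one, 120, 192)
  expect_gt(gain_after, gain_arrested)
})

test_that("GR assay counts invert the GR transform exactly", {
  # no effect: treated equals control
  t_none <- gr_truth("L1", "C1", gr_inf = 1, gec50 = 10, hill = 1)
  a <- gen_gr_assay(list(t_none), concentrations = 10^(0:4))
  expect_equal(gr_transform(a$x0, a$x_ctrl, a$x_c), rep(1, 5),
               tolerance = 1e-12)

  # deep cytostasis at saturating dose: treated frozen at baseline
  t_stat <- gr_truth("L1", "C2", gr_inf = 0, gec50 = 1, hill = 5)
  a2 <- gen_gr_assay(list(t_stat), concentrations = 1e5)
  expect_equal(gr_transform(a2$x0, a2$x_ctrl, a2$x_c), 0, tolerance = 1e-9)
  expect_equal(a2$x_c, a2$x0, tolerance = 1e-6)

  # generic round trip across the dose range
  t_mid <- gr_truth("L1", "C3", gr_inf = -0.7, gec50 = 30, hill = 1.3)
  a3 <- gen_gr_assay(list(t_mid))
  expect_equal(gr_transform(a3$x0, a3$x_ctrl, a3$x_c),
               true_gr(t_mid, a3$concentration_nM), tolerance = 1e-12)
})

test_that("expression generator plants exact monotone biomarkers when noiseless", {
  gr50 <- matrix(10^seq(0.5, 2.9, length.out = 13), nrow = 1,
                 dimnames = list("C1", sprintf("L%02d", 1:13)))
  tru <- expression_truth(
    data.frame(gene = c("SENS1", "RES1"), compound = "C1",
               direction = c("sensitizing", "resistance"),
               effect_size = 5),
    n_genes = 100, n_lines = 13)
  ex <- gen_expression(tru, gr50, noise_sd = 0, seed = 3)
  rho_s <- cor(ex$fpkm["SENS1", ], gr50["C1", ], method = "spearman")
  rho_r <- cor(ex$fpkm["RES1", ], gr50["C1", ], method = "spearman")
  expect_equal(rho_s, -1)
  expect_equal(rho_r, 1)
  expect_true(all(is.finite(ex$fpkm)) && all(ex$fpkm >= 0))

  # the unexpressed fraction is below the floor in every line
  off <- apply(ex$fpkm, 1, function(x) all(x < 10))
  expect_equal(sum(off), 10)  # frac_unexpressed 0.1 of 100 genes
  expect_equal(nrow(filter_expressed(ex$fpkm)), 90)
})

test_that("background-only matrices stay consistent with the null association rate", {
  gr50 <- matrix(10^seq(0, 3, length.out = 13), nrow = 1,
                 dimnames = list("C1", sprintf("L%02d", 1:13)))
  tru <- expression_truth(data.frame(), n_genes = 1000, n_lines = 13,
                          frac_unexpressed = 0)
  ex <- gen_expression(tru, gr50, seed = 9)
  assoc <- correlate_gene_drug(log10(ex$fpkm), gr50["C1", ])
  # P(|rho| >= 0.65 and p < 0.05) under the null at n = 13 is about 0.02;
  # a binomial bound at 1000 genes keeps the count well under 45
  expect_lt(sum(assoc$passes_single), 45)
})

test_that("gene-set generator validates inputs and deduplicates planted sets", {
  expect_error(gen_gene_sets(character(0), 5), "empty")
  s0 <- gen_gene_sets(letters, 0, set_size_range = c(2, 5))
  expect_length(s0, 0)
  path <- tempfile(fileext = ".gmt")
  write_gmt(s0, path)
  expect_identical(readLines(path), character(0))

  expect_warning(
    s1 <- gen_gene_sets(letters, 0, set_size_range = c(2, 5),
                        planted_set = c("a", "b", "a")),
    "duplicate")
  expect_identical(s1$PLANTED_SET, c("a", "b"))
})

test_that("gene sets round-trip through GMT and expression through GCT", {
  sets <- gen_gene_sets(paste0("G", 1:60), 4, set_size_range = c(5, 10),
                        seed = 2)
  p <- tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  expect_identical(read_gmt(p), sets)

  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  pg <- tempfile(fileext = ".gct")
  write_gct(m, pg)
  expect_equal(read_gct(pg), m, tolerance = 1e-12)
})
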