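lines13 <- sprintf("L%02d", 1:13)

test_that("duplicate gene rows are resolved by highest standard deviation", {
  m <- rbind(c(1, 2, 30), c(5, 5.1, 5.2), c(0, 0, 0.1))
  rownames(m) <- c("A", "A", "B")
  colnames(m) <- paste0("S", 1:3)
  out <- preprocess_expression(m)
  expect_identical(sort(rownames(out)), c("A", "B"))
  # the high-SD row of A ranks above B in every sample, the low-SD row
  # would not have in sample 1
  expect_true(all(out["A", ] > out["B", ]))
  expect_error(preprocess_expression(-m), "non-negative")
})

test_that("quantile normalization fixes identical columns and matches a hand-worked case", {
  m <- matrix(c(5, 2, 9, 5, 2, 9), ncol = 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  out <- preprocess_expression(m)
  expect_equal(out[, 1], out[, 2])

  # 3 x 2 toy: columns (2, 4, 6) and (3, 1, 5); rank-wise reference means
  # are (mean(2,1), mean(4,3), mean(6,5)) = (1.5, 3.5, 5.5)
  m2 <- matrix(c(2, 4, 6, 3, 1, 5), ncol = 2,
               dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  out2 <- preprocess_expression(m2)
  expect_equal(10^out2[, "S1"] - 1e-5, c(A = 1.5, B = 3.5, C = 5.5),
               tolerance = 1e-9)
  expect_equal(10^out2[, "S2"] - 1e-5, c(A = 3.5, B = 1.5, C = 5.5),
               tolerance = 1e-9)
})

test_that("the expression floor drops only genes below it in every line", {
  m <- rbind(rep(9.9, 13), c(rep(9.9, 12), 10.1), rep(300, 13))
  rownames(m) <- c("ALL_LOW", "ONE_HIGH", "HIGH")
  colnames(m) <- lines13
  out <- filter_expressed(m)
  expect_identical(rownames(out), c("ONE_HIGH", "HIGH"))
  expect_identical(filter_expressed(m, floor = 0), m)
})

test_that("gene-drug correlation is a rank statistic with t-approximate p-values", {
  resp <- setNames(10^seq(0, 3, length.out = 13), lines13)
  m <- rbind(UP = resp^0.3,             # strictly increasing transform
             DOWN = max(resp) - resp,
             CONST = rep(1, 13))
  colnames(m) <- lines13
  a <- correlate_gene_drug(m, resp)
  expect_equal(a$rho[a$gene == "UP"], 1)
  expect_equal(a$p_value[a$gene == "UP"], 0)
  expect_equal(a$rho[a$gene == "DOWN"], -1)
  expect_identical(a$direction[a$gene == "DOWN"], "sensitizing")
  expect_true(is.na(a$rho[a$gene == "CONST"]))
  expect_identical(a$reason[a$gene == "CONST"], "constant expression")

  # reversing the response negates rho and preserves p
  m2 <- rbind(G = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9))
  colnames(m2) <- lines13
  a_f <- correlate_gene_drug(m2, resp)
  a_r <- correlate_gene_drug(m2, setNames(rev(unname(resp)), lines13))
  expect_equal(a_r$rho, -a_f$rho, tolerance = 1e-12)
  expect_equal(a_r$p_value, a_f$p_value, tolerance = 1e-12)

  # invariance under strictly monotone transforms of either variable
  a_log <- correlate_gene_drug(log10(m2), log10(resp))
  expect_equal(a_log$rho, a_f$rho, tolerance = 1e-12)
  expect_error(correlate_gene_drug(m2[, 1:3], resp[1:3]), "4 shared")
})

test_that("the t approximation tracks the exact permutation p at n = 6", {
  set.seed(14)
  resp <- setNames(c(2, 5, 1, 9, 4, 7), paste0("L", 1:6))
  for (i in 1:5) {
    m <- matrix(rnorm(6), 1, dimnames = list("G", names(resp)))
    a <- correlate_gene_drug(m, resp)
    p_exact <- spearman_perm_p(as.numeric(m), unname(resp))
    expect_lt(abs(a$p_value - p_exact), 0.07)
  }
})

test_that("leave-one-out selection keeps planted monotone genes and rejects outlier-driven ones", {
  resp <- setNames(10^seq(0.2, 2.8, length.out = 13), lines13)
  planted <- resp^0.5
  outlier <- c(rep(1, 12), 1e6)  # association exists only through L13
  noise <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9)
  m <- rbind(PLANTED = planted, OUTLIER = outlier, NOISE = noise)
  colnames(m) <- lines13
  sel <- loo_robust_biomarkers(m, resp)
  expect_identical(sel$gene, "PLANTED")
  expect_equal(sel$rho_full, 1)
  expect_equal(sel$rho_min, 1)
  expect_identical(sel$direction, "resistance")
  # the outlier gene fails precisely because the fold dropping L13 kills it
  drop13 <- suppressWarnings(
    cor(outlier[-13], unname(resp)[-13], method = "spearman"))
  expect_true(is.na(drop13) || abs(drop13) < 0.8)
  expect_error(loo_robust_biomarkers(m[, 1:4], resp[1:4]), "5 shared")
})

test_that("null background matrices yield essentially no robust biomarkers", {
  resp <- setNames(10^seq(0, 3, length.out = 13), lines13)
  counts <- vapply(1:10, function(s) {
    set.seed(s)
    m <- matrix(rnorm(400 * 13), 400, 13,
                dimnames = list(sprintf("G%03d", 1:400), lines13))
    nrow(loo_robust_biomarkers(m, resp))
  }, numeric(1))
  expect_lt(mean(counts), 0.5)
})

test_that("enrichment scores match the brute-force running sum", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    scores <- setNames(rnorm(n), paste0("g", seq_len(n)))
    k <- sample(3:max(3, n %/% 3), 1)
    set <- sample(names(scores), k)
    r <- gsea_preranked(scores, list(S = set), n_perm = 10, seed = 1,
                        min_size = 1, max_size = n - 1)
    expect_equal(r$es, es_brute(scores, set), tolerance = 1e-12)
  }
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  set.seed(61)
  scores <- setNames(rnorm(120), paste0("g", 1:120))
  for (k in c(10, 25, 40)) {
    set <- sample(names(scores), k)
    r <- gsea_preranked(scores, list(S = set), n_perm = 10, seed = 1,
                        min_size = 1, max_size = 119)
    s_sorted <- sort(scores, decreasing = TRUE)
    es_ref <- fgsea::calcGseaStat(s_sorted,
                                  which(names(s_sorted) %in% set),
                                  gseaParam = 1)
    expect_equal(r$es, es_ref, tolerance = 1e-9)
  }
})

test_that("score negation flips every enrichment score and empty overlaps are skipped", {
  set.seed(7)
  scores <- setNames(rnorm(100), paste0("g", 1:100))
  sets <- list(A = paste0("g", 1:20), B = paste0("g", 41:70),
               MISSING = paste0("x", 1:10))
  r1 <- gsea_preranked(scores, sets, n_perm = 50, seed = 2, min_size = 5)
  r2 <- gsea_preranked(-scores, sets, n_perm = 50, seed = 2, min_size = 5)
  expect_equal(r2$es[match(r1$gene_set, r2$gene_set)], -r1$es,
               tolerance = 1e-12)
  expect_identical(attr(r1, "skipped")$gene_set, "MISSING")
  expect_true(all(r1$leading_edge[[1]] %in% sets$A))
  # deterministic given the seed
  r3 <- gsea_preranked(scores, sets, n_perm = 50, seed = 2, min_size = 5)
  expect_identical(r1$fdr, r3$fdr)
})

test_that("random gene sets are not called significant", {
  set.seed(9)
  scores <- setNames(rnorm(300), paste0("g", 1:300))
  sets <- lapply(1:10, function(i) sample(names(scores), 25))
  names(sets) <- paste0("R", 1:10)
  r <- gsea_preranked(scores, sets, n_perm = 200, seed = 3)
  expect_true(all(abs(r$es) < 0.6))
  expect_false(any(r$significant))
})
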