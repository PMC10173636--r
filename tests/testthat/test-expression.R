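mk_em <- function(m, conds = NULL, unit = "FPKM") {
  cols <- colnames(m)
  conds <- conds %||% sub("_r\\d+$", "", cols)
  expression_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                     tibble::as_tibble(m)),
    tibble::tibble(sample = cols, condition = conds,
                   replicate = as.integer(stats::ave(seq_along(cols),
                                                     conds, FUN = seq_along))),
    unit = unit)
}

test_that("FPKM follows the formula and its invariances", {
  m <- matrix(c(10, 0, 90, 20, 5, 40), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("x_r1", "x_r2")))
  lens <- c(a = 1000, b = 500, c = 2000)
  em <- mk_em(m, unit = "count")
  fp <- fpkm_from_counts(em, lens)
  fm <- as.matrix(fp$values[-1])
  rownames(fm) <- fp$values$gene_id
  expect_equal(fm["a", "x_r1"], 10 * 1e9 / (1000 * 100))
  expect_equal(fm["b", "x_r1"], 0)
  # column identity: sum FPKM * length / 1e9 == 1
  expect_equal(unname(colSums(fm * lens[rownames(fm)]) / 1e9), c(1, 1))
  # doubling a column leaves its FPKM unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  fp2 <- fpkm_from_counts(mk_em(m2, unit = "count"), lens)
  expect_equal(unname(as.matrix(fp2$values[-1])[, 1]), unname(fm[, 1]))
  expect_error(fpkm_from_counts(mk_em(m * 0, unit = "count"), lens), "zero")
})

test_that("expressed calls require the threshold in enough replicates", {
  m <- matrix(c(1.2, 1.2, 0, 0.8, 1.0, 0), nrow = 3, byrow = FALSE,
              dimnames = list(c("g1", "g2", "g3"), c("s_r1", "s_r2")))
  calls <- expressed_calls(mk_em(m))
  expect_equal(calls$s, c(FALSE, TRUE, FALSE))  # (1.2, .8) no; (1.2, 1.0) yes
  calls1 <- expressed_calls(mk_em(m), min_samples = 1)
  expect_equal(calls1$s, c(TRUE, TRUE, FALSE))
})

test_that("tau matches its closed forms and the independent oracle", {
  expect_equal(tau(c(5, 5, 5, 5)), 0)
  expect_equal(tau(c(8, 0, 0, 0)), 1)
  expect_equal(tau(c(4, 2, 2, 0)), 2 / 3)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(c(-1, 2)), "non-negative")
  set.seed(71)
  for (i in 1:200) {
    x <- rexp(sample(3:12, 1)) * sample(1:100, 1)
    expect_equal(tau(x), oracle_tau(x), tolerance = 1e-12)
    expect_equal(tau(x * 7.3), tau(x), tolerance = 1e-12)  # scale invariance
  }
  # decreasing a non-max entry weakly increases tau
  for (i in 1:100) {
    x <- rexp(6) + 0.1
    j <- which(x != max(x))[1]
    y <- x; y[j] <- y[j] * runif(1)
    expect_gte(tau(y), tau(x))
  }
})

test_that("stage sharing matches the set-algebra oracle", {
  set.seed(72)
  calls <- tibble::as_tibble(
    matrix(runif(200) > 0.5, 20, 10,
           dimnames = list(NULL, sprintf("S%02d", 1:10))))
  calls <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%02d", 1:20)),
                            calls)
  sh <- stage_sharing(calls)
  orc <- oracle_sharing(calls)
  expect_equal(sh$per_stage$n_expressed, unname(orc$per_stage))
  expect_equal(sh$cumulative$cumulative, orc$cumulative)
  got <- dplyr::left_join(sh$pairwise, tibble::as_tibble(orc$pairwise),
                          by = c("a", "b"), suffix = c("", ".o"))
  expect_equal(got$shared, got$shared.o)
  # shared fraction bounded by 1 and symmetric counts
  expect_true(all(got$frac_a <= 1 & got$frac_b <= 1))
  # cumulative curve is non-decreasing
  expect_true(all(diff(sh$cumulative$cumulative) >= 0))
})

test_that("stage sharing closed cases: identical and disjoint stages", {
  calls <- tibble::tibble(gene_id = c("a", "b", "c"),
                          s1 = c(TRUE, TRUE, FALSE),
                          s2 = c(TRUE, TRUE, FALSE))
  sh <- stage_sharing(calls)
  expect_equal(sh$pairwise$frac_a, 1)
  expect_equal(sh$pairwise$frac_b, 1)
  expect_equal(sh$cumulative$novel, c(2L, 0L))
  dis <- tibble::tibble(gene_id = c("a", "b", "c"),
                        s1 = c(TRUE, FALSE, FALSE),
                        s2 = c(FALSE, TRUE, TRUE))
  sh2 <- stage_sharing(dis)
  expect_equal(sh2$pairwise$shared, 0L)
  expect_equal(sh2$cumulative$cumulative, c(1L, 3L))
})

test_that("correlation structure recovers duplicated and grouped samples", {
  set.seed(73)
  base <- matrix(2^rnorm(400, 3, 1), 100, 4)
  m <- cbind(base[, 1], base[, 1], base[, 2] * exp(rnorm(100, 0, 0.05)),
             base[, 2])
  dimnames(m) <- list(sprintf("g%03d", 1:100),
                      c("a_r1", "a_r2", "b_r1", "b_r2"))
  cs <- correlation_structure(mk_em(m), method = "spearman")
  expect_equal(unname(cs$cor["a_r1", "a_r2"]), 1)
  expect_true(all(abs(diag(cs$cor) - 1) < 1e-12))
  expect_equal(sum(cs$var_explained), 1)
  # duplicated samples merge first in the dendrogram
  first_merge <- cs$hclust$merge[1, ]
  expect_setequal(cs$hclust$labels[-first_merge], c("a_r1", "a_r2"))
  # two planted groups split at the top: cut into 2 separates a from b
  k2 <- cutree(cs$hclust, k = 2)
  expect_equal(length(unique(k2[c("a_r1", "a_r2")])), 1)
  expect_equal(length(unique(k2[c("b_r1", "b_r2")])), 1)
  expect_false(k2[["a_r1"]] == k2[["b_r1"]])
  p <- autoplot(cs)
  expect_s3_class(p, "ggplot")
})

test_that("tissue specificity applies the strict below-threshold rule", {
  ret <- mk_em(matrix(c(5, 5, 3, 3, 2, 2), 3, 2, byrow = TRUE,
                      dimnames = list(c("g1", "g2", "g3"),
                                      c("ret_r1", "ret_r2"))))
  panel_m <- matrix(c(10, 0, 0.2,
                      10, 2.5, 0.99,
                      10, 0.1, 0.5), 3, 3, byrow = TRUE,
                    dimnames = list(c("g1", "g2", "g3"),
                                    c("retina", "cerebrum", "lung")))
  panel <- mk_em(panel_m, conds = colnames(panel_m))
  ts <- tissue_specificity(ret, panel)
  expect_equal(ts$retina_specific, c(TRUE, FALSE, TRUE))
  expect_equal(ts$shared_tissues[2], "cerebrum")
  # 0.99 everywhere stays specific (strict <1)
  panel_m2 <- panel_m; panel_m2["g1", -1] <- 0.99
  ts2 <- tissue_specificity(ret, mk_em(panel_m2, conds = colnames(panel_m2)))
  expect_true(ts2$retina_specific[1])
  # missing gene flagged
  panel3 <- mk_em(panel_m[1:2, ], conds = colnames(panel_m))
  expect_warning(ts3 <- tissue_specificity(ret, panel3), "missing")
  expect_true(is.na(ts3$retina_specific[3]))
})

test_that("planted specificity survives 20% replicate noise", {
  tr <- make_toy_genome(seed = 81, n_coding = 34, n_lnc_per_class = 10)
  ex <- make_expression(tr, noise_sd = 0.2, p_specific = 0.3,
                        p_constitutive = 0.3, seed = 82)
  sp <- tau_specificity(ex$stages, threshold = 0.8)
  spec_rate <- mean(sp$is_specific[sp$gene_id %in% ex$truth$specific])
  cons_rate <- mean(sp$is_specific[sp$gene_id %in% ex$truth$constitutive])
  expect_gte(spec_rate, 0.9)
  expect_lte(cons_rate, 0.05)
  # planted peak stage is recovered
  pk <- sp$peak_condition[match(ex$truth$specific, sp$gene_id)]
  expect_equal(unname(pk), unname(ex$truth$peak_stage))
  # retina-specific planted genes are called specific in the panel
  ts <- tissue_specificity(ex$stages, ex$tissues)
  expect_true(all(ts$retina_specific[ts$gene_id %in% ex$truth$retina_specific]))
})
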