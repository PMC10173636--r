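test_that("pearson_with_p matches cor.test to 1e-10 on random vectors", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    got <- pearson_with_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  exact <- pearson_with_p(1:6, 2 * (1:6) + 1)
  expect_equal(exact$r, 1)
  expect_lt(exact$p_value, 1e-10)
  expect_true(is.na(pearson_with_p(rep(1, 5), rnorm(5))$r))
  expect_error(pearson_with_p(1:3, 1:4), "equal length")
})

test_that("module detection recovers planted blocks and backgrounds the rest", {
  set.seed(92)
  n_s <- 12
  z1 <- rnorm(n_s, 0, 2); z2 <- rnorm(n_s, 0, 2)
  mk_block <- function(z, k, tag) {
    m <- t(sapply(1:k, function(i) 2^(3 + z + rnorm(n_s, 0, 0.15))))
    rownames(m) <- sprintf("%s%02d", tag, 1:k)
    m
  }
  noise <- matrix(2^rnorm(20 * n_s, 3, 1.5), 20,
                  dimnames = list(sprintf("n%02d", 1:20), NULL))
  m <- rbind(mk_block(z1, 10, "a"), mk_block(z2, 10, "b"), noise)
  colnames(m) <- sprintf("s%02d_r1", 1:n_s)
  em <- expression_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                     tibble::as_tibble(m)),
    tibble::tibble(sample = colnames(m), condition = colnames(m),
                   replicate = 1L), "FPKM")
  mod <- detect_modules(em, min_module_size = 5, cut_height = 0.25)
  planted <- c(rep("A", 10), rep("B", 10), rep("bg", 20))
  in_block <- planted != "bg"
  expect_equal(
    adjusted_rand_index(mod$module_id[in_block], planted[in_block]), 1)
  # the two blocks land in different modules, neither in the background
  expect_false(any(mod$module_id[in_block] == "M0"))
  # duplicated gene rows land in the same module
  expect_equal(mod$module_id[1], mod$module_id[2])
  # all-independent genes collapse to background
  mod2 <- detect_modules(em, min_module_size = 25, cut_height = 0.25)
  expect_true(all(mod2$module_id == "M0"))
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50),
                                    rep(c(1, 2, 2, 1), 25))), 0.2)
})

test_that("cis calls require nearest, close, correlated and significant", {
  loci <- tibble::tibble(locus_id = c("L1", "L2", "L3"), chrom = "c1",
                        start = c(1000L, 300000L, 601000L),
                        end = c(2000L, 301000L, 602000L), strand = "+")
  genes <- tibble::tibble(gene_id = c("G1", "G2", "G3"), chrom = "c1",
                          start = c(52001L, 451001L, 580000L),
                          end = c(60000L, 460000L, 590000L), strand = "-")
  # L1 -> G1 at 50 kb; L2 -> G2 at 150 kb (too far); L3 -> G3 at 11 kb
  set.seed(93)
  z <- rnorm(12, 0, 2)
  val <- rbind(
    L1 = 2^(3 + z), G1 = 2^(3.2 + z + rnorm(12, 0, 0.1)),   # correlated
    L2 = 2^(3 + z), G2 = 2^(3 + z),                          # correlated, far
    L3 = 2^rnorm(12, 3, 1), G3 = 2^rnorm(12, 3, 1))          # uncorrelated
  colnames(val) <- sprintf("s%02d_r1", 1:12)
  em <- expression_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(val)),
                     tibble::as_tibble(val)),
    tibble::tibble(sample = colnames(val), condition = colnames(val),
                   replicate = 1L), "FPKM")
  calls <- call_cis(loci, genes, em)
  expect_equal(calls$lnc_id, "L1")
  expect_equal(calls$target_gene_id, "G1")
  expect_equal(calls$distance, 50000)
  expect_true(calls$cor >= 0.9 && calls$p_value <= 0.05)
})

test_that("trans calls require correlation plus shared non-background module", {
  fp <- tibble::tibble(gene_id = c("L1", "L2", "G1", "G2"))
  set.seed(94)
  z <- rnorm(10, 0, 2)
  m <- rbind(2^(3 + z), 2^(3 + z + rnorm(10, 0, 0.1)),
             2^(3 + z + rnorm(10, 0, 0.1)), 2^(3 + z))
  colnames(m) <- sprintf("s%d_r1", 1:10)
  em <- expression_matrix(dplyr::bind_cols(fp, tibble::as_tibble(m)),
                          tibble::tibble(sample = colnames(m),
                                         condition = colnames(m),
                                         replicate = 1L), "FPKM")
  mods <- tibble::tibble(gene_id = c("L1", "L2", "G1", "G2"),
                         module_id = c("M1", "M2", "M1", "M0"))
  calls <- call_trans(c("L1", "L2"), c("G1", "G2"), em, mods)
  expect_equal(nrow(calls), 1)                    # only L1-G1 share module M1
  expect_equal(calls$lnc_id, "L1")
  expect_equal(calls$target_gene_id, "G1")
  # high correlation in different modules (L2-G1) or background (G2) is not enough
  expect_false(any(calls$target_gene_id == "G2"))
})

test_that("regulation recovery on planted pairs reaches 90% precision and recall", {
  tr <- make_toy_genome(seed = 95, n_coding = 40, n_lnc_per_class = 8,
                        chrom_length = 1.5e6)
  ex <- make_expression(tr, n_stages = 20, n_cis = 15, n_trans = 15,
                        n_modules = 3, noise_sd = 0.2, seed = 96)
  em <- ex$stages
  lnc_loci <- tr$lnc_loci |> dplyr::rename(locus_id = lnc_id)
  cis <- call_cis(lnc_loci, tr$coding_genes, em)
  truth_cis <- with(ex$truth$cis_pairs, paste(lnc_id, gene_id))
  got_cis <- with(cis, paste(lnc_id, target_gene_id))
  expect_gte(sum(got_cis %in% truth_cis) / max(length(got_cis), 1), 0.9)
  expect_gte(sum(truth_cis %in% got_cis) / length(truth_cis), 0.9)
  mods <- detect_modules(em, min_module_size = 5)
  trans <- call_trans(tr$lnc_loci$lnc_id, tr$coding_genes$gene_id, em, mods)
  truth_tr <- with(ex$truth$trans_pairs, paste(lnc_id, gene_id))
  got_tr <- with(trans, paste(lnc_id, target_gene_id))
  expect_gte(sum(got_tr %in% truth_tr) / max(length(got_tr), 1), 0.9)
  expect_gte(sum(truth_tr %in% got_tr) / length(truth_tr), 0.9)
})

test_that("term enrichment agrees with chisq.test and the Fisher oracle", {
  bg <- sprintf("g%04d", 1:1000)
  target <- bg[1:100]
  term_map <- dplyr::bind_rows(
    tibble::tibble(gene_id = c(bg[1:20], bg[101:110]), term = "T_enr"),
    tibble::tibble(gene_id = bg[c(5:14, 105:204)], term = "T_null"))
  res <- enrich_terms(target, bg, term_map)
  # cross-check every term against stats::chisq.test without correction
  for (tt in res$term) {
    genes_with <- unique(term_map$gene_id[term_map$term == tt])
    a <- sum(target %in% genes_with); b <- length(target) - a
    cc <- length(setdiff(genes_with, target)); d <- 1000 - 100 - cc
    ref <- suppressWarnings(chisq.test(matrix(c(a, b, cc, d), 2),
                                       correct = FALSE))
    i <- which(res$term == tt)
    expect_equal(res$chi2[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-12)
  }
  expect_lt(res$p_value[res$term == "T_enr"], 0.05)
  expect_gt(res$p_value[res$term == "T_null"], 0.05)
  # empty target set -> no rows
  expect_equal(nrow(enrich_terms(character(0), bg, term_map)), 0)
  expect_error(enrich_terms("not_in_bg", bg, term_map), "subset")
})

test_that("enrichment decisions agree with the exact Fisher oracle on well-filled tables", {
  set.seed(97)
  agree <- 0; total <- 0
  for (i in 1:200) {
    cells <- sample(5:60, 4, replace = TRUE)  # a, b, c, d
    n <- sum(cells)
    bg <- sprintf("g%04d", seq_len(n))
    target <- bg[seq_len(cells[1] + cells[2])]
    with_term <- c(bg[seq_len(cells[1])],
                   bg[cells[1] + cells[2] + seq_len(cells[3])])
    res <- enrich_terms(target, bg,
                        tibble::tibble(gene_id = with_term, term = "T"))
    fis <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    total <- total + 1
    agree <- agree + ((res$p_value <= 0.05) == (fis <= 0.05))
  }
  expect_gte(agree / total, 0.95)
})
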