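mk_tx <- function(id, starts, ends, strand = "+", source = "short_read",
                  gene = id, chrom = "c1", biotype = "unknown") {
  tibble::tibble(transcript_id = id, gene_id = gene, chrom = chrom,
                 start = as.integer(starts), end = as.integer(ends),
                 strand = strand, source = source, biotype = biotype)
}
cp_nc <- function(ids) tibble::tibble(transcript_id = ids, label = "noncoding")

test_that("short-read filter removes short, single-exon, overlapping and coding transcripts", {
  coding <- mk_tx("cg1", c(5000, 6000), c(5500, 6500), source = "annotation",
                  biotype = "coding")
  short2 <- mk_tx("short", c(100, 300), c(174, 374))          # 150 nt, 2 exons
  se <- mk_tx("se", 1000, 1499)                               # 500 nt, 1 exon
  ok <- mk_tx("ok", c(2000, 2500), c(2249, 2749))             # 500 nt, 2 exons
  codingish <- mk_tx("codingish", c(3000, 3500), c(3249, 3749))
  tx <- dplyr::bind_rows(short2, se, ok, codingish)
  cp <- dplyr::bind_rows(cp_nc(c("short", "se", "ok")),
                         tibble::tibble(transcript_id = "codingish",
                                        label = "coding"))
  kept <- filter_short_read_set(tx, coding, cp)
  expect_equal(unique(kept$transcript_id), "ok")
})

test_that("a single exonic base of coding overlap removes a transcript", {
  coding <- mk_tx("cg1", c(5000, 6000), c(5500, 6500), source = "annotation",
                  strand = "-", biotype = "coding")
  # last exon ends exactly on the first coding base
  touch <- mk_tx("touch", c(4000, 4700), c(4300, 5000))
  clear <- mk_tx("clear", c(3999, 4699), c(4299, 4999))
  kept <- filter_short_read_set(dplyr::bind_rows(touch, clear), coding,
                                cp_nc(c("touch", "clear")))
  expect_equal(unique(kept$transcript_id), "clear")
  expect_equal(oracle_exonic_overlap(touch, coding), 1)
  expect_equal(oracle_exonic_overlap(clear, coding), 0)
})

test_that("exonic-overlap decisions match the per-base oracle on random sets", {
  set.seed(21)
  coding <- transcript_models(dplyr::bind_rows(lapply(1:5, function(i) {
    random_transcript(sprintf("cg%d", i), source = "annotation")
  })))
  coding$biotype <- "coding"
  for (rep in 1:20) {
    tx <- transcript_models(dplyr::bind_rows(lapply(1:6, function(i) {
      random_transcript(sprintf("t%d", i), n_exons = sample(2:3, 1))
    })))
    tx <- dplyr::filter(
      tx, transcript_id %in%
        names(which(exonic_length(tx) >= 200)))
    kept <- filter_short_read_set(tx, coding,
                                  cp_nc(unique(tx$transcript_id)))
    for (id in unique(tx$transcript_id)) {
      ov <- oracle_exonic_overlap(dplyr::filter(tx, transcript_id == id),
                                  coding)
      expect_equal(id %in% kept$transcript_id, ov == 0, label = id)
    }
  }
})

test_that("strand assignment applies the joint fold and chi-squared rule", {
  calls <- assign_strand(tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    plus_reads = c(100L, 30L, 10L, 0L),
    minus_reads = c(10L, 20L, 100L, 0L)))
  expect_equal(calls$assigned_strand, c("+", "unassigned", "-", "unassigned"))
  expect_equal(calls$chi2[1], (100 - 55)^2 / 55 + (10 - 55)^2 / 55)
  expect_equal(calls$fold[1], 10)
  expect_equal(calls$p_value[4], 1)
  # chi-squared matches stats::chisq.test without continuity correction
  ct <- suppressWarnings(chisq.test(c(100, 10), p = c(0.5, 0.5)))
  expect_equal(calls$chi2[1], unname(ct$statistic))
  expect_equal(calls$p_value[1], ct$p.value)
  # decision agrees with an exact binomial oracle here
  expect_lt(binom.test(100, 110)$p.value, 0.05)
  # (30, 20): fold 1.5 blocks assignment regardless of p
  expect_equal(calls$fold[2], 1.5)
})

test_that("strand assignment is equivariant under swapping the counts", {
  set.seed(31)
  p <- rpois(200, 60); m <- rpois(200, 25)
  a <- assign_strand(tibble::tibble(transcript_id = as.character(1:200),
                                    plus_reads = p, minus_reads = m))
  b <- assign_strand(tibble::tibble(transcript_id = as.character(1:200),
                                    plus_reads = m, minus_reads = p))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold, b$fold)
  flip <- c("+" = "-", "-" = "+", unassigned = "unassigned")
  expect_equal(unname(flip[a$assigned_strand]), b$assigned_strand)
})

test_that("long-read filter drops unassigned, single-exon and intron-sharing transcripts", {
  coding <- mk_tx("cg1", c(5000, 6000), c(5500, 6500), source = "annotation",
                  biotype = "coding")
  share <- mk_tx("share", c(5400, 6000), c(5500, 6100), strand = "*",
                 source = "long_read")      # intron 5501..5999 == coding intron
  opp <- mk_tx("opp", c(5400, 6000), c(5500, 6100), strand = "*",
               source = "long_read")        # same intron, minus strand
  unassigned <- mk_tx("un", c(8000, 8500), c(8200, 8700), strand = "*",
                      source = "long_read")
  fine <- mk_tx("fine", c(9000, 9500), c(9200, 9700), strand = "*",
                source = "long_read")
  calls <- assign_strand(tibble::tibble(
    transcript_id = c("share", "opp", "un", "fine"),
    plus_reads = c(100L, 2L, 50L, 90L),
    minus_reads = c(5L, 100L, 40L, 3L)))
  kept <- filter_long_read_set(dplyr::bind_rows(share, opp, unassigned, fine),
                               calls, coding)
  expect_setequal(unique(kept$transcript_id), c("opp", "fine"))
  expect_equal(unique(kept$strand[kept$transcript_id == "opp"]), "-")
  expect_error(filter_long_read_set(share, calls[0, ], coding),
               "without a strand call")
})

test_that("merging collapses identical intron chains and keeps the widest ends", {
  a <- mk_tx("t.ann", c(100, 500), c(200, 600), source = "annotation")
  b <- mk_tx("t.sr", c(90, 500), c(200, 650), source = "short_read")
  m <- merge_sources(a, b, NULL)
  expect_equal(nrow(m$loci), 1)
  tx <- m$transcripts
  expect_equal(sort(unique(m$members$source)), c("annotation", "short_read"))
  expect_equal(c(min(tx$start), max(tx$end)), c(90L, 650L))
  expect_equal(tx$end[1], 200L)   # internal boundaries untouched
  expect_equal(unique(tx$transcript_id), "t.ann")  # annotation id preferred
})

test_that("locus clustering needs same-strand overlap and is transitive", {
  # 1 bp overlap, same strand -> one locus; opposite strand -> two
  x <- mk_tx("x", c(100, 300), c(200, 400))
  y <- mk_tx("y", c(400, 700), c(500, 800))
  z <- mk_tx("z", c(400, 700), c(500, 800), strand = "-")
  expect_equal(nrow(merge_sources(x, y, NULL)$loci), 1)
  expect_equal(nrow(merge_sources(x, z, NULL)$loci), 2)
  # A-B overlap, B-C overlap, A-C disjoint -> one locus (union-find);
  # distinct intron chains keep the three transcripts separate
  a <- mk_tx("a", c(100, 300), c(200, 400))
  b <- mk_tx("b", c(350, 700), c(450, 900))
  cc <- mk_tx("c", c(850, 1100), c(950, 1200))
  m <- merge_sources(NULL, dplyr::bind_rows(a, b, cc), NULL)
  expect_equal(nrow(m$loci), 1)
  expect_equal(m$loci$n_transcripts, 3)
})

test_that("merge is idempotent and order-invariant up to locus ids", {
  set.seed(41)
  tr <- make_toy_genome(seed = 41)
  lnc <- dplyr::filter(tr$annotation, biotype == "lncRNA")
  sr <- dplyr::filter(tr$short_read, !grepl("DECOY", transcript_id))
  lr <- dplyr::mutate(tr$long_read, strand = tr$transcripts$true_strand[
    match(transcript_id, tr$transcripts$transcript_id)])
  lr <- dplyr::filter(lr, !is.na(strand))
  m1 <- merge_sources(lnc, sr, lr)
  m2 <- merge_sources(m1$transcripts[names(lnc)], NULL, NULL)
  key <- function(m) {
    k <- m$transcripts |>
      dplyr::group_by(transcript_id) |>
      dplyr::summarise(sig = paste(chrom[1], strand[1],
                                   paste(start, end, collapse = ";")))
    sort(k$sig)
  }
  expect_equal(key(m2), key(m1))
  expect_equal(nrow(m2$loci), nrow(m1$loci))
  m3 <- merge_sources(NULL, sr, NULL)
  m4 <- merge_sources(sr, NULL, NULL)
  expect_equal(key(m3), key(m4))
})

test_that("merge report satisfies inclusion-exclusion on planted source overlap", {
  tr <- make_toy_genome(seed = 55, n_coding = 30, n_lnc_per_class = 6)
  lnc <- dplyr::filter(tr$annotation, biotype == "lncRNA")
  sr <- dplyr::filter(tr$short_read, !grepl("DECOY", transcript_id))
  lr <- dplyr::mutate(tr$long_read, strand = tr$transcripts$true_strand[
    match(transcript_id, tr$transcripts$transcript_id)]) |>
    dplyr::filter(!grepl("DECOY", transcript_id))
  m <- merge_sources(lnc, sr, lr)
  rpt <- m$report
  # source-specific + shared combination counts sum to the merged total
  expect_equal(sum(rpt$gene_combos$n_loci), rpt$n_loci)
  # per-source totals are the sums of the combinations containing the source
  for (s in c("annotation", "short_read", "long_read")) {
    expect_equal(
      rpt$per_source_genes$n_loci[rpt$per_source_genes$source == s],
      sum(rpt$gene_combos$n_loci[grepl(s, rpt$gene_combos$combo)]))
  }
  # merged loci equal planted loci; per-locus sources match the planted ones
  expect_equal(rpt$n_loci, nrow(tr$lnc_loci))
  truth_sources <- tr$lnc_loci |>
    dplyr::left_join(
      dplyr::distinct(m$members |>
                        dplyr::left_join(
                          dplyr::distinct(dplyr::bind_rows(lnc, sr, lr),
                                          transcript_id, gene_id),
                          by = c(member_id = "transcript_id")),
                      locus_id, gene_id),
      by = c(lnc_id = "gene_id"))
  locus_srcs <- m$loci$sources[match(truth_sources$locus_id, m$loci$locus_id)]
  expect_equal(locus_srcs, truth_sources$sources)
  # novel isoforms counted = planted novel isoforms at annotation-backed loci
  ann_loci <- tr$lnc_loci$lnc_id[grepl("annotation", tr$lnc_loci$sources)]
  expect_equal(rpt$novel_isoforms,
               sum(tr$transcripts$novel & tr$transcripts$lnc_id %in% ann_loci))
})

test_that("the expression gate keeps loci reaching the threshold anywhere", {
  loci <- tibble::tibble(locus_id = c("L1", "L2", "L3"))
  v <- tibble::tibble(gene_id = c("L1", "L2", "L3"),
                      s1 = c(0.99, 1.0, 0), s2 = c(0.5, 0.2, 0),
                      s3 = c(0.98, 0.9, 0), s4 = c(0.97, 0.95, 0))
  meta <- tibble::tibble(sample = paste0("s", 1:4),
                         condition = rep(c("a", "b"), each = 2),
                         replicate = rep(1:2, 2))
  fpkm <- expression_matrix(v, meta, "FPKM")
  kept <- expression_gate(loci, fpkm)
  expect_equal(kept$locus_id, "L2")      # 1.0 in one replicate is enough
  # per-condition mode requires both replicates of one condition
  expect_equal(nrow(expression_gate(loci, fpkm, per_condition = TRUE)), 0)
  expect_error(expression_gate(tibble::tibble(locus_id = "L9"), fpkm),
               "absent")
})
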