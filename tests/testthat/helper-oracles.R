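# Independent oracles used to check the package's vectorised implementations.
# Everything here is deliberately brute-force: per-base sets, explicit loops,
# base-R statistics.

# per-base positional classifier: enumerates every (lncRNA, coding) pair
oracle_classify <- function(loci, coding_exons, window = 1000, frac = 0.5) {
  genes <- split(coding_exons, coding_exons$gene_id)
  gene_tbl <- lapply(genes, function(g) {
    g <- g[order(g$start), ]
    list(id = g$gene_id[1], strand = g$strand[1],
         span = c(min(g$start), max(g$end)),
         body = seq(min(g$start), max(g$end)),
         intron = setdiff(seq(min(g$start), max(g$end)),
                          unlist(Map(seq, g$start, g$end))))
  })
  out <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    span_bases <- seq(l$start, l$end)
    ex <- attr(loci, "exons")[[l$locus_id]]
    exon_bases <- unique(unlist(Map(seq, ex$start, ex$end)))
    if (length(gene_tbl) == 0) {
      return(data.frame(locus_id = l$locus_id, positional_class = "intergenic",
                        stringsAsFactors = FALSE))
    }
    dists <- vapply(gene_tbl, function(g) {
      max(0, g$span[1] - l$end - 1, l$start - g$span[2] - 1)
    }, numeric(1))
    ids <- vapply(gene_tbl, function(g) g$id, character(1))
    o <- order(dists, ids)
    nearest <- gene_tbl[[o[1]]]
    anti <- any(vapply(gene_tbl, function(g) {
      g$strand != l$strand && length(intersect(span_bases, g$body)) >= 1
    }, logical(1)))
    same_introns <- unique(unlist(lapply(gene_tbl, function(g) {
      if (g$strand == l$strand) g$intron else integer(0)
    })))
    infrac <- length(intersect(exon_bases, same_introns)) / length(exon_bases)
    cls <- if (anti) "antisense"
    else if (infrac >= frac) "intronic"
    else if (dists[o[1]] <= window && nearest$strand != l$strand) "divergent"
    else if (dists[o[1]] <= window && nearest$strand == l$strand) "convergent"
    else "intergenic"
    data.frame(locus_id = l$locus_id, positional_class = cls,
               nearest_gene = nearest$id, distance = dists[o[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# wrap merged transcripts into the shape oracle_classify wants
as_oracle_loci <- function(merged) {
  ex <- if (inherits(merged, "lnc_merge")) merged$transcripts else merged
  loci <- do.call(rbind, lapply(split(ex, ex$locus_id), function(e) {
    data.frame(locus_id = e$locus_id[1], start = min(e$start),
               end = max(e$end), strand = e$strand[1],
               stringsAsFactors = FALSE)
  }))
  attr(loci, "exons") <- split(ex[, c("start", "end")], ex$locus_id)
  loci
}

# independent tau (direct transliteration of the index definition)
oracle_tau <- function(x) {
  xh <- x / max(x)
  sum(1 - xh) / (length(x) - 1)
}

# brute-force per-base exonic overlap between two exon tables
oracle_exonic_overlap <- function(ex_a, ex_b) {
  a <- unlist(Map(seq, ex_a$start, ex_a$end))
  b <- unlist(Map(seq, ex_b$start, ex_b$end))
  length(intersect(a, b))
}

# median-of-ratios by explicit loops
oracle_size_factors <- function(m) {
  keep <- apply(m > 0, 1, all)
  mm <- m[keep, , drop = FALSE]
  geo <- apply(mm, 1, function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(mm)), function(j) median(mm[, j] / geo), numeric(1))
}

# set-algebra stage sharing
oracle_sharing <- function(calls) {
  conds <- setdiff(names(calls), "gene_id")
  sets <- lapply(conds, function(cc) calls$gene_id[calls[[cc]]])
  names(sets) <- conds
  pairs <- t(combn(conds, 2))
  pairwise <- data.frame(a = pairs[, 1], b = pairs[, 2])
  pairwise$shared <- apply(pairs, 1, function(p) {
    length(intersect(sets[[p[1]]], sets[[p[2]]]))
  })
  seen <- character(0)
  cumulative <- vapply(conds, function(cc) {
    seen <<- union(seen, sets[[cc]])
    length(seen)
  }, integer(1))
  list(pairwise = pairwise, cumulative = unname(cumulative),
       per_stage = vapply(sets, length, integer(1)))
}

# a random exon tibble on a short chromosome (for overlap-filter fuzzing)
random_transcript <- function(id, chrom_len = 10000, n_exons = sample(1:3, 1),
                              strand = sample(c("+", "-"), 1),
                              source = "short_read") {
  ex_len <- sample(50:300, n_exons, replace = TRUE)
  int_len <- if (n_exons > 1) sample(30:200, n_exons - 1, replace = TRUE) else integer(0)
  span <- sum(ex_len) + sum(int_len)
  start <- sample.int(max(chrom_len - span, 1), 1)
  starts <- integer(n_exons); ends <- integer(n_exons); pos <- start
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + ex_len[i] - 1L
    pos <- ends[i] + (if (i < n_exons) int_len[i] else 0L) + 1L
  }
  tibble::tibble(transcript_id = id, gene_id = id, chrom = "c1",
                 start = starts, end = ends, strand = strand,
                 source = source, biotype = "unknown")
}
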