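# The lncRNA identification cascade: per-source filters, strand inference
# for unstranded long reads, three-source merging with contribution
# accounting, and the expression gate.

#' Filter a short-read assembled transcript set
#'
#' Keeps transcripts that are multi-exon, at least `min_length` nt of summed
#' exonic length (the mature-transcript length), have no exonic-base overlap
#' with any coding exon on either strand, and are labeled noncoding in the
#' coding-potential table. Transcripts absent from the table are dropped
#' with a warning (configurable).
#'
#' @param transcripts Exon tibble of assembled transcripts.
#' @param coding Exon tibble of protein-coding transcripts.
#' @param coding_potential Tibble `transcript_id`, `label` with label
#'   `"coding"` or `"noncoding"`.
#' @param min_length Minimum exonic length in nt.
#' @param missing_potential `"drop"` (default) or `"keep"` for transcripts
#'   missing from the coding-potential table.
#' @return The filtered exon tibble.
#' @export
filter_short_read_set <- function(transcripts, coding, coding_potential,
                                  min_length = 200,
                                  missing_potential = c("drop", "keep")) {
  missing_potential <- match.arg(missing_potential)
  if (nrow(transcripts) == 0) return(transcripts)
  sp <- transcript_spans(transcripts)
  keep <- sp$n_exons >= 2 & sp$exonic_length >= min_length
  # exonic overlap with coding exons, strand-blind
  if (nrow(coding) > 0) {
    hit <- GenomicRanges::findOverlaps(
      .exons_granges(transcripts, ignore_strand = TRUE),
      .exons_granges(coding, ignore_strand = TRUE))
    over <- unique(transcripts$transcript_id[S4Vectors::queryHits(hit)])
    keep <- keep & !(sp$transcript_id %in% over)
  }
  lab <- coding_potential$label[match(sp$transcript_id,
                                      coding_potential$transcript_id)]
  unknown <- is.na(lab)
  if (any(unknown & keep)) {
    if (missing_potential == "drop") {
      warn(paste0(sum(unknown & keep),
                  " transcript(s) missing from coding-potential table; dropped"))
      keep <- keep & !unknown
    }
  }
  keep <- keep & (unknown & missing_potential == "keep" |
                    (!unknown & lab == "noncoding"))
  filter(transcripts, .data$transcript_id %in% sp$transcript_id[keep])
}

#' Infer transcription direction from stranded read counts
#'
#' Chi-squared goodness of fit of (plus, minus) read counts against an equal
#' split (df = 1, no continuity correction). The majority strand is assigned
#' iff the fold ratio of the larger to the smaller count exceeds `fold`
#' (strictly) and the chi-squared p-value is at most `alpha`; otherwise the
#' transcript stays unassigned. Zero total reads give p = 1 and fold = 1.
#'
#' @param counts Tibble `transcript_id`, `plus_reads`, `minus_reads`.
#' @param fold Fold-ratio threshold (strict inequality).
#' @param alpha Chi-squared p-value threshold.
#' @return A strand-call tibble: the inputs plus `fold`, `chi2`, `p_value`,
#'   `assigned_strand` (`"+"`, `"-"` or `"unassigned"`).
#' @export
assign_strand <- function(counts, fold = 2, alpha = 0.05) {
  if (fold < 1) abort("fold threshold must be >= 1")
  p <- as.numeric(counts$plus_reads)
  m <- as.numeric(counts$minus_reads)
  if (any(p < 0 | m < 0)) abort("negative read counts")
  n <- p + m
  chi2 <- if_else(n > 0, (p - m)^2 / n, 0)
  pval <- if_else(n > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  fr <- dplyr::case_when(n == 0 ~ 1,
                         pmin(p, m) == 0 ~ Inf,
                         TRUE ~ pmax(p, m) / pmin(p, m))
  assigned <- fr > fold & pval <= alpha
  tibble(transcript_id = counts$transcript_id,
         plus_reads = as.integer(p), minus_reads = as.integer(m),
         fold = fr, chi2 = chi2, p_value = pval,
         assigned_strand = dplyr::case_when(
           !assigned ~ "unassigned",
           p > m ~ "+",
           TRUE ~ "-"))
}

# strand-aware intron keys "chrom:strand:start-end"
.intron_keys <- function(exons) {
  ii <- introns_of(exons)
  paste(ii$chrom, ii$strand, ii$start, ii$end, sep = ":")
}

#' Filter a long-read transcript set
#'
#' Applies inferred strands to strand-unknown transcripts, then keeps
#' transcripts that (i) have a strand (unassigned ones are dropped), (ii) are
#' multi-exon, and (iii) share no intron — exact donor-acceptor coordinate
#' pair on the same strand — with any coding transcript.
#'
#' @param transcripts Exon tibble (strand `"*"` for unstranded entries).
#' @param strand_calls Output of [assign_strand()] covering every
#'   strand-unknown transcript.
#' @param coding Exon tibble of protein-coding transcripts.
#' @return The filtered exon tibble with strands resolved.
#' @export
filter_long_read_set <- function(transcripts, strand_calls, coding) {
  if (nrow(transcripts) == 0) return(transcripts)
  unk <- unique(transcripts$transcript_id[transcripts$strand == "*"])
  miss <- setdiff(unk, strand_calls$transcript_id)
  if (length(miss) > 0) {
    abort(paste0("strand-unknown transcript(s) without a strand call: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  res <- strand_calls$assigned_strand[match(transcripts$transcript_id,
                                            strand_calls$transcript_id)]
  transcripts <- transcripts |>
    mutate(strand = if_else(.data$strand == "*", res, .data$strand)) |>
    filter(.data$strand %in% c("+", "-"))
  sp <- transcript_spans(transcripts)
  keep <- sp$transcript_id[sp$n_exons >= 2]
  transcripts <- filter(transcripts, .data$transcript_id %in% keep)
  if (nrow(transcripts) == 0) return(transcripts)
  bad_keys <- .intron_keys(coding)
  ii <- introns_of(transcripts)
  shared <- unique(ii$transcript_id[paste(ii$chrom, ii$strand, ii$start,
                                          ii$end, sep = ":") %in% bad_keys])
  filter(transcripts, !.data$transcript_id %in% shared)
}

# collapse transcripts with identical intron chains (multi-exon) or
# overlapping same-strand spans (single-exon); returns collapsed exon tibble
# plus a member map
.collapse_transcripts <- function(exons) {
  sp <- transcript_spans(exons)
  multi <- sp$transcript_id[sp$n_exons >= 2]
  pri <- match(sp$source, .SOURCES)  # annotation < short_read < long_read
  rep_of <- setNames(sp$transcript_id, sp$transcript_id)
  group_of <- setNames(seq_len(nrow(sp)), sp$transcript_id)

  if (length(multi) > 0) {
    ii <- introns_of(filter(exons, .data$transcript_id %in% multi))
    chain <- ii |>
      group_by(.data$transcript_id) |>
      summarise(key = paste(first(.data$chrom), first(.data$strand),
                            paste(.data$start, .data$end, collapse = ";"),
                            sep = "|"), .groups = "drop")
    grp <- split(chain$transcript_id, chain$key)
  } else grp <- list()
  single <- sp |> filter(.data$n_exons == 1)
  if (nrow(single) > 0) {
    sg <- .exons_granges(single)
    red <- GenomicRanges::reduce(sg, with.revmap = TRUE, min.gapwidth = 0L,
                                 ignore.strand = FALSE)
    sgrp <- lapply(S4Vectors::mcols(red)$revmap,
                   function(i) single$transcript_id[i])
    grp <- c(grp, sgrp)
  }

  out <- vector("list", length(grp))
  members <- vector("list", length(grp))
  for (k in seq_along(grp)) {
    ids <- grp[[k]]
    # representative id: preferred source, then lexicographic
    o <- order(pri[match(ids, sp$transcript_id)], ids)
    rep_id <- ids[o[1]]
    ex <- filter(exons, .data$transcript_id %in% ids)
    n_ex <- sum(ex$transcript_id == rep_id)
    rex <- filter(ex, .data$transcript_id == rep_id) |> arrange(.data$start)
    # widest terminal exons over the group
    firsts <- ex |> group_by(.data$transcript_id) |>
      summarise(s = min(.data$start), e = max(.data$end), .groups = "drop")
    rex$start[1] <- min(firsts$s)
    rex$end[n_ex] <- max(firsts$e)
    out[[k]] <- rex
    members[[k]] <- tibble(transcript_id = rep_id, member_id = ids,
                           source = sp$source[match(ids, sp$transcript_id)])
  }
  list(exons = bind_rows(out), members = bind_rows(members))
}

#' Merge transcript sets from the three sources into gene loci
#'
#' Transcripts with identical intron chains collapse to one representative
#' that keeps the union of source tags and the widest terminal exons
#' (single-exon transcripts are equivalent when their spans overlap on the
#' same strand). Collapsed transcripts whose spans overlap by at least one
#' base on the same strand then cluster into gene loci by transitive closure,
#' and loci receive fresh XLOC-style ids ordered along the genome. The merge
#' report tallies the contribution of each source combination at gene and
#' transcript level, plus novel isoforms at annotation-backed loci.
#'
#' @param annotation,short_read,long_read Exon tibbles (any may be NULL); all
#'   transcripts must be stranded.
#' @return An `lnc_merge` object: `$transcripts` (collapsed exon tibble with
#'   `locus_id`), `$members` (representative to member transcript map with
#'   source tags), `$loci` (one row per locus with source combination), and
#'   `$report` (a `MergeReport` list of tally tibbles).
#' @export
merge_sources <- function(annotation = NULL, short_read = NULL,
                          long_read = NULL) {
  exons <- bind_rows(annotation, short_read, long_read)
  if (nrow(exons) == 0) abort("no transcripts to merge")
  if (any(exons$strand == "*")) {
    abort("all transcripts must be stranded before merging")
  }
  dup <- exons |> distinct(.data$transcript_id, .data$source) |>
    count(.data$transcript_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate transcript_id across sources; ids must be unique")
  }
  col <- .collapse_transcripts(exons)

  sp <- transcript_spans(col$exons)
  gr <- .exons_granges(sp)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L,
                               ignore.strand = FALSE)
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red),
               as.character(GenomicRanges::strand(red)))
  locus_of <- character(nrow(sp))
  loci <- vector("list", length(red))
  for (k in seq_along(ord)) {
    i <- ord[k]
    ids <- sp$transcript_id[S4Vectors::mcols(red)$revmap[[i]]]
    lid <- sprintf("XLOC_%06d", k)
    locus_of[match(ids, sp$transcript_id)] <- lid
    loci[[k]] <- tibble(
      locus_id = lid,
      chrom = as.character(GenomicRanges::seqnames(red))[i],
      strand = as.character(GenomicRanges::strand(red))[i],
      start = GenomicRanges::start(red)[i],
      end = GenomicRanges::end(red)[i],
      n_transcripts = length(ids))
  }
  loci <- bind_rows(loci)
  tx2locus <- setNames(locus_of, sp$transcript_id)
  transcripts <- col$exons |>
    mutate(locus_id = unname(tx2locus[.data$transcript_id]))
  members <- col$members |>
    mutate(locus_id = unname(tx2locus[.data$transcript_id]))

  locus_sources <- members |>
    group_by(.data$locus_id) |>
    summarise(sources = paste(sort(unique(.data$source)), collapse = ","),
              .groups = "drop")
  loci <- left_join(loci, locus_sources, by = "locus_id")

  # report: gene-level source-combination tallies + per-source totals
  combo_genes <- count(loci, combo = .data$sources, name = "n_loci")
  per_source_genes <- purrr::map_dfr(.SOURCES, function(s) {
    tibble(source = s,
           n_loci = sum(stringr::str_detect(loci$sources,
                                            stringr::fixed(s))))
  })
  tx_in <- exons |> distinct(.data$transcript_id, .data$source) |>
    count(.data$source, name = "n_transcripts")
  novel <- members |>
    group_by(.data$locus_id) |>
    filter(any(.data$source == "annotation")) |>
    group_by(.data$locus_id, .data$transcript_id) |>
    summarise(novel = !any(.data$source == "annotation"), .groups = "drop") |>
    summarise(n_novel_isoforms = sum(.data$novel))
  report <- structure(list(
    n_loci = nrow(loci),
    n_transcripts = dplyr::n_distinct(members$transcript_id),
    gene_combos = combo_genes,
    per_source_genes = per_source_genes,
    input_transcripts = tx_in,
    novel_isoforms = novel$n_novel_isoforms %||% 0L
  ), class = "merge_report")

  structure(list(transcripts = transcripts, members = members,
                 loci = loci, report = report),
            class = "lnc_merge")
}

#' @export
print.lnc_merge <- function(x, ...) {
  cat(sprintf("<lnc_merge> %d loci from %d collapsed transcripts\n",
              nrow(x$loci), dplyr::n_distinct(x$transcripts$transcript_id)))
  print(x$report)
  invisible(x)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("merge report: %d loci, %d transcripts, %d novel isoform(s)\n",
              x$n_loci, x$n_transcripts, x$novel_isoforms))
  print(x$gene_combos)
  invisible(x)
}

#' Tidy a merged locus set
#'
#' @param x An `lnc_merge`.
#' @param ... Unused.
#' @return The locus tibble.
#' @export
tidy.lnc_merge <- function(x, ...) x$loci

#' One-line merge summary
#'
#' @param x An `lnc_merge`.
#' @param ... Unused.
#' @return A one-row tibble with locus/transcript/novel-isoform counts.
#' @export
glance.lnc_merge <- function(x, ...) {
  tibble(n_loci = x$report$n_loci, n_transcripts = x$report$n_transcripts,
         n_novel_isoforms = x$report$novel_isoforms)
}

#' Remove lowly expressed loci
#'
#' Keeps loci whose FPKM reaches `threshold` in at least one sample column
#' (the default reading of the low-expression removal rule), or in at least
#' `min_samples` replicate columns of some one condition when
#' `per_condition = TRUE`.
#'
#' @param merged An `lnc_merge`, or a locus tibble with `locus_id`.
#' @param fpkm An FPKM `expr_matrix` containing every locus id.
#' @param threshold FPKM threshold (kept iff >= threshold).
#' @param per_condition Require the threshold within one condition's
#'   replicates instead of any single sample.
#' @param min_samples Replicate count required when `per_condition = TRUE`.
#' @return Same type as `merged`, restricted to expressed loci.
#' @export
expression_gate <- function(merged, fpkm, threshold = 1,
                            per_condition = FALSE, min_samples = 2) {
  loci <- if (inherits(merged, "lnc_merge")) merged$loci else as_tibble(merged)
  m <- .em_matrix(fpkm)
  miss <- setdiff(loci$locus_id, rownames(m))
  if (length(miss) > 0) {
    abort(paste0("locus id(s) absent from FPKM matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  m <- m[loci$locus_id, , drop = FALSE]
  if (per_condition) {
    hits <- .cond_matrix(m, fpkm$samples, function(x) rowSums(x >= threshold))
    reps <- table(fpkm$samples$condition)[colnames(hits)]
    ok <- sweep(hits, 2, pmin(min_samples, as.integer(reps)), ">=")
    keep <- rownames(m)[rowSums(ok) > 0]
  } else {
    keep <- rownames(m)[apply(m, 1, max) >= threshold]
  }
  if (inherits(merged, "lnc_merge")) {
    merged$loci <- filter(merged$loci, .data$locus_id %in% keep)
    merged$transcripts <- filter(merged$transcripts, .data$locus_id %in% keep)
    merged$members <- filter(merged$members, .data$locus_id %in% keep)
    merged
  } else {
    filter(loci, .data$locus_id %in% keep)
  }
}
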