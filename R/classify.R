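# Positional classification of lncRNA loci relative to coding genes, and
# conservation-track scoring of exon sets against a matched random background.

# per-gene coding spans and intron sets from a coding exon tibble
.coding_index <- function(coding_exons) {
  if (nrow(coding_exons) == 0) {
    return(list(genes = tibble(gene_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               strand = character()),
                introns = tibble(gene_id = character(), chrom = character(),
                                 strand = character(), start = integer(),
                                 end = integer())))
  }
  genes <- coding_exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop")
  introns <- introns_of(coding_exons) |>
    left_join(distinct(coding_exons, .data$transcript_id, .data$gene_id),
              by = "transcript_id") |>
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end)
  list(genes = genes, introns = introns)
}

#' Classify lncRNA loci by position relative to coding genes
#'
#' Each locus receives exactly one of five classes, decided in precedence
#' order: antisense if its span overlaps an opposite-strand coding gene body
#' by at least `min_overlap` bases; intronic if at least `intronic_frac` of
#' its exonic bases fall inside same-strand coding introns; divergent if its
#' nearest coding gene lies within `window` bp on the opposite strand;
#' convergent if within `window` bp on the same strand; intergenic otherwise.
#' Distances are measured between the closest gene-body boundaries (0 when
#' the spans overlap); a locus exactly `window` bp away is still
#' divergent/convergent (inclusive boundary). Nearest-gene ties break by
#' distance then lexicographic gene id.
#'
#' @param merged An `lnc_merge`, or an exon tibble carrying a `locus_id`
#'   column (one locus may have several transcripts).
#' @param coding_exons Exon tibble of protein-coding transcripts.
#' @param window Distance window for divergent/convergent calls (bp).
#' @param intronic_frac Minimum fraction of exonic bases inside same-strand
#'   coding introns for an intronic call.
#' @param min_overlap Minimum antisense gene-body overlap (bp).
#' @param antisense_on `"gene_body"` (default) or `"exon"`: what the
#'   opposite-strand overlap is measured against.
#' @return A tibble with one row per locus: `locus_id`, `positional_class`,
#'   `nearest_gene`, `distance`, `overlap_bases`, `intronic_fraction`.
#' @export
classify_loci <- function(merged, coding_exons, window = 1000,
                          intronic_frac = 0.5, min_overlap = 1,
                          antisense_on = c("gene_body", "exon")) {
  antisense_on <- match.arg(antisense_on)
  exons <- if (inherits(merged, "lnc_merge")) merged$transcripts else as_tibble(merged)
  if (!"locus_id" %in% names(exons)) {
    abort("classify_loci needs a locus_id column (merge first)")
  }
  loci <- exons |>
    group_by(.data$locus_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop")
  if (nrow(loci) == 0) {
    return(tibble(locus_id = character(), positional_class = character(),
                  nearest_gene = character(), distance = integer(),
                  overlap_bases = integer(), intronic_fraction = double()))
  }
  idx <- .coding_index(coding_exons)
  if (nrow(idx$genes) == 0) {
    return(tibble(locus_id = loci$locus_id, positional_class = "intergenic",
                  nearest_gene = NA_character_, distance = NA_integer_,
                  overlap_bases = 0L, intronic_fraction = 0))
  }
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end))
  gg <- GenomicRanges::GRanges(idx$genes$chrom,
                               IRanges::IRanges(idx$genes$start, idx$genes$end))

  # nearest coding gene with deterministic tie-break (distance, gene id)
  hits <- GenomicRanges::distanceToNearest(lg, gg, select = "all",
                                           ignore.strand = TRUE)
  nearest <- tibble(
    li = S4Vectors::queryHits(hits), gi = S4Vectors::subjectHits(hits),
    distance = S4Vectors::mcols(hits)$distance,
    gene_id = idx$genes$gene_id[S4Vectors::subjectHits(hits)]) |>
    arrange(.data$li, .data$distance, .data$gene_id) |>
    group_by(.data$li) |> dplyr::slice(1) |> ungroup()
  res <- loci |>
    mutate(li = row_number()) |>
    left_join(nearest, by = "li")

  # overlap bases with the nearest gene span
  ns <- idx$genes[res$gi, ]
  res$overlap_bases <- pmax(0L, pmin(res$end, ns$end) -
                              pmax(res$start, ns$start) + 1L)
  res$overlap_bases[is.na(res$overlap_bases)] <- 0L

  # antisense: opposite-strand coding-body (or exon) overlap
  anti_target <- if (antisense_on == "gene_body") {
    GenomicRanges::GRanges(idx$genes$chrom,
                           IRanges::IRanges(idx$genes$start, idx$genes$end),
                           strand = idx$genes$strand)
  } else {
    .exons_granges(coding_exons)
  }
  lgs <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start, loci$end),
                                strand = loci$strand)
  oh <- GenomicRanges::findOverlaps(lgs, anti_target,
                                    minoverlap = as.integer(min_overlap),
                                    ignore.strand = TRUE)
  opp_strand <- as.character(GenomicRanges::strand(anti_target))[
    S4Vectors::subjectHits(oh)] !=
    loci$strand[S4Vectors::queryHits(oh)]
  is_anti <- seq_len(nrow(loci)) %in% S4Vectors::queryHits(oh)[opp_strand]

  # intronic fraction: unique lncRNA exonic bases (the locus's exonic
  # footprint, transcripts unioned) inside same-strand coding introns
  lx_all <- .exons_granges(exons)
  lx <- unlist(GenomicRanges::reduce(
    S4Vectors::split(lx_all, exons$locus_id)))
  lx_locus <- names(lx)
  ir <- idx$introns
  igr <- GenomicRanges::GRanges(ir$chrom, IRanges::IRanges(ir$start, ir$end),
                                strand = ir$strand)
  igr <- GenomicRanges::reduce(igr)
  ov <- GenomicRanges::findOverlaps(lx, igr, ignore.strand = FALSE)
  inside <- GenomicRanges::pintersect(lx[S4Vectors::queryHits(ov)],
                                      igr[S4Vectors::subjectHits(ov)])
  in_by_locus <- tibble(locus_id = lx_locus[S4Vectors::queryHits(ov)],
                        w = GenomicRanges::width(inside)) |>
    group_by(.data$locus_id) |>
    summarise(inside = sum(.data$w), .groups = "drop")
  ex_by_locus <- tibble(locus_id = lx_locus,
                        w = GenomicRanges::width(lx)) |>
    group_by(.data$locus_id) |>
    summarise(exonic = sum(.data$w), .groups = "drop")
  frac <- ex_by_locus |>
    left_join(in_by_locus, by = "locus_id") |>
    mutate(frac = dplyr::coalesce(.data$inside, 0L) / .data$exonic)
  res$intronic_fraction <- frac$frac[match(res$locus_id, frac$locus_id)]

  ns_strand <- ns$strand
  res |>
    mutate(positional_class = dplyr::case_when(
      is_anti ~ "antisense",
      .data$intronic_fraction >= intronic_frac ~ "intronic",
      .data$distance <= window & .data$strand != ns_strand ~ "divergent",
      .data$distance <= window & .data$strand == ns_strand ~ "convergent",
      TRUE ~ "intergenic")) |>
    select("locus_id", "positional_class", nearest_gene = "gene_id",
           "distance", "overlap_bases", "intronic_fraction")
}

#' Summarise a classification into per-class counts
#'
#' @param classes Output of [classify_loci()].
#' @return A tibble `positional_class`, `n` over the five classes (zero rows
#'   for absent classes included), counts summing to the number of loci.
#' @export
class_summary <- function(classes) {
  tibble(positional_class = .CLASSES) |>
    left_join(count(classes, .data$positional_class), by = "positional_class") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Bar plot of positional class counts
#'
#' @param classes Output of [classify_loci()].
#' @return A ggplot object.
#' @export
plot_class_counts <- function(classes) {
  ggplot2::ggplot(class_summary(classes),
                  ggplot2::aes(x = .data$positional_class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "lncRNA loci") +
    ggplot2::theme_minimal()
}

# mean per-base track score of regions; uncovered bases score 0
.region_scores <- function(regions, track) {
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  tg <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start, track$end))
  ov <- GenomicRanges::findOverlaps(rg, tg)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    rg[S4Vectors::queryHits(ov)], tg[S4Vectors::subjectHits(ov)]))
  contrib <- tibble(i = S4Vectors::queryHits(ov),
                    s = w * track$score[S4Vectors::subjectHits(ov)]) |>
    group_by(.data$i) |> summarise(s = sum(.data$s), .groups = "drop")
  total <- rep(0, nrow(regions))
  total[contrib$i] <- contrib$s
  total / (regions$end - regions$start + 1)
}

#' Score exon conservation against a matched random background
#'
#' Computes the mean per-base conservation score of every lncRNA exon and
#' every coding exon, plus a random background of the same cardinality as
#' the lncRNA exon set with lengths uniform on 1..`max_len` placed uniformly
#' on the chromosomes. Track-uncovered bases count as score 0.
#'
#' @param lnc_exons Exon tibble of lncRNA loci.
#' @param coding_exons Exon tibble of coding transcripts.
#' @param track Score-track tibble (see [read_score_track()]).
#' @param chrom_lengths Named vector of chromosome lengths for random
#'   placement.
#' @param max_len Maximum random-region length (bp).
#' @param seed Integer seed for the random background.
#' @return A tibble `group` (`lnc_exon`, `coding_exon`, `random`), `chrom`,
#'   `start`, `end`, `mean_score`.
#' @export
exon_conservation <- function(lnc_exons, coding_exons, track, chrom_lengths,
                              max_len = 1000, seed = 1) {
  pick <- function(ex) distinct(ex, .data$chrom, .data$start, .data$end)
  lnc_r <- pick(lnc_exons)
  cod_r <- pick(coding_exons)
  n <- nrow(lnc_r)
  rand_r <- .with_seed(seed, {
    len <- sample.int(max_len, n, replace = TRUE)
    chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    maxs <- unname(chrom_lengths[chrom]) - len + 1
    start <- floor(runif(n, 1, pmax(maxs, 1) + 1))
    tibble(chrom = chrom, start = as.integer(start),
           end = as.integer(start + len - 1L))
  })
  regions <- bind_rows(
    mutate(lnc_r, group = "lnc_exon"),
    mutate(cod_r, group = "coding_exon"),
    mutate(rand_r, group = "random"))
  regions$mean_score <- .region_scores(regions, track)
  select(regions, "group", "chrom", "start", "end", "mean_score")
}

#' Violin/box plot of conservation score distributions
#'
#' @param scores Output of [exon_conservation()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$group, y = .data$mean_score)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "mean per-base score") +
    ggplot2::theme_minimal()
}
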