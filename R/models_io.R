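#' Transcript model tables
#'
#' Transcript models are represented as ordinary tibbles with one row per
#' exon and columns `transcript_id`, `gene_id`, `chrom`, `start`, `end`,
#' `strand`, `source`, `biotype`. Coordinates are 1-based inclusive (the
#' R/Bioconductor convention); strand is one of `"+"`, `"-"`, `"*"` (`"*"` =
#' unknown, e.g. long-read transcripts before strand assignment); `source` is
#' one of `"annotation"`, `"short_read"`, `"long_read"`; `biotype` one of
#' `"coding"`, `"lncRNA"`, `"unknown"`.
#'
#' `transcript_models()` validates such a table: exons sorted by start within
#' transcript, non-overlapping (adjacent exons separated by at least one
#' intronic base), one chromosome and strand per transcript, at least one exon.
#' Overlapping or book-ended exons of the same transcript are merged before
#' validation, mirroring how assemblers emit exon lines.
#'
#' @param exons A data frame with the columns listed above (`source` and
#'   `biotype` optional; they default to `"annotation"` / `"unknown"`).
#' @return A validated exon tibble, sorted by transcript then start.
#' @examples
#' tx <- transcript_models(tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = c(101, 301), end = c(200, 400), strand = "+"
#' ))
#' exonic_length(tx)
#' @export
transcript_models <- function(exons) {
  exons <- as_tibble(exons)
  if (!"source" %in% names(exons)) exons$source <- "annotation"
  if (!"biotype" %in% names(exons)) exons$biotype <- "unknown"
  need <- c("transcript_id", "gene_id", "chrom", "start", "end",
            "strand", "source", "biotype")
  miss <- setdiff(need, names(exons))
  if (length(miss) > 0) {
    abort(paste0("transcript table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  exons <- select(exons, dplyr::all_of(need))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0) return(exons)
  if (anyNA(exons)) abort("transcript table contains missing values")
  if (any(exons$start > exons$end)) abort("exon with start > end")
  if (any(exons$start < 1)) abort("exon with start < 1")
  if (!all(exons$strand %in% .STRANDS)) {
    abort("strand must be one of '+', '-', '*'")
  }
  if (!all(exons$source %in% .SOURCES)) {
    abort(paste0("source must be one of: ", paste(.SOURCES, collapse = ", ")))
  }
  if (!all(exons$biotype %in% c("coding", "lncRNA", "unknown"))) {
    abort("biotype must be one of 'coding', 'lncRNA', 'unknown'")
  }
  # one chrom/strand/gene/source/biotype per transcript
  meta <- distinct(exons, .data$transcript_id, .data$chrom, .data$strand,
                   .data$gene_id, .data$source, .data$biotype)
  bad <- meta$transcript_id[duplicated(meta$transcript_id)]
  if (length(bad) > 0) {
    abort(paste0("transcript(s) with inconsistent chrom/strand/gene metadata: ",
                 paste(unique(bad), collapse = ", ")))
  }
  # merge touching/overlapping exons per transcript, then sort
  exons <- exons |>
    arrange(.data$transcript_id, .data$start, .data$end) |>
    group_by(.data$transcript_id) |>
    mutate(.grp = cumsum(.data$start > lag(cummax(.data$end), default = -1L) + 1L)) |>
    group_by(.data$transcript_id, .data$.grp) |>
    summarise(across(c("gene_id", "chrom", "strand", "source", "biotype"), first),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select(-".grp") |>
    select(dplyr::all_of(need)) |>
    arrange(.data$transcript_id, .data$start)
  exons
}

#' Per-transcript span summary
#'
#' Collapses an exon table to one row per transcript with its genomic span,
#' exon count, exonic length (sum of exon lengths, the mature-transcript
#' length) and metadata.
#'
#' @param exons A validated exon tibble (see [transcript_models()]).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `source`, `biotype`, `n_exons`,
#'   `exonic_length`.
#' @export
transcript_spans <- function(exons) {
  exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id), chrom = first(.data$chrom),
      n_exons = n(),
      exonic_length = sum(.data$end - .data$start + 1L),
      start = min(.data$start), end = max(.data$end),
      strand = first(.data$strand), source = first(.data$source),
      biotype = first(.data$biotype),
      .groups = "drop"
    ) |>
    select("transcript_id", "gene_id", "chrom", "start", "end", "strand",
           "source", "biotype", "n_exons", "exonic_length")
}

#' Exonic length per transcript
#'
#' @param exons A validated exon tibble.
#' @return Named integer vector of summed exon lengths, one per transcript.
#' @export
exonic_length <- function(exons) {
  sp <- transcript_spans(exons)
  setNames(as.integer(sp$exonic_length), sp$transcript_id)
}

#' Intron table of a transcript set
#'
#' Introns are the gaps between consecutive exons of a multi-exon transcript;
#' their exact (start, end) coordinate pairs on a strand define the intron
#' chain used for transcript equivalence and the coding-intron sharing filter.
#'
#' @param exons A validated exon tibble.
#' @return A tibble `transcript_id`, `chrom`, `strand`, `start`, `end` with
#'   one row per intron (1-based inclusive intronic bases).
#' @export
introns_of <- function(exons) {
  exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(intron_start = lag(.data$end) + 1L, intron_end = .data$start - 1L) |>
    ungroup() |>
    filter(!is.na(.data$intron_start)) |>
    select("transcript_id", "chrom", "strand",
           start = "intron_start", end = "intron_end")
}

# exon tibble -> GRanges (strand "*" kept as "*")
.exons_granges <- function(exons, ignore_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = if (ignore_strand) "*" else exons$strand
  )
}

# quick structural scan of a GTF so parse errors can name a line
.scan_gtf_lines <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      abort(paste0("malformed GTF line ", i, " in ", path))
    }
  }
  length(body)
}

#' Read transcript models from a GTF file
#'
#' Reads exon features from a GTF (Ensembl/GENCODE dialect: attributes
#' `gene_id`, `transcript_id`, optional `gene_biotype`), assembles one
#' transcript model per `transcript_id`, merges and sorts exons, and tags
#' every transcript with `source_tag`. GTF's 1-based inclusive coordinates
#' are kept as-is (the internal convention). Strand `"."` becomes `"*"`.
#'
#' @param path Path to a GTF file.
#' @param source_tag One of `"annotation"`, `"short_read"`, `"long_read"`.
#' @param biotypes Optional named character vector mapping `gene_id` to
#'   `"coding"`/`"lncRNA"`, used when the file carries no `gene_biotype`
#'   attribute (sidecar list).
#' @return A validated exon tibble (see [transcript_models()]).
#' @export
read_gtf <- function(path, source_tag = "annotation", biotypes = NULL) {
  source_tag <- match.arg(source_tag, .SOURCES)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  n_body <- .scan_gtf_lines(path)
  gr <- if (n_body > 0) rtracklayer::import(path, format = "gtf") else NULL
  if (!is.null(gr)) gr <- gr[gr$type == "exon"]
  if (is.null(gr) || length(gr) == 0) {
    return(transcript_models(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      source = character(), biotype = character()
    )))
  }
  bt <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    dplyr::case_match(as.character(gr$gene_biotype),
                      "protein_coding" ~ "coding",
                      "coding" ~ "coding",
                      "lncRNA" ~ "lncRNA",
                      .default = "unknown")
  } else "unknown"
  exons <- tibble(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    source = source_tag,
    biotype = bt
  )
  if (!is.null(biotypes)) {
    hit <- exons$gene_id %in% names(biotypes)
    exons$biotype[hit] <- unname(biotypes[exons$gene_id[hit]])
  }
  transcript_models(exons)
}

#' Write transcript models (or merged loci) to GTF
#'
#' Emits one `exon` line per exon with `gene_id` and `transcript_id`
#' attributes, plus `gene_biotype` when known and `locus_class` when the
#' table carries a positional class column. Reading the file back with
#' [read_gtf()] reproduces the exon structures, strands and ids
#' (round-trip identity).
#'
#' @param exons A validated exon tibble; may carry extra columns `locus_id`
#'   and `positional_class` (e.g. from [merge_sources()] + classification).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  if (nrow(exons) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- .exons_granges(exons)
  S4Vectors::mcols(gr)$source <- exons$source
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  S4Vectors::mcols(gr)$transcript_id <- exons$transcript_id
  if (any(exons$biotype != "unknown")) {
    S4Vectors::mcols(gr)$gene_biotype <-
      if_else(exons$biotype == "coding", "protein_coding", exons$biotype)
  }
  if ("locus_id" %in% names(exons)) {
    S4Vectors::mcols(gr)$locus_id <- exons$locus_id
  }
  if ("positional_class" %in% names(exons)) {
    cls <- exons$positional_class
    if (any(cls != "unset")) {
      S4Vectors::mcols(gr)$locus_class <- if_else(cls == "unset", NA_character_, cls)
    }
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Export loci as BED6
#'
#' One line per locus span; the score column carries 0 and the name column
#' the locus id.
#'
#' @param loci A locus tibble (`locus_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   loci$chrom, loci$start - 1L, loci$end, loci$locus_id,
                   if_else(loci$strand == "*", ".", loci$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Expression matrices
#'
#' An expression matrix couples a genes-by-samples value table with per-sample
#' metadata. `values` is a tibble whose first column is `gene_id` and whose
#' remaining columns are samples; `samples` is a tibble with columns `sample`,
#' `condition` (stage or tissue label) and `replicate`; `unit` is `"FPKM"` or
#' `"count"`. All cells must be present and non-negative; counts must be
#' integers; every value column must have metadata.
#'
#' @param values Tibble, `gene_id` + one column per sample.
#' @param samples Tibble with `sample`, `condition`, `replicate`.
#' @param unit `"FPKM"` or `"count"`.
#' @return A validated `expr_matrix` object (list with the three fields).
#' @export
expression_matrix <- function(values, samples, unit = c("FPKM", "count")) {
  unit <- match.arg(unit)
  values <- as_tibble(values)
  samples <- as_tibble(samples)
  if (names(values)[1] != "gene_id") {
    names(values)[1] <- "gene_id"
  }
  cols <- setdiff(names(values), "gene_id")
  if (length(cols) == 0) abort("expression matrix has no sample columns")
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(samples))) {
    abort("sample metadata needs columns sample, condition, replicate")
  }
  miss <- setdiff(cols, samples$sample)
  if (length(miss) > 0) {
    abort(paste0("sample column(s) without metadata: ",
                 paste(miss, collapse = ", ")))
  }
  samples <- filter(samples, .data$sample %in% cols)
  samples <- samples[match(cols, samples$sample), ]
  m <- as.matrix(values[cols])
  if (!is.numeric(m) || anyNA(m)) abort("expression values must be numeric and complete")
  if (any(m < 0)) abort("negative expression value")
  if (unit == "count" && any(m != round(m))) {
    abort("count matrix contains non-integer values")
  }
  if (anyDuplicated(values$gene_id)) abort("duplicated gene_id rows")
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s], %d condition(s)\n",
              nrow(x$values), nrow(x$samples), x$unit,
              dplyr::n_distinct(x$samples$condition)))
  print(head(x$values, 5))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) c(nrow(x$values), nrow(x$samples))

#' Tidy an expression matrix to long form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble `gene_id`, `sample`, `condition`, `replicate`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  x$values |>
    pivot_longer(-"gene_id", names_to = "sample", values_to = "value") |>
    left_join(x$samples, by = "sample") |>
    select("gene_id", "sample", "condition", "replicate", "value")
}

# numeric matrix view (genes in rownames)
.em_matrix <- function(x) {
  m <- as.matrix(x$values[setdiff(names(x$values), "gene_id")])
  rownames(m) <- x$values$gene_id
  m
}

#' Read an expression matrix with its sample sidecar
#'
#' The matrix is a TSV whose first column is `gene_id` and whose header names
#' the samples; the sidecar is a TSV with columns `sample`, `condition`,
#' `replicate` mapping every column to its stage/tissue and replicate index.
#'
#' @param path Matrix TSV path.
#' @param samples_path Sidecar TSV path.
#' @param unit `"FPKM"` or `"count"`.
#' @return A validated `expr_matrix`.
#' @export
read_matrix <- function(path, samples_path, unit = c("FPKM", "count")) {
  values <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  expression_matrix(values, samples, unit = match.arg(unit))
}

#' Write an expression matrix and its sample sidecar
#'
#' @param x An `expr_matrix`.
#' @param path Matrix TSV path.
#' @param samples_path Sidecar TSV path (default: `path` + `.samples.tsv`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, samples_path = paste0(path, ".samples.tsv")) {
  readr::write_tsv(x$values, path, progress = FALSE)
  readr::write_tsv(x$samples, samples_path, progress = FALSE)
  invisible(path)
}

#' Read a conservation score track (bedGraph)
#'
#' bedGraph semantics: 0-based half-open records, converted to 1-based
#' inclusive on input. Scores must lie in [0, 1] and records within one
#' chromosome must not overlap. Bases not covered by any record score 0.
#'
#' @param path bedGraph path.
#' @return A tibble `chrom`, `start`, `end`, `score`.
#' @export
read_score_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score)
  )
  validate_score_track(track)
}

#' Validate a score track tibble
#'
#' @param track Tibble `chrom`, `start`, `end`, `score` (1-based inclusive).
#' @return The validated tibble, sorted by chrom then start.
#' @export
validate_score_track <- function(track) {
  track <- as_tibble(track)
  if (any(track$score < 0 | track$score > 1)) {
    abort("score track values must lie in [0, 1]")
  }
  track <- arrange(track, .data$chrom, .data$start)
  ovl <- track |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start <= lag(.data$end, default = 0L) &
                          row_number() > 1), .groups = "drop")
  if (any(ovl$bad)) abort("score track has overlapping records on one chromosome")
  track
}

#' Write a score track as bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end`, `score` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start - 1L,
                   track$end, format(track$score, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
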