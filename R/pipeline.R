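# End-to-end pipeline wiring: config validation, the synthetic demo, and a
# run manifest making reruns verifiable.

.default_config <- function() {
  list(
    seed = 1,
    n_coding = 20, n_lnc_per_class = 5, chrom_length = 1e6,
    depth = 200, bias = 0.95,
    min_length = 200, fold = 2, alpha = 0.05,
    fpkm_gate = 1, n_stages = 10, n_reps = 2, n_tissues = 15,
    noise_sd = 0.2, tau_threshold = 0.8,
    window = 1000, intronic_frac = 0.5,
    max_dist = 100000, min_cor = 0.9, cut_height = 0.3,
    min_module_size = 4, lfc = 1, de_alpha = 0.05,
    n_mutant_genes = 1000, n_de = 50, dispersion = 0.05, n_mutant_reps = 3
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and thresholds outside their
#' documented ranges.
#'
#' @param config A named list of overrides (may be empty).
#' @return The completed configuration list.
#' @export
validate_pipeline_config <- function(config = list()) {
  def <- .default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config)
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  chk(cfg$fold >= 1, "fold must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must lie in (0, 1]")
  chk(cfg$de_alpha > 0 && cfg$de_alpha <= 1, "de_alpha must lie in (0, 1]")
  chk(cfg$bias >= 0.5 && cfg$bias <= 1, "bias must lie in [0.5, 1]")
  chk(cfg$min_length >= 0, "min_length must be non-negative")
  chk(cfg$fpkm_gate >= 0, "fpkm_gate must be non-negative")
  chk(cfg$window >= 0, "window must be non-negative")
  chk(cfg$intronic_frac > 0 && cfg$intronic_frac <= 1,
      "intronic_frac must lie in (0, 1]")
  chk(cfg$min_cor >= -1 && cfg$min_cor <= 1, "min_cor must lie in [-1, 1]")
  chk(cfg$max_dist >= 0, "max_dist must be non-negative")
  chk(cfg$cut_height > 0 && cfg$cut_height < 2, "cut_height must lie in (0, 2)")
  chk(cfg$lfc >= 0, "lfc must be non-negative")
  chk(cfg$tau_threshold >= 0 && cfg$tau_threshold <= 1,
      "tau_threshold must lie in [0, 1]")
  chk(cfg$dispersion >= 0, "dispersion must be non-negative")
  chk(cfg$seed == as.integer(cfg$seed), "seed must be an integer")
  cfg
}

#' Run the full synthetic demo pipeline
#'
#' Generates a toy genome with planted lncRNAs, writes its input files,
#' reads them back, and runs the whole workflow: per-source filtering,
#' strand assignment, three-source merging, expression gating, positional
#' classification, stage/tau/tissue analytics, cis/trans target calling,
#' and three simulated knockout contrasts with the NB test. All outputs and
#' a JSON run manifest land in `out_dir`; a rerun with the same config is
#' bit-identical.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config Named list of config overrides (see
#'   [validate_pipeline_config()]).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
lnc_demo <- function(out_dir, seed = 1, config = list()) {
  config$seed <- seed
  cfg <- validate_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- file.path(out_dir, "inputs")

  # --- synthetic inputs ---
  truth <- make_toy_genome(n_coding = cfg$n_coding,
                           n_lnc_per_class = cfg$n_lnc_per_class,
                           chrom_length = cfg$chrom_length,
                           seed = cfg$seed, dir = inp)
  strand_counts <- make_stranded_counts(truth, depth = cfg$depth,
                                        bias = cfg$bias, seed = cfg$seed + 1)
  readr::write_tsv(select(strand_counts, -"true_strand"),
                   file.path(inp, "stranded_counts.tsv"), progress = FALSE)

  # --- identification cascade (from the files on disk) ---
  ann <- read_gtf(file.path(inp, "annotation.gtf"), "annotation")
  sr <- read_gtf(file.path(inp, "short_read.gtf"), "short_read")
  lr <- read_gtf(file.path(inp, "long_read.gtf"), "long_read")
  cp <- readr::read_tsv(file.path(inp, "coding_potential.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  coding <- filter(ann, .data$biotype == "coding")
  ann_lnc <- filter(ann, .data$biotype == "lncRNA")
  sr_kept <- filter_short_read_set(sr, coding, cp, min_length = cfg$min_length)
  calls <- assign_strand(readr::read_tsv(file.path(inp, "stranded_counts.tsv"),
                                         show_col_types = FALSE,
                                         progress = FALSE),
                         fold = cfg$fold, alpha = cfg$alpha)
  readr::write_tsv(calls, file.path(out_dir, "strand_calls.tsv"),
                   progress = FALSE)
  lr_kept <- filter_long_read_set(lr, calls, coding)
  merged <- merge_sources(ann_lnc, sr_kept, lr_kept)
  write_gtf(mutate(merged$transcripts, gene_id = .data$locus_id),
            file.path(out_dir, "merged.gtf"))

  # --- expression + gate (locus ids mapped onto the planted gene ids) ---
  expr <- make_expression(truth, n_stages = cfg$n_stages, n_reps = cfg$n_reps,
                          n_tissues = cfg$n_tissues, noise_sd = cfg$noise_sd,
                          seed = cfg$seed + 2)
  id_map <- merged$members |>
    left_join(distinct(bind_rows(ann_lnc, sr_kept, lr_kept),
                       .data$transcript_id, .data$gene_id),
              by = c(member_id = "transcript_id")) |>
    distinct(.data$locus_id, .data$gene_id)
  relabel <- function(em) {
    v <- em$values
    hit <- match(v$gene_id, id_map$gene_id)
    v$gene_id <- if_else(is.na(hit), v$gene_id, id_map$locus_id[hit])
    expression_matrix(v, em$samples, em$unit)
  }
  fpkm <- relabel(expr$stages)
  panel <- relabel(expr$tissues)
  write_matrix(fpkm, file.path(out_dir, "fpkm_stages.tsv"))
  gated <- expression_gate(merged, fpkm, threshold = cfg$fpkm_gate)

  # --- classification ---
  classes <- classify_loci(gated, coding, window = cfg$window,
                           intronic_frac = cfg$intronic_frac)
  readr::write_tsv(classes, file.path(out_dir, "classes.tsv"),
                   progress = FALSE)

  # --- expression analytics ---
  spec <- tau_specificity(fpkm, threshold = cfg$tau_threshold)
  readr::write_tsv(spec, file.path(out_dir, "tau.tsv"), progress = FALSE)
  lnc_ids <- gated$loci$locus_id
  calls_tbl <- expressed_calls(
    expression_matrix(filter(fpkm$values, .data$gene_id %in% lnc_ids),
                      fpkm$samples, "FPKM"),
    threshold = cfg$fpkm_gate)
  sharing <- stage_sharing(calls_tbl)
  readr::write_tsv(sharing$pairwise, file.path(out_dir, "stage_sharing.tsv"),
                   progress = FALSE)
  tspec <- tissue_specificity(fpkm, panel, threshold = 1)
  readr::write_tsv(tspec, file.path(out_dir, "tissue_specificity.tsv"),
                   progress = FALSE)

  # --- regulation ---
  coding_genes <- .coding_index(coding)$genes
  modules <- detect_modules(fpkm, min_module_size = cfg$min_module_size,
                            cut_height = cfg$cut_height)
  cis <- call_cis(gated$loci, coding_genes, fpkm, max_dist = cfg$max_dist,
                  min_cor = cfg$min_cor, alpha = cfg$alpha)
  trans <- call_trans(lnc_ids, coding_genes$gene_id, fpkm, modules,
                      min_cor = cfg$min_cor)
  regulation <- bind_rows(cis, trans)
  readr::write_tsv(regulation, file.path(out_dir, "regulation.tsv"),
                   progress = FALSE)

  # --- knockout contrasts on the identified loci ---
  contrasts <- list()
  for (k in 1:3) {
    mc <- make_mutant_counts(gene_ids = lnc_ids,
                             n_de = min(cfg$n_de, length(lnc_ids) %/% 4),
                             n_reps = cfg$n_mutant_reps,
                             dispersion = cfg$dispersion,
                             seed = cfg$seed + 10 + k)
    de <- nb_test(mc$wt, mc$mut, lfc_threshold = cfg$lfc,
                  alpha = cfg$de_alpha)
    contrasts[[paste0("KO", k)]] <- de
    readr::write_tsv(de_intergenic(de, classes),
                     file.path(out_dir, sprintf("de_intergenic_KO%d.tsv", k)),
                     progress = FALSE)
  }
  cross <- cross_mutant_summary(contrasts)
  readr::write_tsv(cross$directions, file.path(out_dir, "de_directions.tsv"),
                   progress = FALSE)

  # --- manifest ---
  truth_class <- count(truth$lnc_loci, .data$positional_class)
  manifest <- list(
    config = cfg,
    truth = list(n_lnc_loci = nrow(truth$lnc_loci),
                 class_counts = setNames(as.list(truth_class$n),
                                         truth_class$positional_class)),
    counts = list(
      identified_loci = merged$report$n_loci,
      identified_class_counts = setNames(
        as.list(class_summary(classify_loci(merged, coding,
                                            window = cfg$window,
                                            intronic_frac = cfg$intronic_frac))$n),
        .CLASSES),
      gated_loci = nrow(gated$loci),
      strand_assigned = sum(calls$assigned_strand != "unassigned"),
      cis_calls = nrow(cis), trans_calls = nrow(trans),
      de_genes = map_int(contrasts, ~ sum(.x$results$is_de))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, merged = merged, gated = gated,
                 classes = classes, specificity = spec, sharing = sharing,
                 modules = modules, regulation = regulation,
                 contrasts = contrasts, cross = cross, manifest = manifest))
}

#' Run the pipeline on user-supplied input files
#'
#' The file-driven twin of [lnc_demo()]: reads the three source GTFs, the
#' stranded count table, the coding-potential table and the FPKM matrix from
#' `paths`, runs identification, merging, gating and classification, and
#' writes the merged GTF plus per-stage tables to `out_dir`.
#'
#' @param paths Named list: `annotation`, `short_read`, `long_read` (GTF),
#'   `stranded_counts` (TSV), `coding_potential` (TSV), `fpkm` and
#'   `fpkm_samples` (TSV matrix + sidecar).
#' @param out_dir Output directory.
#' @param config Named list of config overrides.
#' @return Invisibly, a list with `merged`, `gated` and `classes`.
#' @export
run_lnc_pipeline <- function(paths, out_dir, config = list()) {
  cfg <- validate_pipeline_config(config)
  need <- c("annotation", "short_read", "long_read", "stranded_counts",
            "coding_potential", "fpkm", "fpkm_samples")
  miss <- setdiff(need, names(paths))
  if (length(miss) > 0) {
    abort(paste0("missing input path(s): ", paste(miss, collapse = ", ")))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ann <- read_gtf(paths$annotation, "annotation")
  sr <- read_gtf(paths$short_read, "short_read")
  lr <- read_gtf(paths$long_read, "long_read")
  cp <- readr::read_tsv(paths$coding_potential, show_col_types = FALSE,
                        progress = FALSE)
  counts <- readr::read_tsv(paths$stranded_counts, show_col_types = FALSE,
                            progress = FALSE)
  fpkm <- read_matrix(paths$fpkm, paths$fpkm_samples, "FPKM")
  coding <- filter(ann, .data$biotype == "coding")
  ann_lnc <- filter(ann, .data$biotype == "lncRNA")
  sr_kept <- filter_short_read_set(sr, coding, cp, min_length = cfg$min_length)
  calls <- assign_strand(counts, fold = cfg$fold, alpha = cfg$alpha)
  lr_kept <- filter_long_read_set(lr, calls, coding)
  merged <- merge_sources(ann_lnc, sr_kept, lr_kept)
  gated <- expression_gate(merged, fpkm, threshold = cfg$fpkm_gate)
  classes <- classify_loci(gated, coding, window = cfg$window,
                           intronic_frac = cfg$intronic_frac)
  write_gtf(mutate(gated$transcripts, gene_id = .data$locus_id),
            file.path(out_dir, "merged.gtf"))
  readr::write_tsv(calls, file.path(out_dir, "strand_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(classes, file.path(out_dir, "classes.tsv"),
                   progress = FALSE)
  invisible(list(merged = merged, gated = gated, classes = classes))
}
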