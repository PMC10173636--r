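# Expression analytics over developmental stages and tissues: FPKM, expressed
# calls, tau specificity, stage sharing, correlation structure, PCA, and
# tissue-specificity calls.

# genes x conditions matrix of a per-condition row statistic; shape-safe for
# single-gene matrices
.cond_matrix <- function(m, samples, fun) {
  conds <- unique(samples$condition)
  res <- lapply(conds, function(cc) {
    fun(m[, samples$sample[samples$condition == cc], drop = FALSE])
  })
  matrix(unlist(res), nrow = nrow(m),
         dimnames = list(rownames(m), conds))
}

#' FPKM from raw counts
#'
#' FPKM = count * 1e9 / (exonic length * column total). Doubling every count
#' in a column leaves its FPKM unchanged (scale invariance), and the column
#' identity sum(FPKM * length) / 1e9 = 1 holds per sample.
#'
#' @param counts A count `expr_matrix`.
#' @param exonic_lengths Named vector of exonic lengths (bp) covering every
#'   gene.
#' @return An FPKM `expr_matrix` with the same samples.
#' @export
fpkm_from_counts <- function(counts, exonic_lengths) {
  if (counts$unit != "count") abort("fpkm_from_counts needs a count matrix")
  m <- .em_matrix(counts)
  miss <- setdiff(rownames(m), names(exonic_lengths))
  if (length(miss) > 0) {
    abort(paste0("gene(s) without exonic length: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  len <- exonic_lengths[rownames(m)]
  if (any(len <= 0)) abort("exonic lengths must be positive")
  tot <- colSums(m)
  if (any(tot == 0)) abort("column with zero total count")
  fp <- sweep(m * 1e9 / len, 2, tot, "/")
  expression_matrix(bind_cols(tibble(gene_id = rownames(m)), as_tibble(fp)),
                    counts$samples, unit = "FPKM")
}

#' Per-condition expressed / not-expressed calls
#'
#' A gene counts as expressed in a condition (stage) iff its FPKM reaches
#' `threshold` in at least `min_samples` replicate columns of that condition
#' (default: both replicates of a two-replicate design; `min_samples` is
#' capped at the condition's replicate count).
#'
#' @param fpkm An FPKM `expr_matrix`.
#' @param threshold FPKM cutoff (inclusive).
#' @param min_samples Replicates required at or above the cutoff.
#' @return A tibble `gene_id` x condition of logicals, conditions in the
#'   order they appear in the sample metadata.
#' @export
expressed_calls <- function(fpkm, threshold = 1, min_samples = 2) {
  m <- .em_matrix(fpkm)
  hits <- .cond_matrix(m, fpkm$samples, function(x) rowSums(x >= threshold))
  reps <- table(fpkm$samples$condition)[colnames(hits)]
  need <- pmin(min_samples, as.integer(reps))
  calls <- sweep(hits, 2, need, ">=")
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(calls))
}

#' Tissue/stage specificity index tau
#'
#' tau = sum(1 - x_i / max(x)) / (N - 1) over an N-condition expression
#' profile: 0 for uniform expression, 1 for expression confined to a single
#' condition. Undefined (NA) for an all-zero profile. tau is invariant to
#' positive rescaling of the profile.
#'
#' @param x Non-negative expression profile (one value per condition, N >= 2).
#' @return tau in [0, 1], or NA for an all-zero profile.
#' @examples
#' tau(c(5, 5, 5, 5))   # 0
#' tau(c(8, 0, 0, 0))   # 1
#' @export
tau <- function(x) {
  if (length(x) < 2) abort("tau needs at least two conditions")
  if (any(x < 0)) abort("tau needs a non-negative profile")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Per-gene tau over stage means
#'
#' Averages replicates within each condition (optionally after a
#' log2(FPKM + 1) transform, the default, which damps outlier dominance) and
#' computes tau per gene.
#'
#' @param fpkm An FPKM `expr_matrix`.
#' @param threshold Specificity call threshold on tau.
#' @param transform `"log2"` (tau on log2(FPKM + 1) stage means) or `"raw"`.
#' @return A tibble `gene_id`, `tau`, `peak_condition`, `is_specific`.
#' @export
tau_specificity <- function(fpkm, threshold = 0.8,
                            transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  m <- .em_matrix(fpkm)
  if (transform == "log2") m <- log2(m + 1)
  sm <- .cond_matrix(m, fpkm$samples, rowMeans)
  taus <- unname(apply(sm, 1, tau))
  tibble(gene_id = rownames(m), tau = taus,
         peak_condition = colnames(sm)[max.col(sm, ties.method = "first")],
         is_specific = !is.na(taus) & taus >= threshold)
}

#' Stage sharing and accumulation of expressed genes
#'
#' From a per-condition expressed-call table (conditions in chronological
#' order): per-condition expressed counts, pairwise shared counts with the
#' shared fraction relative to each member, and the cumulative number of
#' distinct genes detected up to each condition (whose increments are the
#' novel genes per condition).
#'
#' @param calls Output of [expressed_calls()].
#' @return A `stage_sharing` list: `$per_stage`, `$pairwise`, `$cumulative`.
#' @export
stage_sharing <- function(calls) {
  conds <- setdiff(names(calls), "gene_id")
  if (length(conds) < 2) abort("stage sharing needs at least two conditions")
  m <- as.matrix(calls[conds])
  per_stage <- tibble(condition = conds, n_expressed = unname(colSums(m)))
  pairs <- tidyr::expand_grid(a = conds, b = conds) |> filter(.data$a < .data$b)
  cs <- colSums(m)
  pairwise <- pairs |>
    mutate(shared = purrr::map2_int(.data$a, .data$b,
                                    ~ sum(m[, .x] & m[, .y])),
           frac_a = .data$shared / unname(cs[.data$a]),
           frac_b = .data$shared / unname(cs[.data$b]))
  seen <- rep(FALSE, nrow(m))
  cum <- integer(length(conds)); novel <- integer(length(conds))
  for (i in seq_along(conds)) {
    novel[i] <- sum(m[, i] & !seen)
    seen <- seen | m[, i]
    cum[i] <- sum(seen)
  }
  structure(list(per_stage = per_stage,
                 pairwise = pairwise,
                 cumulative = tibble(condition = conds, novel = novel,
                                     cumulative = cum)),
            class = "stage_sharing")
}

#' @export
print.stage_sharing <- function(x, ...) {
  cat("<stage_sharing>\n"); print(x$per_stage); print(x$cumulative)
  invisible(x)
}

#' Tidy stage sharing to the pairwise table
#'
#' @param x A `stage_sharing`.
#' @param ... Unused.
#' @return The pairwise shared-count tibble.
#' @export
tidy.stage_sharing <- function(x, ...) x$pairwise

#' Accumulation-curve plot of detectable genes
#'
#' @param x A `stage_sharing`.
#' @return A ggplot object.
#' @export
plot_accumulation <- function(x) {
  d <- mutate(x$cumulative, condition = factor(.data$condition,
                                               levels = .data$condition))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$cumulative,
                                  group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "cumulative detectable genes") +
    ggplot2::theme_minimal()
}

#' Sample correlation structure: matrix, dendrogram and PCA
#'
#' Pairwise sample correlations (Spearman by default) on log2(FPKM + 1),
#' average-linkage hierarchical clustering on 1 - correlation, and PCA of
#' samples on the log-transformed, gene-centered matrix with
#' explained-variance fractions.
#'
#' @param fpkm An FPKM `expr_matrix` with at least two samples.
#' @param method `"spearman"` or `"pearson"`.
#' @return An `lnc_corstruct`: `$cor` (matrix), `$hclust`, `$pca_scores`
#'   (tibble), `$var_explained` (fractions summing to 1).
#' @export
correlation_structure <- function(fpkm, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- log2(.em_matrix(fpkm) + 1)
  if (ncol(m) < 2) abort("need at least two samples")
  cm <- suppressWarnings(cor(m, method = method))
  zero_var <- apply(m, 2, sd) == 0
  if (any(zero_var)) {
    cm[zero_var, ] <- NA; cm[, zero_var] <- NA; diag(cm) <- 1
    warn("zero-variance sample column(s); correlations flagged NA")
  }
  hc <- hclust(as.dist(1 - ifelse(is.na(cm), 0, cm)), method = "average")
  keep <- apply(m, 1, sd) > 0
  pc <- prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- bind_cols(tibble(sample = colnames(m)),
                      as_tibble(pc$x)) |>
    left_join(fpkm$samples, by = "sample")
  structure(list(cor = cm, hclust = hc, pca_scores = scores,
                 var_explained = ve, method = method),
            class = "lnc_corstruct")
}

#' @export
print.lnc_corstruct <- function(x, ...) {
  cat(sprintf("<lnc_corstruct> %d samples, %s correlation; PC1 %.1f%%, PC2 %.1f%%\n",
              ncol(x$cor), x$method, 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Tidy PCA scores of a correlation structure
#'
#' @param x An `lnc_corstruct`.
#' @param ... Unused.
#' @return The PCA score tibble with sample metadata.
#' @export
tidy.lnc_corstruct <- function(x, ...) x$pca_scores

#' Variance explained summary
#'
#' @param x An `lnc_corstruct`.
#' @param ... Unused.
#' @return One-row tibble with PC1/PC2 variance fractions and sample count.
#' @export
glance.lnc_corstruct <- function(x, ...) {
  tibble(n_samples = ncol(x$cor), pc1_var = x$var_explained[1],
         pc2_var = x$var_explained[2])
}

#' PCA plot of samples
#'
#' @param object An `lnc_corstruct`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_corstruct <- function(object, ...) {
  ggplot2::ggplot(object$pca_scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Retina-specific versus shared tissue expression
#'
#' A gene is tissue-specific to the focal tissue (retina) iff its FPKM stays
#' strictly below `threshold` in every non-retina tissue of the panel;
#' otherwise the tissues at or above the threshold are listed.
#'
#' @param retina_fpkm Focal-tissue FPKM `expr_matrix` (any sample columns).
#' @param panel_fpkm Body-panel FPKM `expr_matrix`, one condition per tissue;
#'   a condition named `retina` is ignored as panel evidence.
#' @param threshold FPKM cutoff.
#' @return A tibble `gene_id`, `retina_specific`, `shared_tissues`
#'   (comma-separated, empty when specific), `n_shared`. Genes missing from
#'   the panel are flagged NA and excluded from specificity calls.
#' @export
tissue_specificity <- function(retina_fpkm, panel_fpkm, threshold = 1) {
  genes <- retina_fpkm$values$gene_id
  pm <- .em_matrix(panel_fpkm)
  non_ret <- panel_fpkm$samples$sample[panel_fpkm$samples$condition != "retina"]
  pm <- pm[, non_ret, drop = FALSE]
  hit <- match(genes, rownames(pm))
  res <- purrr::map_dfr(seq_along(genes), function(i) {
    if (is.na(hit[i])) {
      return(tibble(gene_id = genes[i], retina_specific = NA,
                    shared_tissues = NA_character_, n_shared = NA_integer_))
    }
    v <- pm[hit[i], ]
    on <- names(v)[v >= threshold]
    tibble(gene_id = genes[i], retina_specific = length(on) == 0,
           shared_tissues = paste(on, collapse = ","),
           n_shared = length(on))
  })
  if (anyNA(res$retina_specific)) {
    warn(paste0(sum(is.na(res$retina_specific)),
                " gene(s) missing from the tissue panel"))
  }
  res
}
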