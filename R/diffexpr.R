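# Negative-binomial differential expression for mutant-versus-wild-type
# contrasts: median-of-ratios normalization, method-of-moments dispersion
# with trend shrinkage, and a Wald test on the log fold change.

#' Median-of-ratios size factors and normalized counts
#'
#' Per-sample size factor = median over genes of the ratio of the sample's
#' count to the gene's geometric mean across samples, using only genes with
#' positive counts in every sample; normalized counts = counts / size factor.
#'
#' @param counts Count matrix (genes x samples) or a count `expr_matrix`.
#' @return A list `size_factors` (named vector) and `normalized` (matrix).
#' @export
normalize_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "expr_matrix")) .em_matrix(counts) else as.matrix(counts)
  if (ncol(m) < 2) abort("need at least two samples")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort("no gene has positive counts in all samples; cannot form the reference")
  }
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)
  sf <- apply(exp(logm - ref), 2, median)
  list(size_factors = sf, normalized = sweep(m, 2, sf, "/"))
}

# gene-wise NB dispersion: method of moments on normalized counts pooled
# within groups, shrunk toward an a0 + a1/mu trend fit
.estimate_dispersion <- function(norm, group, prior_weight = 6) {
  g1 <- norm[, group == levels(factor(group))[1], drop = FALSE]
  g2 <- norm[, group == levels(factor(group))[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  mu1 <- rowMeans(g1); mu2 <- rowMeans(g2)
  ss <- rowSums((g1 - mu1)^2) + rowSums((g2 - mu2)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df
  mu <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  raw <- if_else(mu > 0, (s2 - mu) / mu^2, NA_real_)
  use <- !is.na(raw) & raw > 0 & mu > 0
  trend <- if (sum(use) >= 10) {
    fit <- lm(raw[use] ~ I(1 / mu[use]))
    pmax(coef(fit)[1] + coef(fit)[2] / mu, 1e-8)
  } else {
    rep(max(mean(raw[use]), 1e-8), length(mu))
  }
  raw_f <- pmax(dplyr::coalesce(raw, trend), 1e-8)
  # precision-weighted compromise between gene-wise and trend estimates
  (df * raw_f + prior_weight * trend) / (df + prior_weight)
}

#' Negative-binomial Wald test for two-group contrasts
#'
#' Counts are normalized by median-of-ratios across both groups jointly;
#' per-gene log2 fold change is the ratio of normalized group means with a
#' pseudo-count of 0.5; gene-wise NB dispersion comes from a method-of-moments
#' estimate shrunk toward an a0 + a1/mu mean-dispersion trend; the Wald
#' statistic tests equal means under NB sampling. A gene is called
#' differential iff |log2 fold change| >= `lfc_threshold` and raw
#' p <= `alpha`; a BH-adjusted column is reported alongside.
#'
#' @param counts_wt,counts_mut Count `expr_matrix` objects (or matrices) with
#'   the same genes; at least 2 replicates per group recommended (with a
#'   single replicate the dispersion is pooled across groups and a warning
#'   is emitted).
#' @param lfc_threshold Absolute log2 fold-change threshold (inclusive).
#' @param alpha Raw p-value threshold (inclusive).
#' @return An `lnc_de` object; `tidy()` gives the per-gene table with
#'   `gene_id`, `base_mean`, `log2fc` (mutant over wild type), `p_value`,
#'   `p_adj`, `is_de`, `direction`.
#' @export
nb_test <- function(counts_wt, counts_mut, lfc_threshold = 1, alpha = 0.05) {
  mw <- if (inherits(counts_wt, "expr_matrix")) .em_matrix(counts_wt) else as.matrix(counts_wt)
  mm <- if (inherits(counts_mut, "expr_matrix")) .em_matrix(counts_mut) else as.matrix(counts_mut)
  if (nrow(mw) != nrow(mm) ||
      !identical(rownames(mw), rownames(mm))) {
    abort("wild-type and mutant matrices must share the same genes")
  }
  n1 <- ncol(mw); n2 <- ncol(mm)
  if (n1 < 2 || n2 < 2) warn("fewer than 2 replicates in a group; dispersion is pooled")
  joint <- cbind(mw, mm)
  group <- factor(rep(c("WT", "MUT"), c(n1, n2)), levels = c("WT", "MUT"))
  nr <- normalize_median_of_ratios(joint)
  norm <- nr$normalized
  mu_wt <- rowMeans(norm[, group == "WT", drop = FALSE])
  mu_mut <- rowMeans(norm[, group == "MUT", drop = FALSE])
  disp <- if (n1 >= 2 && n2 >= 2) {
    .estimate_dispersion(norm, group)
  } else {
    mu <- (n1 * mu_wt + n2 * mu_mut) / (n1 + n2)
    s2 <- apply(norm, 1, var)
    rep(max(median((s2 - mu) / mu^2, na.rm = TRUE), 1e-2), nrow(norm))
  }
  lfc <- log2((mu_mut + 0.5) / (mu_wt + 0.5))
  se_ln <- sqrt((1 / (mu_wt + 0.5) + disp) / n1 +
                  (1 / (mu_mut + 0.5) + disp) / n2)
  z <- (log(mu_mut + 0.5) - log(mu_wt + 0.5)) / se_ln
  p <- 2 * pnorm(-abs(z))
  allzero <- mu_wt + mu_mut == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  res <- tibble(
    gene_id = rownames(norm),
    base_mean = unname((mu_wt + mu_mut) / 2),
    log2fc = unname(lfc),
    p_value = unname(p),
    p_adj = unname(p.adjust(p, "BH"))) |>
    mutate(is_de = abs(.data$log2fc) >= lfc_threshold & .data$p_value <= alpha,
           direction = dplyr::case_when(
             .data$is_de & .data$log2fc > 0 ~ "up",
             .data$is_de & .data$log2fc < 0 ~ "down",
             TRUE ~ "none"))
  structure(list(results = res, size_factors = nr$size_factors,
                 dispersion = setNames(disp, rownames(norm)),
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 n_wt = n1, n_mut = n2),
            class = "lnc_de")
}

#' @export
print.lnc_de <- function(x, ...) {
  cat(sprintf("<lnc_de> %d genes, %d vs %d replicates: %d up, %d down (|lfc| >= %g, p <= %g)\n",
              nrow(x$results), x$n_wt, x$n_mut,
              sum(x$results$direction == "up"),
              sum(x$results$direction == "down"),
              x$lfc_threshold, x$alpha))
  invisible(x)
}

#' Per-gene differential expression table
#'
#' @param x An `lnc_de`.
#' @param ... Unused.
#' @return The per-gene result tibble.
#' @export
tidy.lnc_de <- function(x, ...) x$results

#' One-row differential expression summary
#'
#' @param x An `lnc_de`.
#' @param ... Unused.
#' @return Tibble with gene/up/down counts and thresholds.
#' @export
glance.lnc_de <- function(x, ...) {
  tibble(n_genes = nrow(x$results),
         n_up = sum(x$results$direction == "up"),
         n_down = sum(x$results$direction == "down"),
         lfc_threshold = x$lfc_threshold, alpha = x$alpha)
}

#' Volcano plot of a contrast
#'
#' @param object An `lnc_de`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_de <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", none = "grey70")) +
    ggplot2::labs(x = "log2 fold change (mutant / WT)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Restrict a differential-expression table to intergenic loci
#'
#' Overlap between lncRNA and mRNA gene bodies confounds count attribution,
#' so knockout contrasts are interpreted on strict intergenic lncRNAs only.
#' Genes without a class label are excluded with a warning.
#'
#' @param de An `lnc_de` or its tidy tibble.
#' @param classes Classification tibble from [classify_loci()].
#' @return The filtered result tibble.
#' @export
de_intergenic <- function(de, classes) {
  res <- if (inherits(de, "lnc_de")) de$results else as_tibble(de)
  cls <- classes$positional_class[match(res$gene_id, classes$locus_id)]
  if (anyNA(cls)) {
    warn(paste0(sum(is.na(cls)), " tested gene(s) without a class label; excluded"))
  }
  filter(res, !is.na(cls) & cls == "intergenic")
}

#' Direction matrix across knockout contrasts
#'
#' Collates per-contrast calls into a gene x contrast direction matrix and
#' convenience lists of genes moving the same way in all contrasts or in
#' opposite ways somewhere.
#'
#' @param contrast_results Named list of `lnc_de` objects or tidy DE tibbles
#'   (>= 2 contrasts).
#' @return An `lnc_cross` list: `$directions` (tibble gene x contrast),
#'   `$shared_up`, `$shared_down`, `$discordant` (gene id vectors).
#' @export
cross_mutant_summary <- function(contrast_results) {
  if (length(contrast_results) < 2) abort("need at least two contrasts")
  if (is.null(names(contrast_results)) || any(names(contrast_results) == "")) {
    abort("contrast_results must be a named list")
  }
  tabs <- imap(contrast_results, function(x, nm) {
    res <- if (inherits(x, "lnc_de")) x$results else as_tibble(x)
    select(res, "gene_id", !!nm := "direction")
  })
  directions <- purrr::reduce(tabs, dplyr::full_join, by = "gene_id") |>
    mutate(across(-"gene_id", ~ replace_na(.x, "none")))
  dm <- as.matrix(directions[-1])
  shared_up <- directions$gene_id[rowSums(dm == "up") == ncol(dm)]
  shared_down <- directions$gene_id[rowSums(dm == "down") == ncol(dm)]
  discordant <- directions$gene_id[rowSums(dm == "up") > 0 &
                                     rowSums(dm == "down") > 0]
  structure(list(directions = directions, shared_up = shared_up,
                 shared_down = shared_down, discordant = discordant),
            class = "lnc_cross")
}

#' @export
print.lnc_cross <- function(x, ...) {
  cat(sprintf("<lnc_cross> %d genes x %d contrasts: %d shared up, %d shared down, %d discordant\n",
              nrow(x$directions), ncol(x$directions) - 1,
              length(x$shared_up), length(x$shared_down),
              length(x$discordant)))
  invisible(x)
}

#' Tidy cross-contrast directions
#'
#' @param x An `lnc_cross`.
#' @param ... Unused.
#' @return The gene x contrast direction tibble.
#' @export
tidy.lnc_cross <- function(x, ...) x$directions
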