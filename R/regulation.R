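# Cis- and trans-target calling from co-expression, module detection, and
# chi-squared term enrichment for target sets.

#' Pearson correlation with a closed-form p-value
#'
#' Two-sided p from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom. Zero variance in either vector flags the result NA.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A one-row tibble `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("x and y must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(x, y)
  p <- .cor_p(r, n)
  tibble(r = r, p_value = p, n = n)
}

# two-sided p for a Pearson r at sample size n (t on n-2 df)
.cor_p <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * pt(tt, df = n - 2, lower.tail = FALSE)
}

#' Detect co-expression modules
#'
#' Hierarchical clustering of genes on the 1 - |r| correlation distance
#' (Pearson on log2(FPKM + 1)), average linkage, tree cut at `cut_height`;
#' clusters smaller than `min_module_size` fall into the background module
#' `"M0"`. Module ids `M1`, `M2`, ... are ordered by decreasing size. Only
#' co-membership is meaningful downstream.
#'
#' @param fpkm An FPKM `expr_matrix` with at least 3 samples.
#' @param min_module_size Smallest cluster kept as a real module.
#' @param cut_height Tree cut height on the 1 - |r| scale.
#' @return A tibble `gene_id`, `module_id`.
#' @export
detect_modules <- function(fpkm, min_module_size = 5, cut_height = 0.3) {
  m <- log2(.em_matrix(fpkm) + 1)
  if (ncol(m) < 3) abort("module detection needs at least 3 samples")
  if (nrow(m) < min_module_size) {
    return(tibble(gene_id = rownames(m), module_id = "M0"))
  }
  ok <- apply(m, 1, sd) > 0
  lab <- rep("M0", nrow(m))
  if (sum(ok) >= 2) {
    r <- suppressWarnings(cor(t(m[ok, , drop = FALSE])))
    r[is.na(r)] <- 0
    hc <- hclust(as.dist(1 - abs(r)), method = "average")
    cl <- cutree(hc, h = cut_height)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_module_size]
    ranks <- rank(-sizes[big], ties.method = "first")
    relab <- setNames(rep("M0", length(sizes)), names(sizes))
    relab[big] <- sprintf("M%d", ranks)
    lab[ok] <- relab[as.character(cl)]
  }
  tibble(gene_id = rownames(m), module_id = lab)
}

# correlation of each lnc row with each coding row on log2(FPKM+1)
.pair_cor <- function(fpkm, lnc_ids, coding_ids) {
  m <- log2(.em_matrix(fpkm) + 1)
  miss <- setdiff(c(lnc_ids, coding_ids), rownames(m))
  if (length(miss) > 0) {
    abort(paste0("gene(s) absent from expression matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  suppressWarnings(cor(t(m[lnc_ids, , drop = FALSE]),
                       t(m[coding_ids, , drop = FALSE])))
}

#' Call cis-regulatory targets
#'
#' For each lncRNA locus, its single nearest coding gene (closest gene-body
#' boundaries, ties broken by distance then gene id) is the only cis
#' candidate; a call is emitted iff the candidate lies within `max_dist` bp
#' and the expression correlation passes `r >= min_cor` and `p <= alpha`
#' (Pearson on log2(FPKM + 1) across samples, raw p).
#'
#' @param lnc_loci Locus tibble (`locus_id`, `chrom`, `start`, `end`,
#'   `strand`), e.g. `tidy()` of an `lnc_merge`.
#' @param coding_genes Coding gene-span tibble (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param fpkm FPKM `expr_matrix` covering loci and coding genes.
#' @param max_dist Maximum boundary-to-boundary distance (bp, inclusive).
#' @param min_cor Correlation threshold (inclusive).
#' @param alpha p-value threshold (inclusive).
#' @return A regulation-call tibble: `lnc_id`, `target_gene_id`, `mode`
#'   (`"cis"`), `distance`, `cor`, `p_value`.
#' @export
call_cis <- function(lnc_loci, coding_genes, fpkm, max_dist = 100000,
                     min_cor = 0.9, alpha = 0.05) {
  if (nrow(lnc_loci) == 0 || nrow(coding_genes) == 0) {
    return(.empty_regulation())
  }
  lg <- GenomicRanges::GRanges(lnc_loci$chrom,
                               IRanges::IRanges(lnc_loci$start, lnc_loci$end))
  gg <- GenomicRanges::GRanges(coding_genes$chrom,
                               IRanges::IRanges(coding_genes$start,
                                                coding_genes$end))
  hits <- GenomicRanges::distanceToNearest(lg, gg, select = "all",
                                           ignore.strand = TRUE)
  nearest <- tibble(li = S4Vectors::queryHits(hits),
                    distance = S4Vectors::mcols(hits)$distance,
                    gene_id = coding_genes$gene_id[S4Vectors::subjectHits(hits)]) |>
    arrange(.data$li, .data$distance, .data$gene_id) |>
    group_by(.data$li) |> dplyr::slice(1) |> ungroup() |>
    mutate(lnc_id = lnc_loci$locus_id[.data$li]) |>
    filter(.data$distance <= max_dist)
  if (nrow(nearest) == 0) return(.empty_regulation())
  cm <- .pair_cor(fpkm, nearest$lnc_id, unique(nearest$gene_id))
  r <- cm[cbind(seq_len(nrow(nearest)),
                match(nearest$gene_id, colnames(cm)))]
  n <- nrow(fpkm$samples)
  nearest |>
    mutate(cor = r, p_value = .cor_p(r, n), mode = "cis") |>
    filter(!is.na(.data$cor), .data$cor >= min_cor, .data$p_value <= alpha) |>
    select("lnc_id", target_gene_id = "gene_id", "mode", "distance",
           "cor", "p_value")
}

.empty_regulation <- function() {
  tibble(lnc_id = character(), target_gene_id = character(),
         mode = character(), distance = integer(), cor = double(),
         p_value = double())
}

#' Call trans-regulatory targets
#'
#' All (lncRNA, coding) pairs with expression correlation `r >= min_cor` that
#' share the same non-background co-expression module.
#'
#' @param lnc_ids,coding_ids Gene id vectors.
#' @param fpkm FPKM `expr_matrix` covering both sets.
#' @param modules Module map from [detect_modules()] covering both sets.
#' @param min_cor Correlation threshold (inclusive).
#' @return A regulation-call tibble with `mode = "trans"` and `module_id`.
#' @export
call_trans <- function(lnc_ids, coding_ids, fpkm, modules, min_cor = 0.9) {
  if (length(lnc_ids) == 0 || length(coding_ids) == 0) {
    return(mutate(.empty_regulation(), module_id = character(0)))
  }
  miss <- setdiff(c(lnc_ids, coding_ids), modules$gene_id)
  if (length(miss) > 0) {
    abort(paste0("gene(s) without module assignment: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  cm <- .pair_cor(fpkm, lnc_ids, coding_ids)
  mod <- setNames(modules$module_id, modules$gene_id)
  n <- nrow(fpkm$samples)
  idx <- which(!is.na(cm) & cm >= min_cor, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(mutate(.empty_regulation(), module_id = character(0)))
  }
  out <- tibble(lnc_id = rownames(cm)[idx[, 1]],
                target_gene_id = colnames(cm)[idx[, 2]],
                cor = cm[idx]) |>
    mutate(module_lnc = unname(mod[.data$lnc_id]),
           module_gene = unname(mod[.data$target_gene_id])) |>
    filter(.data$module_lnc == .data$module_gene,
           .data$module_lnc != "M0") |>
    mutate(mode = "trans", distance = NA_integer_,
           p_value = .cor_p(.data$cor, n)) |>
    select("lnc_id", "target_gene_id", "mode", "distance", "cor",
           "p_value", module_id = "module_lnc")
  out
}

#' Chi-squared term enrichment of a target set
#'
#' For every term, a 2x2 table of target/background membership against
#' with/without the term, chi-squared with one degree of freedom (no
#' continuity correction), two-sided p. Raw p-values by default (a
#' Benjamini-Hochberg column is added when `adjust = TRUE`); terms sorted
#' by p.
#'
#' @param target_set Gene ids (must be a subset of `background`).
#' @param background Background gene ids.
#' @param term_map Tibble `gene_id`, `term`.
#' @param adjust Add a BH-adjusted p column.
#' @return A tibble `term`, `n_target`, `n_background`, `chi2`, `p_value`
#'   (and `p_adj`), sorted by `p_value`.
#' @export
enrich_terms <- function(target_set, background, term_map, adjust = FALSE) {
  if (!all(target_set %in% background)) {
    abort("target_set must be a subset of background")
  }
  if (length(target_set) == 0) {
    out <- tibble(term = character(), n_target = integer(),
                  n_background = integer(), chi2 = double(),
                  p_value = double())
    return(if (adjust) mutate(out, p_adj = double()) else out)
  }
  n_terms_in <- dplyr::n_distinct(term_map$term)
  tm <- term_map |>
    filter(.data$gene_id %in% background) |>
    distinct(.data$gene_id, .data$term)
  if (dplyr::n_distinct(tm$term) < n_terms_in) {
    warn("term(s) with no background gene skipped")
  }
  n_t <- length(unique(target_set))
  n_b <- length(unique(background))
  stats <- tm |>
    group_by(.data$term) |>
    summarise(a = sum(.data$gene_id %in% target_set),
              with_term = dplyr::n_distinct(.data$gene_id),
              .groups = "drop") |>
    mutate(b = n_t - .data$a,
           c = .data$with_term - .data$a,
           d = n_b - n_t - .data$c) |>
    mutate(across(c("a", "b", "c", "d"), as.numeric))
  chi2 <- with(stats, {
    nn <- a + b + c + d
    num <- nn * (a * d - b * c)^2
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    if_else(den > 0, num / den, 0)
  })
  stats |>
    mutate(chi2 = chi2,
           p_value = pchisq(chi2, df = 1, lower.tail = FALSE)) |>
    select("term", n_target = "a", n_background = "with_term",
           "chi2", "p_value") |>
    (\(d) if (adjust) mutate(d, p_adj = p.adjust(.data$p_value, "BH")) else d)() |>
    arrange(.data$p_value, .data$term)
}

#' Adjusted Rand index of two labelings
#'
#' Agreement between two partitions of the same items, corrected for chance;
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' recovered co-expression modules against planted block structure.
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nn <- comb2(sum(tab))
  expected <- si * sj / nn
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
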