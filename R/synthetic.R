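# Synthetic inputs with planted ground truth.
#
# The generator emulates the study design the pipeline is built for: a
# developmental series of retinas (two replicates per stage), a 15-tissue
# body panel, three overlapping transcript-model sources, stranded read
# counts for unstranded long reads, and NB-distributed knockout contrasts.
# Every generator is a pure function of its parameters and seed.

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# exon starts/ends from a position and alternating exon/intron lengths
.lay_exons <- function(start, ex_len, int_len) {
  n <- length(ex_len)
  starts <- integer(n); ends <- integer(n)
  pos <- start
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + ex_len[i] - 1L
    pos <- ends[i] + (if (i < n) int_len[i] else 0L) + 1L
  }
  list(start = starts, end = ends)
}

#' Generate a toy genome with planted lncRNA loci of every positional class
#'
#' Lays out `n_coding` multi-exon protein-coding genes on one chromosome and
#' plants `n_lnc_per_class` lncRNA loci per positional class so that each
#' satisfies exactly one class definition: antisense and intronic lncRNAs sit
#' inside a host gene's intron (opposite / same strand), divergent and
#' convergent lncRNAs sit 100-900 bp from a flanking gene (opposite / same
#' strand), and intergenic lncRNAs sit more than 1 kb from every coding gene.
#' Each lncRNA locus is distributed over a random non-empty subset of the
#' three sources; long-read copies get slightly extended terminal exons and
#' are mostly emitted strand-unknown. A handful of decoy transcripts exercise
#' every branch of the identification filter cascade.
#'
#' @param n_coding Number of coding genes (3-5 exons each).
#' @param n_lnc_per_class Planted lncRNA loci per positional class.
#' @param chrom_length Chromosome length in bp; generation errors out if the
#'   layout does not fit.
#' @param seed Integer seed; the same seed reproduces byte-identical files.
#' @param p_source Per-source inclusion probabilities (named: annotation,
#'   short_read, long_read); empty draws are re-forced to one source.
#' @param p_unknown_strand Probability a long-read copy is emitted unstranded.
#' @param p_novel_isoform Probability an annotation-backed 3-exon locus gains
#'   a short-read-only isoform with a shifted internal splice site.
#' @param lr_extension Terminal-exon extension of long-read copies (bp).
#' @param with_decoys Emit the four filter-cascade decoys.
#' @param chrom Chromosome name.
#' @param dir If non-NULL, write `annotation.gtf`, `short_read.gtf`,
#'   `long_read.gtf`, `coding_potential.tsv` and `truth.json` there.
#' @return An `lnc_truth` list: `$annotation`, `$short_read`, `$long_read`
#'   (exon tibbles), `$coding_exons`, `$coding_genes`, `$lnc_loci` (planted
#'   loci with true class, nearest gene and distance), `$transcripts` (per
#'   emitted transcript: true strand, whether emitted unstranded, novelty),
#'   `$decoys`, `$coding_potential`, `$params`.
#' @export
make_toy_genome <- function(n_coding = 20, n_lnc_per_class = 5,
                            chrom_length = 1e6, seed = 1,
                            p_source = c(annotation = 0.6, short_read = 0.7,
                                         long_read = 0.6),
                            p_unknown_strand = 0.7, p_novel_isoform = 0.3,
                            lr_extension = 50L, with_decoys = TRUE,
                            chrom = "chrToy", dir = NULL) {
  stopifnot(n_coding >= 1, n_lnc_per_class >= 0)
  n_dec <- if (with_decoys) 4L else 0L
  if (2 * n_lnc_per_class > n_coding) {
    abort("not enough coding genes to host antisense+intronic lncRNAs")
  }
  if (3 * n_lnc_per_class + n_dec - 1L > n_coding + 1) {
    abort("not enough intergenic gaps for the requested lncRNA loci")
  }
  .with_seed(seed, {
    # ---- coding gene layout ----
    n_ex <- sample(3:5, n_coding, replace = TRUE)
    gaps <- sample(8000:15000, n_coding + 1, replace = TRUE)
    genes <- vector("list", n_coding)
    pos <- gaps[1]
    for (i in seq_len(n_coding)) {
      ex_len <- sample(150:400, n_ex[i], replace = TRUE)
      int_len <- sample(2500:4000, n_ex[i] - 1, replace = TRUE)
      lay <- .lay_exons(pos, ex_len, int_len)
      genes[[i]] <- list(id = sprintf("CG%03d", i),
                         strand = sample(c("+", "-"), 1),
                         start = lay$start, end = lay$end)
      pos <- max(lay$end) + gaps[i + 1] + 1L
    }
    if (pos + 100 > chrom_length) {
      abort(sprintf("chrom_length %d too small: layout needs %d bp",
                    as.integer(chrom_length), pos + 100L))
    }
    gene_start <- map_int(genes, ~ min(.x$start))
    gene_end <- map_int(genes, ~ max(.x$end))
    gene_strand <- map_chr(genes, "strand")
    gene_id <- map_chr(genes, "id")
    coding_exons <- purrr::map_dfr(genes, function(g) {
      tibble(transcript_id = paste0(g$id, ".t1"), gene_id = g$id,
             chrom = chrom, start = g$start, end = g$end,
             strand = g$strand, source = "annotation", biotype = "coding")
    })
    coding_genes <- tibble(gene_id = gene_id, chrom = chrom,
                           start = gene_start, end = gene_end,
                           strand = gene_strand)

    # ---- lncRNA structures ----
    opp <- function(s) if_else(s == "+", "-", "+")
    draw_struct <- function() {
      k <- sample(2:3, 1)
      list(ex = sample(120:200, k, replace = TRUE),
           int = sample(200:400, max(k - 1, 0), replace = TRUE))
    }
    classes <- rep(.CLASSES, each = n_lnc_per_class)
    n_lnc <- length(classes)
    hosts <- sample(n_coding)            # genes hosting antisense/intronic
    free_gaps <- sample(n_coding + 1)    # gaps hosting the distance classes
    lnc <- vector("list", n_lnc)
    hi <- 0L; gi <- 0L
    for (j in seq_len(n_lnc)) {
      cls <- classes[j]
      st <- draw_struct()
      span <- sum(st$ex) + sum(st$int)
      if (cls %in% c("antisense", "intronic")) {
        hi <- hi + 1L
        g <- genes[[hosts[hi]]]
        ints <- tibble(s = head(g$end, -1) + 1L, e = tail(g$start, -1) - 1L)
        ints <- filter(ints, .data$e - .data$s + 1L >=
                         span + 2L * (100L + lr_extension))
        pick <- ints[sample(nrow(ints), 1), ]
        off <- sample(100:(pick$e - pick$s + 1L - span - 100L -
                             2L * lr_extension), 1)
        start <- pick$s + lr_extension + off
        strand <- if (cls == "antisense") opp(g$strand) else g$strand
        host <- g$id; dist <- 0L
      } else {
        gi <- gi + 1L
        gp <- free_gaps[gi]
        left_end <- if (gp == 1) 0L else gene_end[gp - 1]
        right_start <- if (gp > n_coding) chrom_length else gene_start[gp]
        if (cls == "intergenic") {
          start <- left_end + max(1101L + lr_extension,
                                  (right_start - left_end - span) %/% 2L)
          strand <- sample(c("+", "-"), 1)
          dl <- start - lr_extension - left_end
          dr <- right_start - (start + span - 1L + lr_extension)
          if (gp == 1) { host <- gene_id[gp]; dist <- dr }
          else if (gp > n_coding) { host <- gene_id[gp - 1]; dist <- dl }
          else if (dl <= dr) { host <- gene_id[gp - 1]; dist <- dl }
          else { host <- gene_id[gp]; dist <- dr }
        } else {
          anchor_right <- gp <= n_coding  # anchor on the right-hand gene
          d <- sample(100:900, 1)
          if (anchor_right) {
            start <- gene_start[gp] - d - span
            host <- gene_id[gp]
          } else {
            start <- gene_end[gp - 1] + d + 1L
            host <- gene_id[gp - 1]
          }
          hs <- gene_strand[match(host, gene_id)]
          strand <- if (cls == "divergent") opp(hs) else hs
          dist <- d
        }
      }
      lay <- .lay_exons(as.integer(start), st$ex, st$int)
      lnc[[j]] <- list(id = sprintf("LNC%03d", j), class = cls,
                       strand = strand, start = lay$start, end = lay$end,
                       nearest = host, distance = as.integer(dist))
    }

    # ---- distribute loci over sources ----
    src_names <- .SOURCES
    tx_rows <- list(); truth_tx <- list()
    for (j in seq_len(n_lnc)) {
      l <- lnc[[j]]
      inc <- runif(3) < p_source[src_names]
      if (!any(inc)) inc[sample(3, 1)] <- TRUE
      base <- tibble(gene_id = l$id, chrom = chrom, start = l$start,
                     end = l$end, strand = l$strand, biotype = "lncRNA")
      for (s in src_names[inc]) {
        ex <- base
        unknown <- FALSE
        if (s == "long_read") {
          ex$start[1] <- ex$start[1] - lr_extension
          ex$end[nrow(ex)] <- ex$end[nrow(ex)] + lr_extension
          unknown <- runif(1) < p_unknown_strand
        }
        tid <- paste0(l$id, ".", c(annotation = "ann", short_read = "sr",
                                   long_read = "lr")[[s]])
        ex <- mutate(ex, transcript_id = tid, source = s,
                     strand = if (unknown) "*" else l$strand)
        tx_rows[[length(tx_rows) + 1L]] <- ex
        truth_tx[[length(truth_tx) + 1L]] <- tibble(
          transcript_id = tid, lnc_id = l$id, source = s,
          true_strand = l$strand, emitted_unstranded = unknown, novel = FALSE)
      }
      if (inc[1] && length(l$start) == 3 && runif(1) < p_novel_isoform) {
        ex <- base
        ex$start[2] <- ex$start[2] + 30L  # shifted acceptor => new chain
        tid <- paste0(l$id, ".sr2")
        ex <- mutate(ex, transcript_id = tid, source = "short_read")
        tx_rows[[length(tx_rows) + 1L]] <- ex
        truth_tx[[length(truth_tx) + 1L]] <- tibble(
          transcript_id = tid, lnc_id = l$id, source = "short_read",
          true_strand = l$strand, emitted_unstranded = FALSE, novel = TRUE)
      }
    }
    lnc_exons <- bind_rows(tx_rows)
    truth_tx <- bind_rows(truth_tx)

    # ---- decoys exercising each filter ----
    decoys <- tibble(transcript_id = character(), source = character(),
                     reason = character())
    decoy_exons <- list()
    if (with_decoys) {
      dg <- free_gaps[gi + seq_len(3)]  # three unused gaps
      mid <- function(gp, span) {
        left_end <- if (gp == 1) 0L else gene_end[gp - 1]
        right_start <- if (gp > n_coding) chrom_length else gene_start[gp]
        as.integer(left_end + (right_start - left_end - span) %/% 2L)
      }
      mk <- function(tid, gp, ex_len, int_len, strand = "+") {
        span <- sum(ex_len) + sum(int_len)
        lay <- .lay_exons(mid(gp, span), ex_len, int_len)
        tibble(transcript_id = tid, gene_id = tid, chrom = chrom,
               start = lay$start, end = lay$end, strand = strand,
               source = "short_read", biotype = "unknown")
      }
      decoy_exons <- list(
        mk("DECOY_short.sr", dg[1], c(80L, 80L), 150L),
        mk("DECOY_se.sr", dg[2], 500L, integer(0)),
        mk("DECOY_coding.sr", dg[3], c(150L, 150L), 300L)
      )
      g <- genes[[sample(n_coding, 1)]]
      decoy_exons[[4]] <- tibble(
        transcript_id = "DECOY_intron.lr", gene_id = "DECOY_intron.lr",
        chrom = chrom, start = c(g$end[1] - 99L, g$start[2]),
        end = c(g$end[1], g$start[2] + 99L), strand = g$strand,
        source = "long_read", biotype = "unknown")
      decoys <- tibble(
        transcript_id = c("DECOY_short.sr", "DECOY_se.sr", "DECOY_coding.sr",
                          "DECOY_intron.lr"),
        source = c("short_read", "short_read", "short_read", "long_read"),
        reason = c("below_min_length", "single_exon", "coding_potential",
                   "shares_coding_intron"))
    }
    all_exons <- bind_rows(lnc_exons, bind_rows(decoy_exons))

    cp <- all_exons |>
      filter(.data$source == "short_read") |>
      distinct(.data$transcript_id) |>
      mutate(label = if_else(.data$transcript_id == "DECOY_coding.sr",
                             "coding", "noncoding"))

    lnc_loci <- purrr::map_dfr(lnc, function(l) {
      tibble(lnc_id = l$id, positional_class = l$class, chrom = chrom,
             start = min(l$start), end = max(l$end), strand = l$strand,
             nearest_gene = l$nearest, distance = l$distance)
    }) |>
      left_join(truth_tx |> group_by(.data$lnc_id) |>
                  summarise(sources = paste(sort(unique(.data$source)),
                                            collapse = ","), .groups = "drop"),
                by = "lnc_id")

    truth <- structure(list(
      annotation = transcript_models(bind_rows(
        coding_exons, filter(all_exons, .data$source == "annotation"))),
      short_read = transcript_models(filter(all_exons, .data$source == "short_read")),
      long_read = transcript_models(filter(all_exons, .data$source == "long_read")),
      coding_exons = transcript_models(coding_exons),
      coding_genes = coding_genes,
      lnc_loci = lnc_loci,
      transcripts = truth_tx,
      decoys = decoys,
      coding_potential = cp,
      params = list(n_coding = n_coding, n_lnc_per_class = n_lnc_per_class,
                    chrom_length = chrom_length, seed = seed, chrom = chrom,
                    p_unknown_strand = p_unknown_strand,
                    p_novel_isoform = p_novel_isoform,
                    lr_extension = lr_extension, with_decoys = with_decoys)
    ), class = "lnc_truth")
    if (!is.null(dir)) write_toy_genome(truth, dir)
    truth
  })
}

#' @export
print.lnc_truth <- function(x, ...) {
  cat(sprintf("<lnc_truth> %d coding genes, %d planted lncRNA loci (%s)\n",
              nrow(x$coding_genes), nrow(x$lnc_loci),
              paste(names(table(x$lnc_loci$positional_class)),
                    table(x$lnc_loci$positional_class),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Write a toy genome's input files
#'
#' @param truth An `lnc_truth` from [make_toy_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_toy_genome <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gtf(truth$annotation, file.path(dir, "annotation.gtf"))
  write_gtf(truth$short_read, file.path(dir, "short_read.gtf"))
  write_gtf(truth$long_read, file.path(dir, "long_read.gtf"))
  readr::write_tsv(truth$coding_potential,
                   file.path(dir, "coding_potential.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(lnc_loci = truth$lnc_loci, transcripts = truth$transcripts,
         coding_genes = truth$coding_genes, decoys = truth$decoys,
         params = truth$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate stranded read counts for long-read transcripts
#'
#' For every long-read transcript, the total read count is Poisson with mean
#' `depth` and the plus-strand count binomial with success probability `bias`
#' toward the transcript's true strand, mimicking stranded short reads
#' aligned back to unstranded full-length transcripts.
#'
#' @param truth An `lnc_truth`.
#' @param depth Expected reads per transcript.
#' @param bias Probability a read maps to the true strand, in [0.5, 1].
#' @param seed Integer seed.
#' @return A tibble `transcript_id`, `plus_reads`, `minus_reads` with the true
#'   strand attached as column `true_strand` (drop before use if undesired).
#' @export
make_stranded_counts <- function(truth, depth = 200, bias = 0.9, seed = 1) {
  if (bias < 0.5 || bias > 1) abort("bias must lie in [0.5, 1]")
  lr <- bind_rows(
    truth$transcripts |> filter(.data$source == "long_read") |>
      select("transcript_id", "true_strand"),
    truth$decoys |> filter(.data$source == "long_read") |>
      mutate(true_strand = "+") |> select("transcript_id", "true_strand")
  )
  .with_seed(seed, {
    total <- rpois(nrow(lr), depth)
    p_plus <- if_else(lr$true_strand == "+", bias, 1 - bias)
    plus <- rbinom(nrow(lr), total, p_plus)
    tibble(transcript_id = lr$transcript_id, plus_reads = plus,
           minus_reads = total - plus, true_strand = lr$true_strand)
  })
}

.STAGE_LABELS <- c("E12.5", "E14.5", "E15.5", "E17.5", "P0",
                   "P1", "P3", "P7", "P14", "P28")
.TISSUE_LABELS <- c("liver", "stomach", "large_intestine", "small_intestine",
                    "colon", "kidney", "thymus", "adrenal", "mammary",
                    "testis", "ovary", "cerebrum", "lung", "heart", "spleen")

#' Simulate staged and tissue expression with planted structure
#'
#' Builds an FPKM matrix over developmental stages (with replicates) for all
#' planted lncRNA loci and coding genes, plus a one-column-per-tissue body
#' panel. Baseline stage profiles are log-normal; planted stage-specific
#' genes are expressed in exactly one stage (true tau = 1), planted
#' constitutive genes are flat (true tau = 0), planted cis pairs (a lncRNA
#' and its nearest coding gene) follow a shared latent stage profile whose
#' population correlation exceeds 0.95 at the default noise level, planted
#' trans modules are hub-shaped (one lncRNA plus its distant coding targets,
#' all on one latent profile, module latents mutually orthogonal), and
#' planted retina-specific genes are near zero in every non-retina tissue.
#'
#' @param truth An `lnc_truth`.
#' @param n_stages Number of stages (10 gives the E12.5-P28 labels).
#' @param n_reps Replicates per stage.
#' @param n_tissues Number of non-retina tissues (15 mirrors the body panel).
#' @param noise_sd Replicate noise, sd of a multiplicative log-normal factor.
#' @param p_specific,p_constitutive Fractions of free lncRNA loci planted as
#'   stage-specific / constitutive.
#' @param n_cis,n_trans Planted cis / trans pair counts (default: a fifth of
#'   the lncRNA loci each, capped by availability).
#' @param n_modules Number of trans hub modules (default: one per ~5 pairs;
#'   each module is one hub lncRNA plus its share of the coding targets).
#' @param p_retina_specific Fraction of lncRNA genes silent outside retina.
#' @param profile_sd Stage-to-stage sd of latent log2 profiles.
#' @param seed Integer seed.
#' @return An `lnc_expression` list: `$stages`, `$tissues` (both
#'   `expr_matrix` FPKM) and `$truth` (planted gene sets and pairs).
#' @export
make_expression <- function(truth, n_stages = 10, n_reps = 2, n_tissues = 15,
                            noise_sd = 0.2, p_specific = 0.08,
                            p_constitutive = 0.2, n_cis = NULL, n_trans = NULL,
                            n_modules = NULL, p_retina_specific = 0.5,
                            profile_sd = 2, seed = 1) {
  stopifnot(n_stages >= 2, n_reps >= 2)
  lnc_ids <- truth$lnc_loci$lnc_id
  cod_ids <- truth$coding_genes$gene_id
  n_lnc <- length(lnc_ids)
  n_cis <- n_cis %||% min(floor(n_lnc / 5), n_lnc)
  n_trans <- n_trans %||% floor(n_lnc / 5)
  n_modules <- n_modules %||% max(1L, ceiling(n_trans / 5))
  if (n_modules > max(n_trans, 1)) abort("more trans modules than trans pairs")
  if (n_cis + n_modules > n_lnc) abort("not enough lncRNA loci for the requested pairs")
  .with_seed(seed, {
    ord <- sample(lnc_ids)
    cis_lnc <- ord[seq_len(n_cis)]
    trans_lnc <- ord[n_cis + seq_len(if (n_trans > 0) n_modules else 0)]
    free <- setdiff(ord, c(cis_lnc, trans_lnc))
    n_spec <- round(p_specific * length(free))
    specific <- head(free, n_spec)
    constitutive <- head(setdiff(free, specific),
                         round(p_constitutive * length(free)))
    cis_partner <- truth$lnc_loci$nearest_gene[match(cis_lnc, truth$lnc_loci$lnc_id)]
    # trans targets are distant coding genes: exclude cis partners and every
    # hub lncRNA's own nearest gene so trans pairs never double as cis pairs
    trans_nearest <- truth$lnc_loci$nearest_gene[match(trans_lnc, truth$lnc_loci$lnc_id)]
    trans_pool <- setdiff(cod_ids, c(cis_partner, trans_nearest))
    if (length(trans_pool) < n_trans) abort("not enough coding genes for trans pairs")
    trans_partner <- sample(trans_pool, n_trans)
    # pairs are distributed over the hub modules as evenly as possible
    trans_module_idx <- if (n_trans > 0) {
      sort(rep_len(seq_len(n_modules), n_trans))
    } else integer(0)
    trans_module <- sprintf("B%02d", trans_module_idx)

    genes <- c(lnc_ids, cod_ids)
    n_genes <- length(genes)
    base <- rnorm(n_genes, 2.5, 0.7)
    names(base) <- genes
    # planted regulatory pairs sit at solidly detectable expression so the
    # log2(FPKM + 1) transform stays near-affine for them
    paired <- unique(c(cis_lnc, cis_partner, trans_lnc, trans_partner))
    base[paired] <- rnorm(length(paired), 3.5, 0.5)
    # latent log2 stage profiles
    prof <- matrix(rnorm(n_genes * n_stages, 0, profile_sd), n_genes,
                   dimnames = list(genes, NULL))
    prof[constitutive, ] <- 0
    # trans modules are hub-shaped: one lncRNA hub plus its coding targets,
    # all sharing one latent stage profile. Module latents come from an
    # orthogonal basis so distinct modules are uncorrelated by construction
    # and never merge by chance in the clustering.
    if (n_trans > 0) {
      qmat <- qr.Q(qr(matrix(rnorm(n_stages * n_stages), n_stages)))
      mod_prof <- apply(qmat[, seq_len(min(n_modules, n_stages)), drop = FALSE],
                        2, function(v) as.numeric(scale(v)) * profile_sd)
      mod_prof <- t(mod_prof[, rep_len(seq_len(ncol(mod_prof)), n_modules),
                             drop = FALSE])
      for (m in seq_len(n_modules)) {
        prof[trans_lnc[m], ] <- mod_prof[m, ]
      }
      for (k in seq_len(n_trans)) {
        prof[trans_partner[k], ] <- mod_prof[trans_module_idx[k], ]
      }
    }
    # one latent profile per unique cis partner; the lncRNA copies its
    # partner's profile, so duplicated partners still correlate with each lnc
    for (g in unique(cis_partner)) {
      prof[g, ] <- rnorm(n_stages, 0, profile_sd)
    }
    for (k in seq_along(cis_lnc)) {
      prof[cis_lnc[k], ] <- prof[cis_partner[k], ]
    }
    mu <- 2^(base + prof)           # noise-free stage-mean FPKM
    peak <- sample.int(n_stages, length(specific), replace = TRUE)
    mu[specific, ] <- 0
    mu[cbind(match(specific, genes), peak)] <- 2^(base[specific] + 2)

    stages <- if (n_stages == 10) .STAGE_LABELS else sprintf("S%02d", 1:n_stages)
    cols <- paste0(rep(stages, each = n_reps), "_r", rep(seq_len(n_reps), n_stages))
    vals <- mu[, rep(seq_len(n_stages), each = n_reps), drop = FALSE] *
      exp(matrix(rnorm(n_genes * n_stages * n_reps, 0, noise_sd),
                 n_genes))
    colnames(vals) <- cols
    stage_em <- expression_matrix(
      bind_cols(tibble(gene_id = genes), as_tibble(vals)),
      tibble(sample = cols, condition = rep(stages, each = n_reps),
             replicate = rep(seq_len(n_reps), n_stages)),
      unit = "FPKM")

    # tissue panel: retina + n_tissues, one column each
    tissues <- if (n_tissues == 15) .TISSUE_LABELS else sprintf("tissue%02d", 1:n_tissues)
    retina_specific <- sample(lnc_ids, round(p_retina_specific * n_lnc))
    tpanel <- matrix(0, n_genes, n_tissues + 1,
                     dimnames = list(genes, c("retina", tissues)))
    tpanel[, "retina"] <- rowMeans(mu) * exp(rnorm(n_genes, 0, noise_sd))
    for (g in seq_len(n_genes)) {
      if (genes[g] %in% retina_specific) {
        tpanel[g, -1] <- runif(n_tissues, 0, 0.3)
      } else {
        on <- runif(n_tissues) < 0.4
        tpanel[g, -1] <- if_else(on, 2^rnorm(n_tissues, 2, 1) + 1,
                                 runif(n_tissues, 0, 0.5))
      }
    }
    tissue_em <- expression_matrix(
      bind_cols(tibble(gene_id = genes), as_tibble(tpanel)),
      tibble(sample = c("retina", tissues),
             condition = c("retina", tissues), replicate = 1L),
      unit = "FPKM")

    structure(list(
      stages = stage_em, tissues = tissue_em,
      truth = list(
        specific = specific, constitutive = constitutive,
        peak_stage = setNames(stages[peak], specific),
        cis_pairs = tibble(lnc_id = cis_lnc, gene_id = cis_partner,
                           distance = truth$lnc_loci$distance[
                             match(cis_lnc, truth$lnc_loci$lnc_id)]),
        trans_pairs = tibble(lnc_id = trans_lnc[trans_module_idx],
                             gene_id = trans_partner,
                             module = trans_module),
        retina_specific = retina_specific)
    ), class = "lnc_expression")
  })
}

#' Simulate mutant-versus-wild-type count matrices
#'
#' Gene-wise negative-binomial counts with log-normal baseline means; a
#' planted subset of genes changes by a true log2 fold change drawn from
#' `lfc_set` in the mutant group, all other genes share means across groups.
#' `dispersion = 0` gives the Poisson limit.
#'
#' @param n_genes Number of genes (ignored if `gene_ids` given).
#' @param n_de Number of planted differential genes.
#' @param lfc_set True log2 fold changes to sample from.
#' @param n_reps Replicates per group.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline means.
#' @param gene_ids Optional gene ids to use as rows.
#' @param seed Integer seed.
#' @return A list `wt`, `mut` (count `expr_matrix`) and `truth` tibble
#'   (`gene_id`, `lfc`, `is_de`).
#' @export
make_mutant_counts <- function(n_genes = 2000, n_de = 100,
                               lfc_set = c(-2, -1.5, 1.5, 2), n_reps = 3,
                               dispersion = 0.05, base_meanlog = log(100),
                               base_sdlog = 1, gene_ids = NULL, seed = 1) {
  stopifnot(n_reps >= 1, dispersion >= 0)
  if (!is.null(gene_ids)) n_genes <- length(gene_ids)
  if (n_de > n_genes) abort("n_de exceeds n_genes")
  .with_seed(seed, {
    ids <- gene_ids %||% sprintf("G%05d", seq_len(n_genes))
    mu_wt <- exp(rnorm(n_genes, base_meanlog, base_sdlog))
    lfc <- rep(0, n_genes)
    de_idx <- sample.int(n_genes, n_de)
    if (n_de > 0) lfc[de_idx] <- sample(lfc_set, n_de, replace = TRUE)
    mu_mut <- mu_wt * 2^lfc
    draw <- function(mu) {
      m <- matrix(rep(mu, n_reps), ncol = n_reps)
      if (dispersion == 0) {
        matrix(rpois(length(m), m), ncol = n_reps)
      } else {
        matrix(rnbinom(length(m), mu = m, size = 1 / dispersion), ncol = n_reps)
      }
    }
    wt <- draw(mu_wt); mut <- draw(mu_mut)
    em <- function(m, cond) {
      cols <- paste0(cond, "_r", seq_len(n_reps))
      colnames(m) <- cols
      expression_matrix(bind_cols(tibble(gene_id = ids), as_tibble(m)),
                        tibble(sample = cols, condition = cond,
                               replicate = seq_len(n_reps)), unit = "count")
    }
    list(wt = em(wt, "WT"), mut = em(mut, "MUT"),
         truth = tibble(gene_id = ids, lfc = lfc, is_de = lfc != 0))
  })
}
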