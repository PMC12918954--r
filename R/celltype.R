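#' Generate synthetic single-cell and bulk expression matrices
#'
#' Emulates, at configurable scale, the comparison of a bulk RNA-seq
#' profile of cultured satellite glia against a single-cell atlas
#' aggregated by major cell class. Counts are negative-binomial around
#' log-normal gene means; each class has a set of planted marker genes
#' elevated by `marker_log2fc` in their home class and suppressed by the
#' same factor elsewhere (cell-type markers are near-absent outside their
#' class); the bulk sample is drawn from a chosen source class mixed with
#' a configurable contamination fraction from a second class (cultures
#' often carry fibroblast/mural material).
#'
#' @param n_genes Number of genes.
#' @param classes Character vector of cell classes; defaults to the seven
#'   major DRG classes.
#' @param cells_per_class Cells simulated per class.
#' @param markers_per_class Planted marker genes per class.
#' @param marker_log2fc Marker elevation (log2).
#' @param dispersion NB size parameter (smaller = noisier).
#' @param n_bulk Number of bulk replicates.
#' @param bulk_source Class the bulk sample derives from.
#' @param contamination Fraction of the bulk mean drawn from
#'   `contaminant_class`.
#' @param contaminant_class Class contaminating the bulk sample.
#' @param bulk_depth_factor Bulk sequencing-depth multiplier relative to a
#'   single cell.
#' @param seed Integer seed; bit-reproducible.
#' @return List with `sc` (genes x cells integer matrix), `cell_classes`
#'   (per-cell class labels), `bulk` (genes x replicates matrix),
#'   `markers` (named list of marker genes per class), and `classes`.
#' @export
generate_synthetic_expression <- function(n_genes = 2000,
                                          classes = c("glia", "neurons",
                                                      "immune",
                                                      "endothelial",
                                                      "erythrocytes",
                                                      "fibroblasts",
                                                      "mural"),
                                          cells_per_class = 40,
                                          markers_per_class = 25,
                                          marker_log2fc = 3,
                                          dispersion = 2,
                                          n_bulk = 2,
                                          bulk_source = "glia",
                                          contamination = 0.1,
                                          contaminant_class = "fibroblasts",
                                          bulk_depth_factor = 50,
                                          seed = 1L) {
  k <- length(classes)
  if (markers_per_class * k > n_genes) abort("too many markers for n_genes")
  if (!bulk_source %in% classes) abort("bulk_source must be one of classes")
  if (contamination < 0 || contamination >= 1) {
    abort("contamination must be in [0, 1)")
  }
  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    base_mu <- rlnorm(n_genes, meanlog = 1, sdlog = 1.2)
    markers <- list()
    idx <- 0L
    for (cl in classes) {
      markers[[cl]] <- if (markers_per_class > 0) {
        genes[idx + seq_len(markers_per_class)]
      } else character(0)
      idx <- idx + markers_per_class
    }
    all_markers <- unlist(markers, use.names = FALSE)
    class_mu <- sapply(classes, function(cl) {
      mu <- base_mu
      own <- genes %in% markers[[cl]]
      other <- genes %in% setdiff(all_markers, markers[[cl]])
      mu[own] <- mu[own] * 2^marker_log2fc
      mu[other] <- mu[other] * 2^-marker_log2fc
      mu
    })
    rownames(class_mu) <- genes
    cell_classes <- rep(classes, each = cells_per_class)
    sc <- sapply(seq_along(cell_classes), function(i) {
      rnbinom(n_genes, mu = class_mu[, cell_classes[i]], size = dispersion)
    })
    rownames(sc) <- genes
    colnames(sc) <- sprintf("cell%04d", seq_along(cell_classes))
    bulk_mu <- (1 - contamination) * class_mu[, bulk_source] +
      contamination * class_mu[, contaminant_class]
    bulk <- sapply(seq_len(n_bulk), function(i) {
      rnbinom(n_genes, mu = bulk_mu * bulk_depth_factor,
              size = dispersion * 5)
    })
    rownames(bulk) <- genes
    colnames(bulk) <- sprintf("bulk%d", seq_len(n_bulk))
    list(sc = sc, cell_classes = cell_classes, bulk = bulk,
         markers = markers, classes = classes)
  })
}

#' Aggregate single-cell counts into pseudobulk class profiles
#'
#' Sums counts per cell class, normalises each class column to counts per
#' million, and takes log2(CPM + prior).
#'
#' @param sc Genes x cells integer count matrix.
#' @param cell_classes Per-cell class labels (length `ncol(sc)`).
#' @param prior Prior count added before the log (default 0.5).
#' @return A `pseudobulk_profile`: list with `counts`, `cpm`, `logcpm`
#'   (genes x classes matrices).
#' @export
pseudobulk <- function(sc, cell_classes, prior = 0.5) {
  if (length(cell_classes) != ncol(sc)) {
    abort("cell_classes must have one label per cell")
  }
  classes <- unique(cell_classes)
  counts <- sapply(classes, function(cl) {
    rowSums(sc[, cell_classes == cl, drop = FALSE])
  })
  rownames(counts) <- rownames(sc)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    abort(paste("class with zero total counts:",
                paste(classes[tot == 0], collapse = ", ")))
  }
  cpm <- sweep(counts, 2, tot, "/") * 1e6
  structure(list(counts = counts, cpm = cpm,
                 logcpm = log2(cpm + prior), prior = prior),
            class = "pseudobulk_profile")
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalisation factors, computed per the
#' standard definition: the reference sample is the one whose
#' upper-quartile (of library-size-scaled counts) is closest to the mean
#' upper-quartile; for each sample, genes positive in both sample and
#' reference contribute an M-value (log2 expression ratio) and an A-value
#' (average log2 expression); genes in the outer 30 percent of M or the
#' outer 5 percent of A are trimmed, and the factor is 2 to the
#' precision-weighted mean of the remaining M-values. Factors are scaled
#' to geometric mean 1.
#'
#' @param counts Genes x samples count matrix (>= 2 samples).
#' @param logratio_trim,abs_expr_trim Two-sided trim fractions on M and A.
#' @return Numeric vector of factors, one per sample, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_expr_trim = 0.05) {
  if (ncol(counts) < 2L) abort("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) abort("sample with zero counts on all shared genes")
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref_i <- which.min(abs(uq - mean(uq)))
  r <- counts[, ref_i]
  nr <- lib[ref_i]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    n <- lib[j]
    keep <- x > 0 & r > 0
    if (!any(keep)) return(1)
    xs <- x[keep] / n
    rs <- r[keep] / nr
    m <- log2(xs / rs)
    a <- 0.5 * log2(xs * rs)
    # delta-method variance of each M-value; precision-weighted mean
    v <- (n - x[keep]) / (n * x[keep]) + (nr - r[keep]) / (nr * r[keep])
    if (max(abs(m)) < 1e-6) return(1)
    ng <- length(m)
    lo_m <- floor(ng * logratio_trim) + 1
    hi_m <- ng + 1 - lo_m
    lo_a <- floor(ng * abs_expr_trim) + 1
    hi_a <- ng + 1 - lo_a
    rm_ <- rank(m)
    ra_ <- rank(a)
    kept <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(kept)) return(1)
    2^(sum(m[kept] / v[kept]) / sum(1 / v[kept]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Jointly TMM-normalised log-CPM
#'
#' Computes TMM factors on the joined count matrix, forms effective
#' library sizes (library size times factor), and returns log2 counts per
#' million on the effective sizes.
#'
#' @inheritParams tmm_factors
#' @param prior Prior count added to CPM before the log.
#' @return List with `logcpm` (genes x samples), `factors` and
#'   `eff_lib_size`.
#' @export
tmm_log_cpm <- function(counts, prior = 0.5) {
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  list(logcpm = log2(cpm + prior), factors = f, eff_lib_size = eff)
}

row_var <- function(m) {
  if (ncol(m) < 2L) return(setNames(rep(0, nrow(m)), rownames(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Shared highly variable genes across platforms
#'
#' Ranks every shared gene by the variance of its log-CPM within each
#' platform separately (rank 1 = most variable), combines the two ranks by
#' their minimum — a symmetric, deterministic reading of "highly variable
#' in either platform" — and returns the top `n` genes (ties broken by
#' the other platform's rank, then by symbol).
#'
#' @param bulk_logcpm,pseudo_logcpm Genes x samples log-CPM matrices with
#'   rownames.
#' @param n Number of genes to return (clamped to the shared set).
#' @return Character vector of gene names.
#' @export
hvg_shared <- function(bulk_logcpm, pseudo_logcpm, n = 5000) {
  shared <- intersect(rownames(bulk_logcpm), rownames(pseudo_logcpm))
  if (!length(shared)) abort("no shared genes between platforms")
  vb <- row_var(bulk_logcpm[shared, , drop = FALSE])
  vp <- row_var(pseudo_logcpm[shared, , drop = FALSE])
  rb <- rank(-vb, ties.method = "min")
  rp <- rank(-vp, ties.method = "min")
  combined <- pmin(rb, rp)
  ord <- order(combined, pmax(rb, rp), shared)
  shared[ord][seq_len(min(n, length(shared)))]
}

#' Transcriptional similarity of a bulk profile to each cell class
#'
#' Spearman rank correlation (ties mid-ranked) between the bulk log-CPM
#' profile (columns averaged if a matrix) and each pseudobulk class
#' column, over the supplied gene list.
#'
#' @param bulk_logcpm Named numeric vector or genes x samples matrix.
#' @param pseudo_logcpm Genes x classes log-CPM matrix.
#' @param genes Gene list to correlate over (>= 3 genes).
#' @return Tibble (`class`, `spearman`), sorted by decreasing correlation.
#' @export
similarity <- function(bulk_logcpm, pseudo_logcpm, genes) {
  if (length(genes) < 3L) abort("need at least 3 genes")
  if (is.matrix(bulk_logcpm)) {
    bulk_logcpm <- rowMeans(bulk_logcpm)
  }
  miss <- setdiff(genes, intersect(names(bulk_logcpm),
                                   rownames(pseudo_logcpm)))
  if (length(miss)) {
    abort(paste("genes absent from one profile, e.g.", miss[1]))
  }
  b <- bulk_logcpm[genes]
  out <- tibble(
    class = colnames(pseudo_logcpm),
    spearman = apply(pseudo_logcpm[genes, , drop = FALSE], 2,
                     function(col) cor(b, col, method = "spearman"))
  )
  arrange(out, desc(.data$spearman))
}

#' Rank candidate genes by glial expression and specificity
#'
#' For each candidate, reports its expression (CPM) in the designated
#' satellite-glia class, the maximum CPM over all other classes, and the
#' specificity ratio (glia / max-other, with a pseudocount floor
#' `eps` on the denominator). Candidates receive a rank by expression and
#' a rank by specificity; the combined rank is the mean of the two (ties
#' broken by specificity ratio, then symbol).
#'
#' @param candidate_genes Character vector of gene symbols.
#' @param pseudo A [pseudobulk()] profile.
#' @param sgc_class Name of the glial class column (default `"glia"`).
#' @param eps Pseudocount floor on the denominator CPM (default 0.01).
#' @return A `candidate_ranking` tibble (`gene`, `sgc_cpm`,
#'   `max_other_cpm`, `specificity_ratio`, `rank_expression`,
#'   `rank_specificity`, `combined_rank`), sorted by combined rank.
#' @export
specificity_and_rank <- function(candidate_genes, pseudo,
                                 sgc_class = "glia", eps = 0.01) {
  stopifnot(inherits(pseudo, "pseudobulk_profile"))
  cpm <- pseudo$cpm
  if (!sgc_class %in% colnames(cpm)) {
    abort(paste("no", sgc_class, "class in the pseudobulk profile"))
  }
  miss <- setdiff(candidate_genes, rownames(cpm))
  if (length(miss)) {
    abort(paste("candidates absent from profile, e.g.", miss[1]))
  }
  sgc <- cpm[candidate_genes, sgc_class]
  other <- cpm[candidate_genes, setdiff(colnames(cpm), sgc_class),
               drop = FALSE]
  max_other <- apply(other, 1, max)
  ratio <- sgc / pmax(max_other, eps)
  perm_rank <- function(value, tiebreak) {
    ord <- order(-value, -tiebreak, candidate_genes)
    rk <- integer(length(value))
    rk[ord] <- seq_along(value)
    rk
  }
  r_expr <- perm_rank(sgc, ratio)
  r_spec <- perm_rank(ratio, sgc)
  combined <- (r_expr + r_spec) / 2
  out <- tibble(gene = candidate_genes, sgc_cpm = unname(sgc),
                max_other_cpm = unname(max_other),
                specificity_ratio = unname(ratio),
                rank_expression = r_expr, rank_specificity = r_spec,
                combined_rank = combined) %>%
    arrange(.data$combined_rank, desc(.data$specificity_ratio), .data$gene)
  class(out) <- c("candidate_ranking", class(out))
  out
}

#' @export
tidy.candidate_ranking <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.candidate_ranking <- function(x, ...) {
  tibble(n_candidates = nrow(x), top_gene = x$gene[1],
         top_specificity = x$specificity_ratio[1])
}

#' Relative expression and fold change by the delta-CT method
#'
#' Per gene and sample, computes delta-CT as the gene's Ct minus the
#' housekeeping gene's Ct in the same sample, and the relative expression
#' 2^(-delta-CT). When a `condition` column is present with two levels,
#' also returns the per-gene fold change: the ratio of condition-mean
#' relative expression (second level over reference).
#'
#' @param ct Tibble with columns `gene`, `sample`, `ct` and optionally
#'   `condition`.
#' @param housekeeping_gene Normalisation-control gene symbol (must have a
#'   Ct in every sample).
#' @param reference Reference condition for fold changes; defaults to the
#'   first level encountered.
#' @return List with `relative` (tibble `gene`, `sample`, `rel_expr`) and,
#'   if conditions are present, `fold_change` (tibble `gene`,
#'   `fold_change`).
#' @export
dct_fold_change <- function(ct, housekeeping_gene, reference = NULL) {
  need <- c("gene", "sample", "ct")
  if (!all(need %in% names(ct))) {
    abort("ct table needs columns gene, sample, ct")
  }
  hk <- ct %>% filter(.data$gene == housekeeping_gene) %>%
    select("sample", hk_ct = "ct")
  all_samples <- unique(ct$sample)
  if (!all(all_samples %in% hk$sample)) {
    abort(paste("housekeeping Ct missing for sample(s):",
                paste(setdiff(all_samples, hk$sample), collapse = ", ")))
  }
  rel <- ct %>%
    filter(.data$gene != housekeeping_gene) %>%
    left_join(hk, by = "sample") %>%
    mutate(rel_expr = 2^(-(.data$ct - .data$hk_ct)))
  out <- list(relative = select(rel, dplyr::any_of(c("gene", "sample",
                                                     "condition",
                                                     "rel_expr"))))
  if ("condition" %in% names(ct)) {
    conds <- unique(rel$condition)
    if (length(conds) == 2L) {
      if (is.null(reference)) reference <- conds[1]
      treated <- setdiff(conds, reference)
      out$fold_change <- rel %>%
        group_by(.data$gene) %>%
        summarise(
          fold_change = mean(.data$rel_expr[.data$condition == treated]) /
            mean(.data$rel_expr[.data$condition == reference]),
          .groups = "drop")
    }
  }
  out
}
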