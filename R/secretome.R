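#' Secretome filtering thresholds
#'
#' Encodes the stringent secreted-protein criteria: a per-protein p-value
#' cutoff, a minimum conditioned-media vs media-control fold change, and a
#' two-part "minimal signal in negative controls" rule (a cap on the
#' number of media-control replicates with any detected signal, and a cap
#' on the control/CM mean-intensity ratio).
#'
#' @param p_max Welch-test p-value cutoff (default 0.05).
#' @param fc_min Minimum fold change; the comparison is inclusive
#'   (`fc >= fc_min`), so a protein sitting exactly at a 2-fold change
#'   passes the default filter.
#' @param control_max_fraction Maximum allowed control/CM mean intensity
#'   ratio (default 0.1).
#' @param control_detect_max Maximum number of media-control replicates
#'   with nonzero intensity (default 0).
#' @return A `secretome_filters` list.
#' @export
secretome_filters <- function(p_max = 0.05, fc_min = 2,
                              control_max_fraction = 0.1,
                              control_detect_max = 0L) {
  if (p_max <= 0 || p_max >= 1) abort("p_max must be in (0, 1)")
  if (fc_min <= 1) abort("fc_min must exceed 1")
  structure(list(p_max = p_max, fc_min = fc_min,
                 control_max_fraction = control_max_fraction,
                 control_detect_max = as.integer(control_detect_max)),
            class = "secretome_filters")
}

#' Generate a synthetic conditioned-media proteomics table
#'
#' Emulates the structure of a mass-spectrometry protein quantification
#' experiment comparing glial conditioned media (CM), the producing-cell
#' pellet, and a culture-media-only negative control. Intensities are
#' log-normal; a designated subset of proteins is genuinely secreted:
#' elevated in CM by `effect_log2fc` relative to its media-control
#' baseline, and detected in the control only with probability
#' `control_detect_rate` (at the unshifted baseline). Non-secreted
#' proteins appear at comparable intensity in CM and control
#' (media-derived material), and everything is present in the pellet.
#' Truth labels are returned for recovery testing.
#'
#' Defaults mirror the scale of a typical SGC conditioned-media screen:
#' 740 identified proteins of which 73 are genuinely secreted, three
#' replicates per group.
#'
#' @param n_proteins Total number of proteins.
#' @param n_secreted Number of genuinely secreted proteins.
#' @param n_replicates Replicates per group.
#' @param effect_log2fc CM enrichment of secreted proteins (log2).
#' @param noise_sd_log Replicate noise SD on the log2 scale.
#' @param control_detect_rate Probability that a secreted protein shows
#'   residual signal in a given media-control replicate (0 = fully absent).
#' @param base_mean_log2,base_sd_log2 Distribution of protein baseline
#'   abundances (log2 intensity units).
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A list with `quant` (long tibble: `protein`, `gene`, `group`,
#'   `replicate`, `intensity`) and `truth` (tibble: `protein`, `gene`,
#'   `secreted`).
#' @export
generate_synthetic_secretome <- function(n_proteins = 740,
                                         n_secreted = 73,
                                         n_replicates = 3,
                                         effect_log2fc = 3,
                                         noise_sd_log = 0.5,
                                         control_detect_rate = 0,
                                         base_mean_log2 = 20,
                                         base_sd_log2 = 2,
                                         seed = 1L) {
  if (n_secreted > n_proteins || n_proteins < 1 || n_replicates < 2) {
    abort("invalid sizes: need n_secreted <= n_proteins, n_replicates >= 2")
  }
  withr::with_seed(seed, {
    protein <- sprintf("P%04d", seq_len(n_proteins))
    gene <- sprintf("Gene%04d", seq_len(n_proteins))
    secreted <- c(rep(TRUE, n_secreted), rep(FALSE, n_proteins - n_secreted))
    base <- rnorm(n_proteins, base_mean_log2, base_sd_log2)
    groups <- c("CM", "pellet", "media_control")
    quant <- purrr::map_dfr(groups, function(g) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        mu <- base +
          ifelse(g == "CM" & secreted, effect_log2fc, 0)
        x <- 2^(mu + rnorm(n_proteins, 0, noise_sd_log))
        if (g == "media_control") {
          drop <- secreted & (runif(n_proteins) > control_detect_rate)
          x[drop] <- 0
        }
        tibble(protein = protein, gene = gene, group = g, replicate = r,
               intensity = x)
      })
    })
    list(quant = quant,
         truth = tibble(protein = protein, gene = gene, secreted = secreted))
  })
}

check_groups <- function(quant, needed) {
  miss <- setdiff(needed, unique(quant$group))
  if (length(miss)) {
    abort(paste("missing group(s):", paste(miss, collapse = ", ")))
  }
}

#' Proteins specific to the conditioned media
#'
#' Returns proteins detected (intensity > 0) in at least one CM replicate
#' and in at most `control_detect_max` media-control replicates — the
#' "present specifically in the CM and absent in culture media" set.
#'
#' @param quant Long protein table (`protein`, `group`, `replicate`,
#'   `intensity`).
#' @param control_detect_max Maximum number of control replicates with
#'   nonzero signal.
#' @return Character vector of protein ids.
#' @export
cm_specific_proteins <- function(quant, control_detect_max = 0L) {
  check_groups(quant, c("CM", "media_control"))
  quant %>%
    filter(.data$group %in% c("CM", "media_control")) %>%
    group_by(.data$protein) %>%
    summarise(cm_det = sum(.data$intensity[.data$group == "CM"] > 0),
              ctl_det = sum(.data$intensity[.data$group == "media_control"] > 0),
              .groups = "drop") %>%
    filter(.data$cm_det >= 1L, .data$ctl_det <= control_detect_max) %>%
    pull("protein")
}

welch_log2_p <- function(x, y) {
  lx <- log2(x + 1)
  ly <- log2(y + 1)
  if (sd(lx) == 0 && sd(ly) == 0) {
    # degenerate: no variance in either group -> no evidence
    return(if (isTRUE(all.equal(mean(lx), mean(ly)))) 1 else 0)
  }
  tryCatch(t.test(lx, ly)$p.value, error = function(e) 1)
}

#' High-confidence secreted-protein candidates
#'
#' Applies the stringent secretome criteria per protein: a Welch
#' two-sample test on log2(intensity + 1) between CM and media-control
#' replicates, the fold change of raw group means (pseudo-count 1), and
#' the negative-control signal rules. A protein passes when
#' `p < p_max`, `fc >= fc_min`, at most `control_detect_max` control
#' replicates show signal, and the control/CM mean ratio is below
#' `control_max_fraction`.
#'
#' @inheritParams cm_specific_proteins
#' @param filters A [secretome_filters()] object.
#' @return Tibble (`protein`, `gene`, `mean_cm`, `mean_control`, `log2fc`,
#'   `p`, `pass`), one row per protein, sorted by p.
#' @export
high_confidence_candidates <- function(quant, filters = secretome_filters()) {
  check_groups(quant, c("CM", "media_control"))
  reps <- quant %>%
    filter(.data$group %in% c("CM", "media_control")) %>%
    dplyr::count(.data$group, .data$replicate)
  for (g in c("CM", "media_control")) {
    if (sum(reps$group == g) < 2L) {
      abort(paste("need >= 2 replicates in group", g))
    }
  }
  has_gene <- "gene" %in% names(quant)
  out <- quant %>%
    filter(.data$group %in% c("CM", "media_control")) %>%
    group_by(.data$protein) %>%
    summarise(
      gene = if (has_gene) .data$gene[1] else NA_character_,
      mean_cm = mean(.data$intensity[.data$group == "CM"]),
      mean_control = mean(.data$intensity[.data$group == "media_control"]),
      ctl_det = sum(.data$intensity[.data$group == "media_control"] > 0),
      p = welch_log2_p(.data$intensity[.data$group == "CM"],
                       .data$intensity[.data$group == "media_control"]),
      .groups = "drop") %>%
    mutate(
      fc = (.data$mean_cm + 1) / (.data$mean_control + 1),
      log2fc = log2(.data$fc),
      ctl_fraction = .data$mean_control / pmax(.data$mean_cm, .Machine$double.eps),
      pass = .data$p < filters$p_max &
        .data$fc >= filters$fc_min &
        .data$ctl_det <= filters$control_detect_max &
        .data$ctl_fraction <= filters$control_max_fraction) %>%
    arrange(.data$p) %>%
    select("protein", "gene", "mean_cm", "mean_control", "log2fc", "p",
           "pass")
  out
}

#' Classify genes into matrisome categories
#'
#' Exact, case-insensitive symbol lookup against a user-supplied
#' two-column map (`gene`, `category`). The categories follow the standard
#' matrisome division: collagens, ECM glycoproteins, proteoglycans, ECM
#' regulators, ECM-affiliated proteins and secreted factors; unmapped
#' genes are reported as `"non-matrisome"`.
#'
#' @param genes Character vector of gene symbols.
#' @param category_map Tibble with columns `gene`, `category`.
#' @return Tibble (`gene`, `category`), one row per input gene, input
#'   order preserved.
#' @export
matrisome_classify <- function(genes, category_map) {
  if (!all(c("gene", "category") %in% names(category_map))) {
    abort("category_map needs columns gene, category")
  }
  key <- toupper(category_map$gene)
  dup <- duplicated(key)
  if (any(dup)) {
    conflicts <- tapply(category_map$category, key, function(x) {
      length(unique(x)) > 1
    })
    if (any(conflicts)) {
      abort(paste("conflicting map entries for:",
                  paste(names(conflicts)[conflicts], collapse = ", ")))
    }
    category_map <- category_map[!dup, ]
    key <- key[!dup]
  }
  idx <- match(toupper(genes), key)
  tibble(gene = genes,
         category = ifelse(is.na(idx), "non-matrisome",
                           category_map$category[idx]))
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each annotation term, computes the upper-tail hypergeometric
#' probability of at least the observed overlap between the hit set and
#' the term's genes (both restricted to the universe), adjusts across all
#' tested terms by Benjamini-Hochberg, and returns terms passing the FDR
#' cutoff, sorted by p.
#'
#' @param hit_set Character vector of hit genes (must lie within
#'   `universe`).
#' @param universe Character vector: the reference gene set (e.g. the full
#'   cell-pellet proteome).
#' @param annotation Named list mapping term ids to gene sets.
#' @param fdr_cutoff Report terms with BH-adjusted value below this
#'   (default 0.5).
#' @return Tibble (`term`, `hits_in_set`, `set_size`, `hits_in_universe`,
#'   `universe_size`, `p`, `fdr`).
#' @export
enrichment <- function(hit_set, universe, annotation, fdr_cutoff = 0.5) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  hit_set <- unique(hit_set)
  if (!all(hit_set %in% universe)) {
    abort("hit_set contains genes outside the universe")
  }
  n_univ <- length(universe)
  n_hits <- length(hit_set)
  rows <- purrr::imap_dfr(annotation, function(genes, term) {
    set_in_univ <- intersect(unique(genes), universe)
    k <- length(intersect(set_in_univ, hit_set))
    m <- length(set_in_univ)
    p <- if (m == 0L) 1 else phyper(k - 1L, m, n_univ - m, n_hits,
                                    lower.tail = FALSE)
    tibble(term = term, hits_in_set = k, set_size = m,
           hits_in_universe = n_hits, universe_size = n_univ, p = p)
  })
  rows$fdr <- p.adjust(rows$p, method = "BH")
  rows %>% filter(.data$fdr < fdr_cutoff) %>% arrange(.data$p)
}
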