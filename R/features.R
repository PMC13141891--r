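#' Taxon prevalence and core-taxon screening
#'
#' `prevalence()` reports, for every taxon, the fraction of samples in which
#' it is detected (count > 0) and its mean relative abundance. `core_taxa()`
#' keeps the taxa whose prevalence meets a threshold; sweeping the threshold
#' over 0.80, 0.90, 0.95 and 1.00 reproduces the usual tiered definition of
#' a core microbiota.
#'
#' @param table A [feature_table].
#' @param threshold Prevalence cut-off in (0, 1]; a taxon is core when its
#'   prevalence is greater than or equal to the threshold.
#' @return A tibble with columns `taxon_id`, `prevalence`,
#'   `mean_rel_abundance`, sorted by prevalence (descending) then taxon_id.
#' @examples
#' ft <- simulate_neutral_table(community_sim_config(
#'   n_taxa = 50, n_samples = 12, seed = 1))$table
#' core_taxa(ft, 0.9)
#' @export
core_taxa <- function(table, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a single value in (0, 1]", call. = FALSE)
  }
  dplyr::filter(prevalence(table), .data$prevalence >= threshold)
}

#' @rdname core_taxa
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  ra <- relative_abundance(table)
  out <- tibble::tibble(
    taxon_id = table$taxon_ids,
    prevalence = unname(rowMeans(table$counts > 0)),
    mean_rel_abundance = unname(rowMeans(ra))
  )
  dplyr::arrange(out, dplyr::desc(.data$prevalence), .data$taxon_id)
}

#' Shannon diversity of one sample
#'
#' Shannon entropy H = -sum(q_i * log(q_i)) over the taxa with positive
#' counts, with q_i the within-sample relative abundance. The natural
#' logarithm is used by default (configurable via `base`), so a perfectly
#' even community of S taxa scores log(S).
#'
#' @param counts Non-negative numeric vector of counts for one sample.
#' @param base Logarithm base; default `exp(1)`.
#' @return A single non-negative number.
#' @examples
#' shannon(c(5, 5, 5, 5))  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("`counts` must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all counts are zero; diversity undefined", call. = FALSE)
  q <- counts[counts > 0] / total
  -sum(q * log(q, base = base))
}

#' Per-sample Shannon diversity of a feature table
#'
#' @param table A [feature_table].
#' @param base Logarithm base passed to [shannon()].
#' @return The table's metadata tibble with an added `shannon` column.
#' @export
sample_shannon <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "feature_table"))
  dplyr::mutate(table$metadata,
                shannon = apply(table$counts, 2, shannon, base = base))
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' Runs a two-sided Wilcoxon rank-sum test for every unordered pair of
#' groups and adjusts the p-values over the full pair set with the
#' Benjamini-Hochberg step-up procedure (reported as `q`). The exact null
#' distribution is used for small tie-free groups (both n <= 20); otherwise
#' the normal approximation with continuity and tie correction applies.
#'
#' @param data A data frame.
#' @param value Column holding the response (e.g. Shannon diversity),
#'   unquoted.
#' @param group Column holding the group labels, unquoted.
#' @return A tibble with columns `group_a`, `group_b`, `n_a`, `n_b`, `p`,
#'   `q`. Pairs where either group has fewer than two observations are
#'   dropped with a warning.
#' @examples
#' df <- data.frame(day = rep(c("D0", "D5", "D10"), each = 6),
#'                  h = c(rnorm(6, 1), rnorm(6, 2), rnorm(6, 2)))
#' pairwise_wilcoxon_bh(df, h, day)
#' @export
pairwise_wilcoxon_bh <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  levs <- unique(g)
  if (length(levs) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("group(s) with < 2 observations skipped: ",
            paste(small, collapse = ", "), call. = FALSE)
    levs <- setdiff(levs, small)
  }
  if (length(levs) < 2) stop("fewer than two usable groups", call. = FALSE)
  pairs <- utils::combn(sort(levs), 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    xa <- v[g == a]; xb <- v[g == b]
    use_exact <- length(xa) <= 20 && length(xb) <= 20 &&
      !anyDuplicated(c(xa, xb))
    p <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = use_exact, correct = TRUE)$p.value
    )
    tibble::tibble(group_a = a, group_b = b,
                   n_a = length(xa), n_b = length(xb), p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Spearman correlations of a covariate against taxon abundances
#'
#' Correlates a per-sample covariate (e.g. larval weight) with the
#' abundance of every taxon. The coefficient is computed on mid-ranks, so
#' ties are handled; significance uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom, and
#' the Bonferroni adjustment multiplies p by the number of taxa tested.
#'
#' @param x Numeric covariate, one value per sample.
#' @param y_matrix Taxon-by-sample numeric matrix of abundances whose
#'   columns align with `x`.
#' @return A tibble with columns `taxon_id`, `rho`, `p`, `p_bonferroni`.
#'   Taxa with constant abundance (rho undefined) are reported as `NA` with
#'   a warning; they still count towards the Bonferroni multiplier.
#' @export
spearman_bonferroni <- function(x, y_matrix) {
  y_matrix <- as.matrix(y_matrix)
  n <- length(x)
  if (ncol(y_matrix) != n) {
    stop("length of `x` must equal the number of samples (columns)", call. = FALSE)
  }
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  n_tests <- nrow(y_matrix)
  if (stats::sd(x) == 0) {
    warning("`x` is constant; all correlations undefined", call. = FALSE)
    return(tibble::tibble(taxon_id = rownames(y_matrix), rho = NA_real_,
                          p = NA_real_, p_bonferroni = NA_real_))
  }
  rx <- rank(x)
  res <- purrr::map(seq_len(n_tests), function(i) {
    yi <- y_matrix[i, ]
    if (stats::sd(yi) == 0) {
      return(tibble::tibble(rho = NA_real_, p = NA_real_))
    }
    rho <- stats::cor(rx, rank(yi))
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    tibble::tibble(rho = rho, p = p)
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out,
                       taxon_id = rownames(y_matrix) %||% as.character(seq_len(n_tests)),
                       p_bonferroni = pmin(1, .data$p * n_tests),
                       .before = 1)
  if (anyNA(out$rho)) {
    warning(sum(is.na(out$rho)), " taxa with constant abundance: rho undefined",
            call. = FALSE)
  }
  out
}

#' Prevalence bar chart across core thresholds
#'
#' Plots taxon prevalence in decreasing order with dashed reference lines
#' at the supplied core-taxon thresholds.
#'
#' @param table A [feature_table].
#' @param thresholds Reference prevalence thresholds to draw.
#' @param top_n Number of highest-prevalence taxa to show.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(table, thresholds = c(0.8, 0.9, 0.95, 1),
                            top_n = 30) {
  pv <- utils::head(prevalence(table), top_n)
  pv$taxon_id <- factor(pv$taxon_id, levels = rev(pv$taxon_id))
  ggplot2::ggplot(pv, ggplot2::aes(x = .data$taxon_id, y = .data$prevalence)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Prevalence across samples") +
    ggplot2::theme_minimal()
}
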