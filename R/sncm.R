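#' Predicted detection frequency under the neutral community model
#'
#' Under neutral assembly with immigration, the local relative abundance of
#' a taxon whose metacommunity mean relative abundance is `p` follows a
#' Beta(N m p, N m (1 - p)) distribution, where `N` is the local community
#' size and `m` the migration (immigration) probability. A taxon is scored
#' detected when its local abundance exceeds the detection limit `d`, so
#' its expected detection frequency across samples is
#' `1 - pbeta(d, N m p, N m (1 - p))`.
#'
#' @param p Mean relative abundance(s) in (0, 1); vectorised.
#' @param m Migration probability in (0, 1).
#' @param N Community size (mean reads per sample), positive.
#' @param d Detection limit in (0, 1); conventionally `1 / N` (one read).
#' @return Predicted detection frequency in \[0, 1\], same length as `p`.
#'   Monotone non-decreasing in both `p` and `m`.
#' @examples
#' predict_freq(c(1e-5, 1e-4, 1e-3), m = 0.05, N = 15000, d = 1 / 15000)
#' @export
predict_freq <- function(p, m, N, d) {
  if (any(p <= 0) || any(p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (m <= 0 || m >= 1) stop("`m` must lie in (0, 1)", call. = FALSE)
  if (N <= 0) stop("`N` must be positive", call. = FALSE)
  if (d <= 0 || d >= 1) stop("`d` must lie in (0, 1)", call. = FALSE)
  shape1 <- N * m * p
  shape2 <- N * m * (1 - p)
  if (any(shape1 <= 0) || any(shape2 <= 0)) {
    stop("beta shape parameters must be positive", call. = FALSE)
  }
  stats::pbeta(d, shape1, shape2, lower.tail = FALSE)
}

#' Summarise a feature table for neutral-model fitting
#'
#' Computes, per taxon, the mean relative abundance `p` (mean over samples
#' of the within-sample relative abundance) and the observed detection
#' frequency `freq` (fraction of samples with a nonzero count), together
#' with the community size `N` (mean per-sample total count).
#'
#' @param table A [feature_table]; taxa absent from every sample should be
#'   removed first with [filter_zero_taxa()].
#' @return A list with `records` (tibble: `taxon_id`, `p`, `freq`),
#'   `N` and `n_samples`.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$counts) == 0 || ncol(table$counts) == 0) {
    stop("empty feature table", call. = FALSE)
  }
  ra <- relative_abundance(table)
  list(
    records = tibble::tibble(
      taxon_id = table$taxon_ids,
      p = unname(rowMeans(ra)),
      freq = unname(rowMeans(table$counts > 0))
    ),
    N = mean(colSums(table$counts)),
    n_samples = ncol(table$counts)
  )
}

#' Wilson score confidence interval
#'
#' Closed-form Wilson score interval for a binomial proportion. The
#' successes argument may be non-integer: when building the neutral-model
#' envelope it is the predicted detection frequency times the number of
#' samples, used without rounding.
#'
#' @param successes Number of successes, in \[0, n\]; may be fractional.
#' @param n Number of trials, positive integer.
#' @param alpha Significance level; default 0.05 gives a 95% interval.
#' @return Named numeric vector `c(lower, upper)` with
#'   `0 <= lower <= successes/n <= upper <= 1`.
#' @examples
#' wilson_interval(7.5, 30)
#' @export
wilson_interval <- function(successes, n, alpha = 0.05) {
  if (length(n) != 1 || n <= 0) stop("`n` must be a positive integer", call. = FALSE)
  if (any(successes < 0) || any(successes > n)) {
    stop("`successes` must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  phat <- successes / n
  centre <- phat + z^2 / (2 * n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lower <- pmax(0, (centre - half) / denom)
  upper <- pmin(1, (centre + half) / denom)
  if (length(successes) == 1) c(lower = lower, upper = upper)
  else cbind(lower = lower, upper = upper)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration probability `m` by bounded non-linear least
#' squares on the relationship between each taxon's mean relative abundance
#' and its observed detection frequency, then classifies every taxon as
#' Neutral, Above or Below the 95% Wilson score envelope around the
#' model-predicted frequencies.
#'
#' The single free parameter `m` is fitted on (1e-6, 1 - 1e-6) with a
#' Levenberg-Marquardt least-squares routine started from several points
#' (0.001, 0.01, 0.1, 0.5); the best residual sum of squares wins, which
#' makes the fit deterministic given the data. Fit quality is reported as
#' `r_squared = 1 - SSE/SST`, `rmse = sqrt(SSE/(n_taxa - 1))`, and AIC/BIC
#' from a Gaussian residual log-likelihood with k = 2 parameters (m and the
#' residual standard deviation).
#'
#' @param table A [feature_table]. Taxa with zero counts across all samples
#'   are removed before fitting.
#' @param d Detection limit; `NULL` (default) uses `1 / N`, i.e. one read
#'   out of the mean per-sample depth.
#' @param alpha Significance level of the Wilson envelope (default 0.05).
#' @return An object of class `neutral_fit` with elements `m`, `N`, `d`,
#'   `r_squared`, `rmse`, `aic`, `bic`, `loglik`, `n_samples`, `n_taxa` and
#'   `records`, a tibble with one row per fitted taxon (`taxon_id`, `p`,
#'   `freq`, `freq_pred`, `ci_lower`, `ci_upper`, `partition`). Use
#'   [generics::tidy()] / [generics::glance()] to extract tidy summaries
#'   and [ggplot2::autoplot()] for the occurrence-abundance plot.
#' @examples
#' sim <- simulate_neutral_table(community_sim_config(
#'   n_taxa = 300, n_samples = 30, seed = 7))
#' fit <- fit_neutral(sim$table)
#' glance(fit)
#' @export
fit_neutral <- function(table, d = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  table <- filter_zero_taxa(table)
  if (nrow(table$counts) < 10) {
    stop("need at least 10 taxa with nonzero counts to fit", call. = FALSE)
  }
  s <- summarize_table(table)
  rec <- s$records
  N <- s$N
  if (is.null(d)) d <- 1 / N
  if (d <= 0 || d >= 1) stop("`d` must lie in (0, 1)", call. = FALSE)

  m_hat <- .fit_m(rec$p, rec$freq, N, d)

  freq_pred <- predict_freq(rec$p, m_hat, N, d)
  resid <- rec$freq - freq_pred
  sse <- sum(resid^2)
  sst <- sum((rec$freq - mean(rec$freq))^2)
  n <- nrow(rec)
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / (n - 1))
  # Gaussian residual log-likelihood at the MLE sigma^2 = SSE/n; k = 2 (m, sigma)
  loglik <- -n / 2 * (log(2 * pi) + log(sse / n) + 1)
  k <- 2
  aic <- 2 * k - 2 * loglik
  bic <- k * log(n) - 2 * loglik

  rec <- dplyr::mutate(rec, freq_pred = freq_pred)
  rec <- classify(rec, n_samples = s$n_samples, alpha = alpha)

  structure(
    list(m = m_hat, N = N, d = d, r_squared = r2, rmse = rmse,
         aic = aic, bic = bic, loglik = loglik,
         n_samples = s$n_samples, n_taxa = n, alpha = alpha,
         records = rec),
    class = "neutral_fit"
  )
}

# Bounded 1-parameter least squares with multistart; deterministic.
.fit_m <- function(p, freq, N, d, starts = c(0.001, 0.01, 0.1, 0.5)) {
  lo <- 1e-6
  hi <- 1 - 1e-6
  sse_of <- function(m) sum((freq - predict_freq(p, m, N, d))^2)
  best <- NULL
  for (m0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(m = m0),
        lower = lo, upper = hi,
        fn = function(par) freq - predict_freq(p, par$m, N, d)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cand <- list(m = fit$par$m, sse = sse_of(fit$par$m), info = fit$info)
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  if (is.null(best)) {
    stop("neutral-model optimisation failed to converge from all starts",
         call. = FALSE)
  }
  # polish with golden-section search in case LM stalled on a plateau
  opt <- stats::optimize(sse_of, interval = c(lo, hi), tol = 1e-10)
  if (opt$objective < best$sse) best <- list(m = opt$minimum, sse = opt$objective)
  best$m
}

#' Classify taxa against the Wilson envelope
#'
#' Adds the 95% (or `1 - alpha`) Wilson score interval around each taxon's
#' predicted detection frequency and partitions taxa by strict comparison:
#' `Above` when the observed frequency exceeds the upper bound, `Below`
#' when it falls short of the lower bound, and `Neutral` on the closed
#' interval (a frequency exactly on a bound is Neutral).
#'
#' @param records Tibble with at least `freq` and `freq_pred` columns.
#' @param n_samples Number of samples behind the observed frequencies.
#' @param alpha Significance level (default 0.05).
#' @return `records` with added `ci_lower`, `ci_upper` and `partition`
#'   (factor with levels Neutral, Above, Below) columns.
#' @export
classify <- function(records, n_samples, alpha = 0.05) {
  ci <- wilson_interval(records$freq_pred * n_samples, n_samples, alpha)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1, dimnames = list(NULL, names(ci)))
  records$ci_lower <- ci[, "lower"]
  records$ci_upper <- ci[, "upper"]
  records$partition <- factor(
    dplyr::case_when(
      records$freq > records$ci_upper ~ "Above",
      records$freq < records$ci_lower ~ "Below",
      TRUE ~ "Neutral"
    ),
    levels = c("Neutral", "Above", "Below")
  )
  records
}

#' Stringent stepwise filter for non-neutral taxa
#'
#' Reduces a classified record set to taxa of high confidence by applying,
#' in order: (1) mean relative abundance above `min_abundance` (default
#' 1%, strict); (2) partition among `keep_partitions` (default Above and
#' Below, i.e. deviating from neutral expectation); (3) detection frequency
#' of at least `min_freq` (default 20% of samples); (4) deviation from the
#' model prediction exceeding `min_deviation` (default 0.05). Stage 4 uses
#' the absolute deviation `|freq - freq_pred| > min_deviation`; set
#' `literal_stage4 = TRUE` to instead require `freq_pred > min_deviation`
#' (a literal reading of the same rule occasionally seen in scripts of this
#' lineage).
#'
#' @param records A classified record tibble (from [classify()] or a
#'   `neutral_fit`'s `records`), or a `neutral_fit` object.
#' @param min_abundance,keep_partitions,min_freq,min_deviation Filter
#'   settings; see above.
#' @param literal_stage4 Use the literal `freq_pred > min_deviation`
#'   predicate for stage 4 instead of the absolute deviation.
#' @return A list with `records` (the surviving rows, with a
#'   `removed_at_stage` audit implied by the counts) and `audit`, a tibble
#'   with one row per stage: `stage`, `rule`, `n_in`, `n_removed`, `n_out`.
#' @examples
#' sim <- simulate_neutral_table(community_sim_config(
#'   n_taxa = 300, n_samples = 30, n_above = 10, seed = 3))
#' fit <- fit_neutral(sim$table)
#' stringent_filter(fit)$audit
#' @export
stringent_filter <- function(records,
                             min_abundance = 0.01,
                             keep_partitions = c("Above", "Below"),
                             min_freq = 0.2,
                             min_deviation = 0.05,
                             literal_stage4 = FALSE) {
  if (inherits(records, "neutral_fit")) records <- records$records
  needed <- c("p", "freq", "freq_pred", "partition")
  if (!all(needed %in% names(records))) {
    stop("`records` must be classified (columns ",
         paste(needed, collapse = ", "), ")", call. = FALSE)
  }
  stage4_rule <- if (literal_stage4) {
    sprintf("freq_pred > %g", min_deviation)
  } else {
    sprintf("|freq - freq_pred| > %g", min_deviation)
  }
  stages <- list(
    list(rule = sprintf("p > %g", min_abundance),
         pred = function(r) r$p > min_abundance),
    list(rule = sprintf("partition in {%s}", paste(keep_partitions, collapse = ", ")),
         pred = function(r) as.character(r$partition) %in% keep_partitions),
    list(rule = sprintf("freq >= %g", min_freq),
         pred = function(r) r$freq >= min_freq),
    list(rule = stage4_rule,
         pred = function(r) {
           if (literal_stage4) r$freq_pred > min_deviation
           else abs(r$freq - r$freq_pred) > min_deviation
         })
  )
  audit <- vector("list", length(stages))
  cur <- records
  for (i in seq_along(stages)) {
    n_in <- nrow(cur)
    keep <- stages[[i]]$pred(cur)
    cur <- cur[keep, , drop = FALSE]
    audit[[i]] <- tibble::tibble(stage = i, rule = stages[[i]]$rule,
                                 n_in = n_in, n_removed = n_in - nrow(cur),
                                 n_out = nrow(cur))
  }
  list(records = cur, audit = dplyr::bind_rows(audit))
}

#' Fit the neutral model per group of samples
#'
#' Splits the samples of a feature table by a metadata field (typically the
#' sub-line), runs the full per-group pipeline — zero-taxon exclusion,
#' summary, model fit, Wilson classification, stringent filter — and
#' returns every group's fit plus tidy record and summary tables.
#'
#' @param table A [feature_table].
#' @param group_by Name of the metadata column to split on (string),
#'   e.g. `"sub_line"`.
#' @param d,alpha Passed to [fit_neutral()].
#' @param min_samples Groups with fewer samples are skipped with a warning
#'   (default 5).
#' @param ... Stringent-filter settings passed to [stringent_filter()].
#' @return An object of class `neutral_fit_set`: a list with `fits` (named
#'   list of `neutral_fit`), `records` (tibble of all per-taxon records
#'   with `group` and `passed_stringent` columns), `summary` (one row per
#'   group: n_taxa, m, N, d, r2, rmse, aic, bic, partition counts) and
#'   `audits` (per-group stringent-filter audit).
#' @export
run_sncm <- function(table, group_by, d = NULL, alpha = 0.05,
                     min_samples = 5, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!group_by %in% names(table$metadata)) {
    stop("metadata has no column `", group_by, "`", call. = FALSE)
  }
  groups <- split(table$metadata$sample_id, table$metadata[[group_by]])
  fits <- list(); recs <- list(); sums <- list(); audits <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < min_samples) {
      warning("group `", g, "` has ", length(ids),
              " samples (< ", min_samples, "); skipped", call. = FALSE)
      next
    }
    sub <- feature_table(table$counts[, ids, drop = FALSE],
                         table$metadata[table$metadata$sample_id %in% ids, ])
    fit <- fit_neutral(sub, d = d, alpha = alpha)
    sf <- stringent_filter(fit, ...)
    fit$records$passed_stringent <- fit$records$taxon_id %in% sf$records$taxon_id
    fits[[g]] <- fit
    recs[[g]] <- dplyr::mutate(fit$records, group = g, .before = 1)
    audits[[g]] <- dplyr::mutate(sf$audit, group = g, .before = 1)
    sums[[g]] <- dplyr::mutate(glance(fit), group = g, .before = 1)
  }
  if (length(fits) == 0) stop("no group had enough samples", call. = FALSE)
  structure(
    list(fits = fits,
         records = dplyr::bind_rows(recs),
         summary = dplyr::bind_rows(sums),
         audits = dplyr::bind_rows(audits),
         group_by = group_by),
    class = "neutral_fit_set"
  )
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("<neutral_fit> ", x$n_taxa, " taxa, ", x$n_samples, " samples\n", sep = "")
  cat(sprintf("  m = %.4f, N = %.1f, d = %.3g\n", x$m, x$N, x$d))
  cat(sprintf("  R2 = %.3f, RMSE = %.4f, AIC = %.1f, BIC = %.1f\n",
              x$r_squared, x$rmse, x$aic, x$bic))
  print(table(x$records$partition))
  invisible(x)
}

#' @export
print.neutral_fit_set <- function(x, ...) {
  cat("<neutral_fit_set> ", length(x$fits), " group(s) by `",
      x$group_by, "`\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy per-taxon records of a neutral-model fit
#'
#' @param x A `neutral_fit` or `neutral_fit_set`.
#' @param ... Unused.
#' @return A tibble with one row per taxon (and a `group` column for sets).
#' @method tidy neutral_fit
#' @export
tidy.neutral_fit <- function(x, ...) x$records

#' @rdname tidy.neutral_fit
#' @method tidy neutral_fit_set
#' @export
tidy.neutral_fit_set <- function(x, ...) x$records

#' One-row fit summary of a neutral-model fit
#'
#' @param x A `neutral_fit` or `neutral_fit_set`.
#' @param ... Unused.
#' @return A tibble with columns n_taxa, n_samples, m, N, d, r_squared,
#'   rmse, aic, bic and the partition counts (one row per group for sets).
#' @method glance neutral_fit
#' @export
glance.neutral_fit <- function(x, ...) {
  counts <- table(x$records$partition)
  tibble::tibble(
    n_taxa = x$n_taxa, n_samples = x$n_samples,
    m = x$m, N = x$N, d = x$d,
    r_squared = x$r_squared, rmse = x$rmse, aic = x$aic, bic = x$bic,
    n_neutral = as.integer(counts[["Neutral"]]),
    n_above = as.integer(counts[["Above"]]),
    n_below = as.integer(counts[["Below"]])
  )
}

#' @rdname glance.neutral_fit
#' @method glance neutral_fit_set
#' @export
glance.neutral_fit_set <- function(x, ...) x$summary

#' Occurrence-frequency versus abundance plot
#'
#' Draws the classic neutral-model figure: observed detection frequency
#' against log10 mean relative abundance, the fitted neutral expectation,
#' and the Wilson envelope, with points coloured by partition.
#'
#' @param object A `neutral_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neutral_fit
#' @export
autoplot.neutral_fit <- function(object, ...) {
  rec <- object$records
  curve <- tibble::tibble(
    p = exp(seq(log(min(rec$p)), log(max(rec$p)), length.out = 400))
  )
  curve$freq_pred <- predict_freq(curve$p, object$m, object$N, object$d)
  ci <- wilson_interval(curve$freq_pred * object$n_samples,
                        object$n_samples, object$alpha)
  curve$ci_lower <- ci[, "lower"]; curve$ci_upper <- ci[, "upper"]
  ggplot2::ggplot(rec, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq, colour = .data$partition),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$freq_pred)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$ci_lower),
                       linetype = "dashed") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$ci_upper),
                       linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(Neutral = "grey50",
                                            Above = "#2166AC",
                                            Below = "#B2182B")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "Detection frequency",
                  colour = "Partition",
                  subtitle = sprintf("m = %.4f, R2 = %.3f",
                                     object$m, object$r_squared)) +
    ggplot2::theme_minimal()
}
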