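#' Mid-parent phenotype
#'
#' The arithmetic mean of the sire and dam phenotypes of one mating pair.
#'
#' @param sire,dam Positive phenotype values (e.g. pupal weight in grams);
#'   vectorised.
#' @return `(sire + dam) / 2`.
#' @export
midparent <- function(sire, dam) {
  if (any(sire <= 0) || any(dam <= 0)) {
    stop("parental phenotypes must be positive", call. = FALSE)
  }
  (sire + dam) / 2
}

#' Narrow-sense heritability by offspring-on-mid-parent regression
#'
#' Estimates narrow-sense heritability h2 of a phenotype as the slope of
#' the ordinary least-squares regression of family mean offspring phenotype
#' on mid-parent phenotype (Falconer-Mackay single-generation design:
#' h2 = b_op, with no factor-of-two correction because the mid-parent value
#' already averages both parents).
#'
#' @param pedigree A data frame with one row per offspring and columns
#'   `family_id`, `sire_weight`, `dam_weight`, `offspring_weight` (all
#'   weights positive).
#' @param weight_by_n Weight families by their offspring count in the
#'   regression (default FALSE: unweighted over family means, matching the
#'   classical design where every family contributes equally).
#' @return An object of class `heritability_fit` with elements `h2`
#'   (slope), `intercept`, `se` (OLS slope standard error, provided for
#'   completeness), `r_squared`, `n_families` and `families` (tibble of
#'   per-family mid-parent and mean offspring values). `tidy()`, `glance()`
#'   and `autoplot()` methods are available.
#' @examples
#' ped <- simulate_pedigree(pedigree_sim_config(n_families = 50, seed = 1))
#' estimate_h2(ped)
#' @export
estimate_h2 <- function(pedigree, weight_by_n = FALSE) {
  pedigree <- tibble::as_tibble(pedigree)
  needed <- c("family_id", "sire_weight", "dam_weight", "offspring_weight")
  if (!all(needed %in% names(pedigree))) {
    stop("pedigree needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(pedigree$offspring_weight <= 0)) {
    stop("offspring weights must be positive", call. = FALSE)
  }
  fam <- pedigree |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      midparent = midparent(.data$sire_weight[1], .data$dam_weight[1]),
      offspring_mean = mean(.data$offspring_weight),
      n_offspring = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(fam) < 3) stop("need at least 3 families", call. = FALSE)
  if (stats::sd(fam$midparent) == 0) {
    stop("all mid-parent values identical; slope undefined", call. = FALSE)
  }
  w <- if (weight_by_n) fam$n_offspring else NULL
  fit <- stats::lm(offspring_mean ~ midparent, data = fam, weights = w)
  sm <- summary(fit)
  structure(
    list(h2 = unname(stats::coef(fit)["midparent"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         se = unname(sm$coefficients["midparent", "Std. Error"]),
         r_squared = sm$r.squared,
         n_families = nrow(fam),
         weighted = weight_by_n,
         families = fam,
         lm = fit),
    class = "heritability_fit"
  )
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat("<heritability_fit> ", x$n_families, " families\n", sep = "")
  cat(sprintf("  h2 = %.3f (SE %.3f), intercept = %.4f, R2 = %.3f\n",
              x$h2, x$se, x$intercept, x$r_squared))
  invisible(x)
}

#' Tidy the per-family data behind a heritability fit
#'
#' @param x A `heritability_fit`.
#' @param ... Unused.
#' @return A tibble with `family_id`, `midparent`, `offspring_mean`,
#'   `n_offspring`.
#' @method tidy heritability_fit
#' @export
tidy.heritability_fit <- function(x, ...) x$families

#' One-row summary of a heritability fit
#'
#' @param x A `heritability_fit`.
#' @param ... Unused.
#' @return A tibble with `h2`, `se`, `intercept`, `r_squared`,
#'   `n_families`.
#' @method glance heritability_fit
#' @export
glance.heritability_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se = x$se, intercept = x$intercept,
                 r_squared = x$r_squared, n_families = x$n_families)
}

#' Offspring-on-mid-parent regression plot
#'
#' @param object A `heritability_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heritability_fit
#' @export
autoplot.heritability_fit <- function(object, ...) {
  ggplot2::ggplot(object$families,
                  ggplot2::aes(x = .data$midparent, y = .data$offspring_mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$h2,
                         colour = "firebrick") +
    ggplot2::labs(x = "Mid-parent phenotype", y = "Mean offspring phenotype",
                  subtitle = sprintf("h2 = %.3f, R2 = %.3f",
                                     object$h2, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Read a pedigree table
#'
#' @param path TSV with columns `family_id`, `sire_weight`, `dam_weight`,
#'   `offspring_weight`, one row per offspring.
#' @return A tibble.
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
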