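test_that("summarize_table matches a naive double-loop recomputation", {
  set.seed(42)
  m <- matrix(rpois(200 * 30, 2), 200, 30,
              dimnames = list(sprintf("t%03d", 1:200), sprintf("s%02d", 1:30)))
  m <- m[rowSums(m) > 0, ]
  ft <- feature_table(m, data.frame(sample_id = colnames(m)))
  s <- summarize_table(ft)

  p_ref <- numeric(nrow(m)); freq_ref <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    acc <- 0
    for (j in seq_len(ncol(m))) acc <- acc + m[i, j] / sum(m[, j])
    p_ref[i] <- acc / ncol(m)
    freq_ref[i] <- sum(m[i, ] > 0) / ncol(m)
  }
  expect_equal(s$records$p, p_ref)
  expect_equal(s$records$freq, freq_ref)
  expect_equal(s$N, mean(colSums(m)))
  expect_equal(s$n_samples, 30)

  # trivial cases
  one <- feature_table(matrix(c(1L, 2L), 1, 2,
                              dimnames = list("t", c("s1", "s2"))),
                       data.frame(sample_id = c("s1", "s2")))
  expect_equal(summarize_table(one)$records$freq, 1)
  two <- feature_table(matrix(c(1L, 9L, 3L, 7L), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       data.frame(sample_id = c("s1", "s2")))
  expect_equal(summarize_table(two)$records$p, c(mean(c(0.1, 0.3)),
                                                 mean(c(0.9, 0.7))))
})

test_that("filter_zero_taxa drops exactly the all-zero taxa", {
  set.seed(13)
  m <- matrix(rbinom(10 * 6, 1, 0.3) * rpois(60, 3), 10, 6,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  m[c(2, 5, 9), ] <- 0L
  ft <- feature_table(m, data.frame(sample_id = colnames(m)))
  out <- filter_zero_taxa(ft)
  expect_setequal(out$taxon_ids, rownames(m)[rowSums(m) > 0])
  expect_equal(out$sample_ids, ft$sample_ids)
  # identity when nothing is all-zero
  m2 <- m[rowSums(m) > 0, ]
  ft2 <- feature_table(m2, data.frame(sample_id = colnames(m2)))
  expect_identical(filter_zero_taxa(ft2)$counts, ft2$counts)
})

test_that("predict_freq obeys limits, monotonicity, and a Monte-Carlo oracle", {
  expect_gt(predict_freq(0.01, 0.05, 15000, 1e-12), 1 - 1e-6)
  expect_lt(predict_freq(1e-9, 0.05, 15000, 1 / 15000), 1e-3)
  expect_error(predict_freq(0.01, 0, 15000, 1e-4))
  expect_error(predict_freq(0, 0.05, 15000, 1e-4))

  # monotone in p and in m on grids
  ps <- 10^seq(-6, -1, length.out = 40)
  expect_true(all(diff(predict_freq(ps, 0.05, 15000, 1 / 15000)) >= 0))
  ms <- seq(0.01, 0.5, length.out = 30)
  f_m <- vapply(ms, function(m) predict_freq(1e-4, m, 15000, 1 / 15000),
                numeric(1))
  expect_true(all(diff(f_m) >= 0))

  # Monte-Carlo oracle: beta draws thresholded at d
  set.seed(202)
  p <- 0.01; m <- 0.05; N <- 15000; d <- 1 / N
  for (p_i in c(0.01, 2e-5)) {
    draws <- rbeta(1e6, N * m * p_i, N * m * (1 - p_i))
    mc <- mean(draws > d)
    se <- sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(predict_freq(p_i, m, N, d) - mc), 3 * se + 1e-9)
  }
})

test_that("wilson_interval matches the closed form over a grid incl. boundaries", {
  z <- qnorm(0.975)
  wilson_ref <- function(s, n, alpha) {
    z <- qnorm(1 - alpha / 2)
    ph <- s / n
    c((ph + z^2 / (2 * n) - z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (ph + z^2 / (2 * n) + z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  for (n in c(5, 10, 30, 60)) {
    for (s in c(0, 0.5, 2.25, 7.5, n / 2, n - 0.1, n)) {
      if (s > n) next
      for (alpha in c(0.01, 0.05, 0.1)) {
        got <- wilson_interval(s, n, alpha)
        ref <- wilson_ref(s, n, alpha)
        expect_lt(max(abs(got - ref)), 1e-10)
        expect_true(got["lower"] >= 0 && got["upper"] <= 1)
        expect_true(got["lower"] <= s / n + 1e-12 && got["upper"] >= s / n - 1e-12)
      }
    }
  }
  expect_equal(unname(wilson_interval(0, 10)["lower"]), 0)
  expect_equal(unname(wilson_interval(10, 10)["upper"]), 1)
  # symmetry about 0.5 at p-hat = 0.5
  ci <- wilson_interval(5, 10)
  expect_equal(unname(ci["upper"] - 0.5), unname(0.5 - ci["lower"]))
  expect_error(wilson_interval(3, 0), "positive")
})

test_that("classification respects the closed-interval boundary convention", {
  rec <- tibble::tibble(taxon_id = c("a", "b", "c"),
                        p = c(0.01, 0.001, 0.02),
                        freq = c(0.5, 1.0, 0.1),
                        freq_pred = c(0.5, 0.05, 0.4))
  out <- classify(rec, n_samples = 40)
  # freq exactly inside -> Neutral; freq 1 with tiny prediction -> Above
  expect_equal(as.character(out$partition), c("Neutral", "Above", "Below"))
  # boundary: set freq exactly to the upper bound -> Neutral
  rec2 <- out[1, ]
  rec2$freq <- rec2$ci_upper
  out2 <- classify(rec2[, c("taxon_id", "p", "freq", "freq_pred")], 40)
  expect_equal(as.character(out2$partition), "Neutral")
  expect_true(all(out$ci_lower <= out$freq_pred & out$freq_pred <= out$ci_upper))
})

test_that("fitting recovers a known migration rate and is self-consistent", {
  # self-consistency: frequencies generated exactly from the model
  set.seed(61)
  p <- sort(runif(300, 1e-6, 0.02))
  N <- 15000; d <- 1 / N
  freq <- predict_freq(p, 0.04, N, d)
  m_hat <- neutralline:::.fit_m(p, freq, N, d)
  expect_lt(abs(m_hat - 0.04), 1e-4)

  # recovery from a simulated table (single seed here; the multi-seed
  # median is exercised in the acceptance suite)
  sim <- simulate_neutral_table(community_sim_config(
    n_taxa = 800, n_samples = 40, m_true = 0.05, seed = 17))
  fit <- fit_neutral(sim$table)
  expect_lt(abs(fit$m - 0.05) / 0.05, 0.3)
  expect_true(fit$r_squared <= 1)

  # diagnostics agree with an independent residual-based recomputation
  resid <- fit$records$freq - predict_freq(fit$records$p, fit$m, fit$N, fit$d)
  sse <- sum(resid^2)
  n <- nrow(fit$records)
  expect_equal(fit$r_squared,
               1 - sse / sum((fit$records$freq - mean(fit$records$freq))^2))
  expect_equal(fit$rmse, sqrt(sse / (n - 1)))
  ll <- -n / 2 * (log(2 * pi) + log(sse / n) + 1)
  expect_equal(fit$aic, 4 - 2 * ll)
  expect_equal(fit$bic, 2 * log(n) - 2 * ll)

  # partitions are exhaustive and exclusive
  expect_equal(sum(table(fit$records$partition)), n)
  expect_error(fit_neutral(tiny_table(n_taxa = 5)), "10 taxa")
})

test_that("stringent filter agrees with a four-predicate brute-force scan", {
  set.seed(77)
  n <- 500
  rec <- tibble::tibble(
    taxon_id = sprintf("t%03d", 1:n),
    p = runif(n, 0, 0.05),
    freq = runif(n),
    freq_pred = runif(n),
    partition = factor(sample(c("Neutral", "Above", "Below"), n, TRUE),
                       levels = c("Neutral", "Above", "Below"))
  )
  out <- stringent_filter(rec)

  keep1 <- rec$p > 0.01
  keep2 <- keep1 & rec$partition %in% c("Above", "Below")
  keep3 <- keep2 & rec$freq >= 0.2
  keep4 <- keep3 & abs(rec$freq - rec$freq_pred) > 0.05
  expect_identical(out$records$taxon_id, rec$taxon_id[keep4])
  expect_equal(out$audit$n_out, c(sum(keep1), sum(keep2), sum(keep3), sum(keep4)))
  expect_equal(out$audit$n_in - out$audit$n_removed, out$audit$n_out)
  expect_equal(out$audit$n_in[1], n)

  # the single-record stage examples
  expect_equal(stringent_filter(dplyr::mutate(rec[1, ], p = 0.005))$audit$n_removed[1], 1)
  neutral_rec <- dplyr::mutate(rec[1, ], p = 0.05, freq = 0.9,
                               partition = factor("Neutral", levels = levels(rec$partition)))
  aud <- stringent_filter(neutral_rec)$audit
  expect_equal(aud$n_removed[2], 1)

  # literal stage-4 reading
  lit <- stringent_filter(rec, literal_stage4 = TRUE)
  keep4l <- keep3 & rec$freq_pred > 0.05
  expect_identical(lit$records$taxon_id, rec$taxon_id[keep4l])
})

test_that("pure-neutral tables classify mostly Neutral; injected deviants are found", {
  sim <- simulate_neutral_table(community_sim_config(
    n_taxa = 1500, n_samples = 60, m_true = 0.05, seed = 23))
  fit <- fit_neutral(sim$table)
  expect_gte(mean(fit$records$partition == "Neutral"), 0.8)
  # false-positive control: stringent survivors are rare under neutrality
  surv <- stringent_filter(fit)
  expect_lte(nrow(surv$records) / fit$n_taxa, 0.05)

  sim2 <- simulate_neutral_table(community_sim_config(
    n_taxa = 1500, n_samples = 60, m_true = 0.05,
    n_above = 30, n_below = 30, seed = 29))
  fit2 <- fit_neutral(sim2$table)
  joined <- dplyr::inner_join(fit2$records, sim2$truth, by = "taxon_id")
  above_inj <- joined[joined$truth == "Above", ]
  expect_gte(sum(above_inj$partition == "Above"), 25)
  # enrichment of injected Above among classified Above
  base_rate <- 30 / nrow(joined)
  above_cls <- joined[joined$partition == "Above", ]
  expect_gte(mean(above_cls$truth == "Above") / base_rate, 5)
})

test_that("run_sncm fits each group and reports tidy summaries", {
  sims <- lapply(1:3, function(i) {
    simulate_neutral_table(community_sim_config(
      n_taxa = 250, n_samples = 12, seed = 100 + i), label = paste0("L", i))
  })
  counts <- do.call(cbind, lapply(sims, function(s) s$table$counts))
  md <- dplyr::bind_rows(lapply(sims, function(s) s$table$metadata))
  ft <- feature_table(counts, md)
  res <- run_sncm(ft, "sub_line")
  expect_equal(nrow(res$summary), 3)
  expect_setequal(res$summary$group, c("L1", "L2", "L3"))
  expect_equal(nrow(glance(res)), 3)
  expect_true(all(c("passed_stringent", "group") %in% names(tidy(res))))
  expect_true(all(res$summary$n_neutral + res$summary$n_above +
                    res$summary$n_below == res$summary$n_taxa))
  # too-small groups are skipped with a warning
  md2 <- md; md2$sub_line[md2$sub_line == "L3"][1:10] <- "L4"
  expect_warning(run_sncm(feature_table(counts, md2), "sub_line"), "skipped")
})
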