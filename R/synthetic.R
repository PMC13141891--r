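#' Simulation configurations
#'
#' Configuration constructors for the three in-package generators. All
#' generators are seed-deterministic: the same configuration and seed give
#' bit-identical output.
#'
#' `community_sim_config()` parameterises a taxon-by-sample count table
#' generated under the neutral community model itself: metacommunity
#' relative abundances are drawn log-normal, each sample's local relative
#' abundance of each taxon follows Beta(N m p, N m (1 - p)) with
#' N = `depth_mean`, and counts are binomial at the sample's sequencing
#' depth (rounded normal, truncated at 1,000 reads). Depth defaults mirror
#' a realistic nanopore 16S experiment (about 15,000 +/- 5,500 reads per
#' sample). Optionally `n_above` taxa are forced present in at least 95% of
#' samples and `n_below` taxa are zeroed in a random 60% of the samples
#' where they occurred, giving known over- and under-represented taxa.
#'
#' @param n_taxa,n_samples Table dimensions.
#' @param depth_mean,depth_sd Per-sample sequencing depth distribution.
#' @param m_true Generating migration probability.
#' @param meta_mu,meta_sigma Log-normal metacommunity shape (log scale).
#' @param n_above,n_below Number of deviant taxa to inject.
#' @param seed Integer RNG seed.
#' @return A config list of the matching class.
#' @export
community_sim_config <- function(n_taxa = 1500, n_samples = 60,
                                 depth_mean = 15000, depth_sd = 5500,
                                 m_true = 0.05, meta_mu = 0, meta_sigma = 2,
                                 n_above = 0, n_below = 0, seed = 1) {
  stopifnot(n_above + n_below <= n_taxa, m_true > 0, m_true < 1,
            depth_mean > 0, depth_sd >= 0)
  structure(list(n_taxa = n_taxa, n_samples = n_samples,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 m_true = m_true, meta_mu = meta_mu, meta_sigma = meta_sigma,
                 n_above = n_above, n_below = n_below, seed = as.integer(seed)),
            class = "community_sim_config")
}

#' @rdname community_sim_config
#' @param n_reads_per_sample Reads generated per sample.
#' @param insert_length_range Inclusive range of clean insert lengths (bp).
#' @param fraction_missing_barcode Fraction of reads lacking one barcode.
#' @param fraction_off_length Fraction of reads with an out-of-window
#'   insert length (half too short, half too long).
#' @export
read_sim_config <- function(n_reads_per_sample = 200,
                            insert_length_range = c(1200, 1800),
                            fraction_missing_barcode = 0,
                            fraction_off_length = 0, seed = 1) {
  stopifnot(fraction_missing_barcode >= 0, fraction_off_length >= 0,
            fraction_missing_barcode + fraction_off_length <= 1,
            length(insert_length_range) == 2,
            insert_length_range[1] <= insert_length_range[2])
  structure(list(n_reads_per_sample = n_reads_per_sample,
                 insert_length_range = insert_length_range,
                 fraction_missing_barcode = fraction_missing_barcode,
                 fraction_off_length = fraction_off_length,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' @rdname community_sim_config
#' @param n_families Number of mating pairs.
#' @param h2_true Generating narrow-sense heritability in \[0, 1\].
#' @param pheno_mean,pheno_sd Phenotype distribution of the parents (the
#'   defaults, 0.2 g +/- 0.03 g, are plausible black-soldier-fly pupal
#'   weights).
#' @param offspring_per_family Offspring measured per pair.
#' @param residual_sd Residual standard deviation of individual offspring
#'   around the additive expectation; `NULL` (default) sets it so that the
#'   offspring phenotypic variance roughly matches the parental one,
#'   `pheno_sd * sqrt(max(0, 1 - h2_true^2 / 2))`. Pass 0 for the
#'   noise-free limit.
#' @export
pedigree_sim_config <- function(n_families = 200, h2_true = 0.2,
                                pheno_mean = 0.2, pheno_sd = 0.03,
                                offspring_per_family = 10,
                                residual_sd = NULL, seed = 1) {
  stopifnot(h2_true >= 0, h2_true <= 1, pheno_mean > 0, pheno_sd >= 0,
            n_families >= 1, offspring_per_family >= 1)
  if (is.null(residual_sd)) {
    residual_sd <- pheno_sd * sqrt(max(0, 1 - h2_true^2 / 2))
  }
  structure(list(n_families = n_families, h2_true = h2_true,
                 pheno_mean = pheno_mean, pheno_sd = pheno_sd,
                 offspring_per_family = offspring_per_family,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "pedigree_sim_config")
}

#' Simulate a count table under the neutral community model
#'
#' Generates a [feature_table] whose detection-frequency versus abundance
#' cloud follows the neutral expectation at the configured migration rate,
#' plus optional injected deviant taxa (see [community_sim_config()]).
#' Deviant taxa are drawn from the band of taxa whose neutral detection
#' frequency lies between 0.2 and 0.8, so that forcing presence (Above) or
#' thinning occurrences (Below) produces a detectable, biologically
#' plausible deviation; when the band is too small it is widened.
#'
#' @param config A [community_sim_config()].
#' @param label Value used for the `sub_line` metadata field.
#' @return A list with `table` (a [feature_table]), `truth` (tibble of
#'   `taxon_id`, `truth` in Neutral/Above/Below) and `config`.
#' @export
simulate_neutral_table <- function(config, label = "SIM") {
  stopifnot(inherits(config, "community_sim_config"))
  set.seed(config$seed)
  nt <- config$n_taxa; ns <- config$n_samples
  meta <- stats::rlnorm(nt, config$meta_mu, config$meta_sigma)
  p <- meta / sum(meta)
  depth <- pmax(1000L, as.integer(round(
    stats::rnorm(ns, config$depth_mean, config$depth_sd))))
  N <- config$depth_mean
  shape1 <- N * config$m_true * p
  shape2 <- N * config$m_true * (1 - p)
  counts <- matrix(0L, nt, ns)
  for (s in seq_len(ns)) {
    x <- stats::rbeta(nt, shape1, shape2)
    counts[, s] <- stats::rbinom(nt, depth[s], x)
  }

  truth <- rep("Neutral", nt)
  n_dev <- config$n_above + config$n_below
  if (n_dev > 0) {
    f0 <- predict_freq(p, config$m_true, N, 1 / N)
    for (band in list(c(0.2, 0.8), c(0.05, 0.95), c(0, 1))) {
      eligible <- which(f0 >= band[1] & f0 <= band[2])
      if (length(eligible) >= n_dev) break
    }
    dev <- sample(eligible, n_dev)
    above <- dev[seq_len(config$n_above)]
    below <- setdiff(dev, above)
    for (i in above) {
      forced <- sample(ns, ceiling(0.95 * ns))
      counts[i, forced] <- pmax(counts[i, forced], 1L)
    }
    for (i in below) {
      present <- which(counts[i, ] > 0)
      if (length(present) > 0) {
        drop <- sample(present, round(0.6 * length(present)))
        counts[i, drop] <- 0L
      }
    }
    truth[above] <- "Above"
    truth[below] <- "Below"
  }

  taxon_ids <- sprintf("taxon_%04d", seq_len(nt))
  sample_ids <- sprintf("%s_s%03d", label, seq_len(ns))
  dimnames(counts) <- list(taxon_ids, sample_ids)
  md <- tibble::tibble(
    sample_id = sample_ids,
    sub_line = label,
    generation = "G1",
    day = "D0",
    replicate = sprintf("r%d", (seq_len(ns) - 1) %% 3 + 1)
  )
  list(table = feature_table(counts, md),
       truth = tibble::tibble(taxon_id = taxon_ids, truth = truth),
       config = config)
}

.random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate barcoded amplicon reads
#'
#' Builds synthetic dual-barcoded long reads for the demultiplexer: clean
#' reads are `fwd_barcode + insert + revcomp(rev_barcode)` with the insert
#' length drawn uniformly from `insert_length_range`; configured fractions
#' of reads lack one barcode or carry an out-of-window insert. Half of all
#' reads are emitted reverse-complemented. Qualities are a constant
#' placeholder (error/quality models are out of scope).
#'
#' @param specs Barcode table (see [barcode_specs()]).
#' @param config A [read_sim_config()].
#' @return A list with `reads` (tibble `read_id`, `sequence`, `qualities`)
#'   and `truth` (tibble `read_id`, `sample_id`, `class`, `insert_length`,
#'   `flipped`, `expected_status`).
#' @export
simulate_reads <- function(specs, config) {
  stopifnot(inherits(config, "read_sim_config"))
  specs <- barcode_specs(specs)
  set.seed(config$seed)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s)))
  rows <- list()
  counter <- 0L
  for (j in seq_len(nrow(specs))) {
    n <- config$n_reads_per_sample
    cls <- sample(c("clean", "missing_barcode", "off_length"), n,
                  replace = TRUE,
                  prob = c(1 - config$fraction_missing_barcode -
                             config$fraction_off_length,
                           config$fraction_missing_barcode,
                           config$fraction_off_length))
    for (i in seq_len(n)) {
      counter <- counter + 1L
      id <- sprintf("read_%06d", counter)
      this_cls <- cls[i]
      if (this_cls == "clean") {
        ilen <- sample(config$insert_length_range[1]:config$insert_length_range[2], 1)
        seq <- paste0(specs$fwd_barcode[j], .random_dna(1, ilen),
                      rc(specs$rev_barcode[j]))
        expected <- "assigned"
        sub_cls <- "clean"
      } else if (this_cls == "missing_barcode") {
        ilen <- sample(config$insert_length_range[1]:config$insert_length_range[2], 1)
        if (stats::runif(1) < 0.5) {
          seq <- paste0(.random_dna(1, ilen), rc(specs$rev_barcode[j]))
          expected <- "no_forward"; sub_cls <- "missing_forward"
        } else {
          seq <- paste0(specs$fwd_barcode[j], .random_dna(1, ilen))
          expected <- "no_reverse"; sub_cls <- "missing_reverse"
        }
      } else {
        if (stats::runif(1) < 0.5) {
          ilen <- sample(200:995, 1)
          expected <- "too_short"; sub_cls <- "too_short"
        } else {
          ilen <- sample(2005:2400, 1)
          expected <- "too_long"; sub_cls <- "too_long"
        }
        seq <- paste0(specs$fwd_barcode[j], .random_dna(1, ilen),
                      rc(specs$rev_barcode[j]))
      }
      flipped <- counter %% 2L == 0L
      if (flipped) seq <- rc(seq)
      rows[[counter]] <- tibble::tibble(
        read_id = id, sample_id = specs$sample_id[j], class = sub_cls,
        insert_length = ilen, flipped = flipped, expected_status = expected,
        sequence = seq
      )
    }
  }
  truth <- dplyr::bind_rows(rows)
  reads <- tibble::tibble(
    read_id = truth$read_id,
    sequence = truth$sequence,
    qualities = strrep("I", nchar(truth$sequence))
  )
  truth$sequence <- NULL
  list(reads = reads, truth = truth)
}

#' Write a reads tibble as FASTQ
#'
#' @param reads Tibble with columns `read_id`, `sequence` and optionally
#'   `qualities` (placeholder qualities are filled in when absent).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  q <- if ("qualities" %in% names(reads)) reads$qualities
       else rep(NA_character_, nrow(reads))
  .write_fastq(reads$read_id, reads$sequence, q, path)
}

#' Simulate an additive-genetic pedigree
#'
#' Draws parental phenotypes from a normal distribution and offspring from
#' the additive mid-parent model
#' `offspring = mu + h2 * (midparent - mu) + e`, so the expected slope of
#' the offspring-on-mid-parent regression equals `h2_true` at any residual
#' noise level.
#'
#' @param config A [pedigree_sim_config()].
#' @return A pedigree tibble with one row per offspring: `family_id`,
#'   `sire_weight`, `dam_weight`, `offspring_weight`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "pedigree_sim_config"))
  set.seed(config$seed)
  nf <- config$n_families; k <- config$offspring_per_family
  mu <- config$pheno_mean
  sire <- pmax(1e-6, stats::rnorm(nf, mu, config$pheno_sd))
  dam <- pmax(1e-6, stats::rnorm(nf, mu, config$pheno_sd))
  mp <- midparent(sire, dam)
  off <- lapply(seq_len(nf), function(f) {
    e <- if (config$residual_sd > 0) stats::rnorm(k, 0, config$residual_sd)
         else rep(0, k)
    pmax(1e-6, mu + config$h2_true * (mp[f] - mu) + e)
  })
  tibble::tibble(
    family_id = rep(sprintf("fam_%03d", seq_len(nf)), each = k),
    sire_weight = rep(sire, each = k),
    dam_weight = rep(dam, each = k),
    offspring_weight = unlist(off)
  )
}
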