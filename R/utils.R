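#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Deterministic example barcode set
#'
#' Generates a small set of distinct ACGT barcodes for examples, tests and
#' simulated sequencing runs. Barcodes are drawn deterministically from the
#' given seed and guaranteed pairwise distinct.
#'
#' @param n_samples Number of samples.
#' @param length Barcode length in bases (default 16).
#' @param seed RNG seed.
#' @return A validated barcode tibble (see [barcode_specs()]).
#' @export
example_barcodes <- function(n_samples = 3, length = 16, seed = 42) {
  set.seed(seed)
  bc <- character(0)
  while (length(bc) < 2 * n_samples) {
    cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
    if (!cand %in% bc) bc <- c(bc, cand)
  }
  barcode_specs(tibble::tibble(
    sample_id = sprintf("sample_%02d", seq_len(n_samples)),
    fwd_barcode = bc[seq_len(n_samples)],
    rev_barcode = bc[n_samples + seq_len(n_samples)]
  ))
}
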