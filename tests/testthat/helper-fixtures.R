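# Shared fixtures, built in code at test time.

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small deterministic count table with known structure
tiny_table <- function(n_taxa = 20, n_samples = 8, seed = 101) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, 5), n_taxa, n_samples)
  dimnames(m) <- list(sprintf("t%02d", seq_len(n_taxa)),
                      sprintf("s%02d", seq_len(n_samples)))
  feature_table(m, data.frame(sample_id = colnames(m),
                              sub_line = rep(c("A", "B"), each = n_samples / 2),
                              day = "D0"))
}

# brute-force all-offsets Hamming scan: independent oracle for find_barcode
brute_find <- function(sequence, barcode, end, window, max_mismatches) {
  len <- nchar(sequence)
  blen <- nchar(barcode)
  rng <- if (end == "head") {
    seq_len(max(0, min(window, len) - blen + 1))
  } else {
    gstart <- max(1, len - window + 1)
    if (len - blen + 1 < gstart) integer(0) else gstart:(len - blen + 1)
  }
  hits <- rng[vapply(rng, function(s) {
    sum(strsplit(substr(sequence, s, s + blen - 1), "")[[1]] !=
          strsplit(barcode, "")[[1]]) <= max_mismatches
  }, logical(1))]
  if (length(hits) == 0) return(NA_integer_)
  as.integer((if (end == "head") min(hits) else max(hits)) - 1L)
}
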