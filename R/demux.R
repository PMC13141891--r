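#' Validate a barcode specification table
#'
#' A barcode table maps each sample to its forward and reverse PCR barcode.
#' Barcodes must be plain ACGT, non-empty, and each (forward, reverse) pair
#' must be unique across samples.
#'
#' @param specs A data frame with columns `sample_id`, `fwd_barcode`,
#'   `rev_barcode`.
#' @return The validated table as a tibble with upper-cased barcodes.
#' @export
barcode_specs <- function(specs) {
  specs <- tibble::as_tibble(specs)
  needed <- c("sample_id", "fwd_barcode", "rev_barcode")
  if (!all(needed %in% names(specs))) {
    stop("barcode table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(specs$sample_id)) {
    stop("duplicate sample_id in barcode table", call. = FALSE)
  }
  specs$fwd_barcode <- toupper(specs$fwd_barcode)
  specs$rev_barcode <- toupper(specs$rev_barcode)
  bc <- c(specs$fwd_barcode, specs$rev_barcode)
  if (any(nchar(bc) == 0) || any(grepl("[^ACGT]", bc))) {
    stop("barcodes must be non-empty ACGT strings", call. = FALSE)
  }
  if (anyDuplicated(paste(specs$fwd_barcode, specs$rev_barcode))) {
    stop("duplicate (fwd, rev) barcode pair across samples", call. = FALSE)
  }
  specs
}

#' Read a barcode table from a TSV file
#'
#' @param path Tab-separated file with header
#'   `sample_id  fwd_barcode  rev_barcode`.
#' @return A validated barcode tibble (see [barcode_specs()]).
#' @export
read_barcode_table <- function(path) {
  barcode_specs(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Locate a barcode near one end of a read
#'
#' Searches for `barcode` within the first (`end = "head"`) or last
#' (`end = "tail"`) `window` bases of `sequence`, allowing up to
#' `max_mismatches` Hamming mismatches. The leftmost occurrence is reported
#' for the head, the rightmost for the tail, so trimming removes as much of
#' the barcode region as possible.
#'
#' @param sequence DNA string to search.
#' @param barcode DNA barcode (ACGT).
#' @param end `"head"` or `"tail"`.
#' @param window Search window length in bases (default 100). Must be at
#'   least the barcode length.
#' @param max_mismatches Maximum Hamming mismatches allowed (default 0,
#'   i.e. exact matching).
#' @return 0-based start position of the match within the full sequence, or
#'   `NA_integer_` when no occurrence is found in the window.
#' @examples
#' find_barcode("AAACGTAAAGGG", "ACGT", end = "head", window = 10)  # 2
#' @export
find_barcode <- function(sequence, barcode, end = c("head", "tail"),
                         window = 100, max_mismatches = 0) {
  end <- match.arg(end)
  if (window < nchar(barcode)) {
    stop("`window` must be at least the barcode length", call. = FALSE)
  }
  if (max_mismatches < 0) stop("`max_mismatches` must be >= 0", call. = FALSE)
  len <- nchar(sequence)
  if (len < nchar(barcode)) return(NA_integer_)
  if (end == "head") {
    sub <- substr(sequence, 1L, min(window, len))
    offset <- 0L
  } else {
    gstart <- max(1L, len - as.integer(window) + 1L)
    sub <- substr(sequence, gstart, len)
    offset <- gstart - 1L
  }
  hits <- Biostrings::matchPattern(barcode, Biostrings::DNAString(sub),
                                   max.mismatch = max_mismatches)
  if (length(hits) == 0) return(NA_integer_)
  st <- Biostrings::start(hits)
  pick <- if (end == "head") min(st) else max(st)
  as.integer(pick - 1L + offset)
}

# Vectorised end-matching over a DNAStringSet. Returns per-read 1-based
# global start of the chosen occurrence (leftmost in head, rightmost in
# tail) or NA.
.match_end <- function(seqs, barcode, end, window, max_mismatches) {
  w <- Biostrings::width(seqs)
  blen <- nchar(barcode)
  if (end == "head") {
    sub <- Biostrings::subseq(seqs, start = 1L, end = pmin(w, as.integer(window)))
    offset <- rep(0L, length(seqs))
  } else {
    gstart <- pmax(1L, w - as.integer(window) + 1L)
    sub <- Biostrings::subseq(seqs, start = gstart, end = w)
    offset <- gstart - 1L
  }
  out <- rep(NA_integer_, length(seqs))
  searchable <- Biostrings::width(sub) >= blen
  if (!any(searchable)) return(out)
  hits <- Biostrings::vmatchPattern(barcode, sub[searchable],
                                    max.mismatch = max_mismatches)
  starts <- Biostrings::startIndex(hits)
  pos <- vapply(starts, function(s) {
    if (is.null(s) || length(s) == 0) NA_integer_
    else if (end == "head") min(s) else max(s)
  }, integer(1))
  out[searchable] <- pos + offset[searchable]
  out
}

# Core demultiplexer over parallel character vectors. Returns a tibble with
# one row per read.
.demux_set <- function(read_ids, seqs, quals, specs, window = 100,
                       max_mismatches = 0, min_len = 1000, max_len = 2000,
                       revcomp_search = TRUE) {
  specs <- barcode_specs(specs)
  if (window < max(nchar(c(specs$fwd_barcode, specs$rev_barcode)))) {
    stop("`window` must be at least the longest barcode", call. = FALSE)
  }
  n <- length(seqs)
  empty <- tibble::tibble(
    read_id = character(), status = character(), sample_id = character(),
    trimmed_sequence = character(), trimmed_qualities = character(),
    orientation = character()
  )
  if (n == 0) return(empty)
  has_qual <- !is.null(quals)
  dna <- Biostrings::DNAStringSet(toupper(seqs))
  k <- nrow(specs)
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(specs$rev_barcode)))

  match_orientation <- function(d) {
    head_end <- matrix(NA_integer_, length(d), k)
    tail_start <- matrix(NA_integer_, length(d), k)
    for (j in seq_len(k)) {
      st <- .match_end(d, specs$fwd_barcode[j], "head", window, max_mismatches)
      head_end[, j] <- st + nchar(specs$fwd_barcode[j]) - 1L
      tail_start[, j] <- .match_end(d, rc_rev[j], "tail", window, max_mismatches)
    }
    list(head_end = head_end, tail_start = tail_start,
         both = !is.na(head_end) & !is.na(tail_start))
  }

  fwd_m <- match_orientation(dna)
  orient <- rep("as_is", n)
  use <- fwd_m
  n_pair <- rowSums(fwd_m$both)
  if (revcomp_search && any(n_pair == 0)) {
    todo <- which(n_pair == 0)
    dna_rc <- Biostrings::reverseComplement(dna[todo])
    rc_m <- match_orientation(dna_rc)
    resolved <- rowSums(rc_m$both) > 0
    idx <- todo[resolved]
    if (length(idx) > 0) {
      orient[idx] <- "reverse_complement"
      dna[idx] <- dna_rc[resolved]
      if (has_qual) {
        quals[idx] <- as.character(Biostrings::reverse(
          Biostrings::BStringSet(quals[todo][resolved])))
      }
      use$head_end[idx, ] <- rc_m$head_end[resolved, , drop = FALSE]
      use$tail_start[idx, ] <- rc_m$tail_start[resolved, , drop = FALSE]
      use$both[idx, ] <- rc_m$both[resolved, , drop = FALSE]
      n_pair[idx] <- rowSums(rc_m$both[resolved, , drop = FALSE])
    }
    # remember where the reverse-complement pass found single ends, for
    # classifying the remaining failures
    fwd_found_rc <- rowSums(!is.na(rc_m$head_end)) > 0
    rev_found_rc <- rowSums(!is.na(rc_m$tail_start)) > 0
    fwd_extra <- rep(FALSE, n); rev_extra <- rep(FALSE, n)
    fwd_extra[todo] <- fwd_found_rc; rev_extra[todo] <- rev_found_rc
  } else {
    fwd_extra <- rep(FALSE, n); rev_extra <- rep(FALSE, n)
  }

  fwd_found <- rowSums(!is.na(use$head_end)) > 0 | fwd_extra
  rev_found <- rowSums(!is.na(use$tail_start)) > 0 | rev_extra

  status <- character(n)
  sample_id <- rep(NA_character_, n)
  trimmed <- rep(NA_character_, n)
  trimmed_q <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  seq_chr <- as.character(dna)

  for (i in seq_len(n)) {
    np <- n_pair[i]
    if (np == 0) {
      status[i] <- if (fwd_found[i] && rev_found[i]) "ambiguous"
                   else if (fwd_found[i]) "no_reverse" else "no_forward"
      next
    }
    if (np > 1) { status[i] <- "ambiguous"; next }
    j <- which(use$both[i, ])
    from <- use$head_end[i, j] + 1L
    to <- use$tail_start[i, j] - 1L
    tlen <- to - from + 1L
    if (tlen < min_len) { status[i] <- "too_short"; next }
    if (tlen > max_len) { status[i] <- "too_long"; next }
    status[i] <- "assigned"
    sample_id[i] <- specs$sample_id[j]
    trimmed[i] <- substr(seq_chr[i], from, to)
    if (has_qual) trimmed_q[i] <- substr(quals[i], from, to)
    orientation[i] <- orient[i]
  }

  # reads matched after reverse complementing are reported in their
  # original strand: the trimmed insert is flipped back, so trimming
  # commutes with reverse complementing the read
  flip <- which(status == "assigned" & orientation == "reverse_complement")
  if (length(flip) > 0) {
    trimmed[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(trimmed[flip])))
    if (has_qual) {
      trimmed_q[flip] <- as.character(Biostrings::reverse(
        Biostrings::BStringSet(trimmed_q[flip])))
    }
  }

  tibble::tibble(
    read_id = read_ids, status = status, sample_id = sample_id,
    trimmed_sequence = trimmed, trimmed_qualities = trimmed_q,
    orientation = orientation
  )
}

#' Demultiplex a single read
#'
#' Assigns one read to a sample by searching for a sample's forward barcode
#' in the head window and the reverse complement of its reverse barcode in
#' the tail window. When neither orientation pairs up as-is, the
#' reverse-complemented read is tried (nanopore reads are strand-mixed);
#' the orientation used is recorded. Assignment requires both ends to match
#' the same sample's pair; after trimming through the end of the forward
#' barcode and from the start of the reverse-barcode match, the inclusive
#' length window `[min_len, max_len]` is enforced.
#'
#' Statuses: `assigned`; `no_forward` / `no_reverse` when an end is missing
#' everywhere; `ambiguous` when more than one sample's pair matches, or
#' both ends match but never the same sample; `too_short` / `too_long`
#' when the trimmed insert falls outside the length window.
#'
#' @param sequence Read sequence (DNA string).
#' @param specs Barcode table (see [barcode_specs()]).
#' @param qualities Optional per-base quality string of equal length.
#' @param read_id Identifier carried into the result.
#' @param window,max_mismatches Barcode search settings (defaults 100 and
#'   0, i.e. exact matches within the first/last 100 bp).
#' @param min_len,max_len Inclusive trimmed-length bounds (defaults 1000
#'   and 2000 bp, the near-full-length 16S window).
#' @param revcomp_search Also try the reverse-complemented read
#'   (default TRUE).
#' @return A one-row tibble: `read_id`, `status`, `sample_id`,
#'   `trimmed_sequence`, `trimmed_qualities`, `orientation`.
#' @export
demux_read <- function(sequence, specs, qualities = NULL, read_id = "read",
                       window = 100, max_mismatches = 0,
                       min_len = 1000, max_len = 2000,
                       revcomp_search = TRUE) {
  if (!is.null(qualities) && nchar(qualities) != nchar(sequence)) {
    stop("`qualities` must have the same length as `sequence`", call. = FALSE)
  }
  .demux_set(read_id, sequence,
             if (is.null(qualities)) NULL else qualities,
             specs, window = window, max_mismatches = max_mismatches,
             min_len = min_len, max_len = max_len,
             revcomp_search = revcomp_search)
}

# Minimal strict 4-line FASTQ reader (gzip-transparent). Errors name the
# offending record so malformed files are diagnosable.
.read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4 + 1,
         call. = FALSE)
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(list(read_id = character(), sequence = character(),
                qualities = character()))
  }
  idx <- seq_len(n)
  hdr <- lines[(idx - 1) * 4 + 1]
  seqs <- lines[(idx - 1) * 4 + 2]
  plus <- lines[(idx - 1) * 4 + 3]
  quals <- lines[(idx - 1) * 4 + 4]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals) | nchar(seqs) == 0)
  if (length(bad) > 0) {
    stop("malformed FASTQ: record ", bad[1], call. = FALSE)
  }
  ids <- sub("^@", "", hdr)
  ids <- sub("[ \t].*$", "", ids)
  list(read_id = ids, sequence = seqs, qualities = quals)
}

.write_fastq <- function(read_id, sequence, qualities, path) {
  if (length(read_id) == 0) { file.create(path); return(invisible(path)) }
  qualities[is.na(qualities)] <- vapply(
    sequence[is.na(qualities)],
    function(s) strrep("I", nchar(s)), character(1))
  writeLines(as.vector(rbind(paste0("@", read_id), sequence, "+", qualities)),
             path)
  invisible(path)
}

#' Demultiplex a FASTQ file into per-sample files
#'
#' Runs [demux_read()]'s logic over every record of a FASTQ file (plain or
#' gzip), writes one FASTQ of trimmed reads per sample into `out_dir`, and
#' a `demux_summary.tsv` with one row per (sample, status) combination.
#' Every input read lands in exactly one status class, so the summary
#' counts sum to the input read count.
#'
#' @param reads_path Input FASTQ path.
#' @param specs Barcode table, or a path to a barcode TSV.
#' @param out_dir Output directory (created if missing).
#' @inheritParams demux_read
#' @return Invisibly, a list with `results` (per-read tibble), `summary`
#'   (per sample/status counts) and `files` (paths written).
#' @export
demux_fastq <- function(reads_path, specs, out_dir,
                        window = 100, max_mismatches = 0,
                        min_len = 1000, max_len = 2000,
                        revcomp_search = TRUE) {
  if (is.character(specs) && length(specs) == 1) {
    specs <- read_barcode_table(specs)
  } else {
    specs <- barcode_specs(specs)
  }
  fq <- .read_fastq(reads_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- .demux_set(fq$read_id, fq$sequence, fq$qualities, specs,
                    window = window, max_mismatches = max_mismatches,
                    min_len = min_len, max_len = max_len,
                    revcomp_search = revcomp_search)
  files <- character()
  for (sid in specs$sample_id) {
    sub <- res[!is.na(res$sample_id) & res$sample_id == sid &
                 res$status == "assigned", ]
    path <- file.path(out_dir, paste0(sid, ".fastq"))
    .write_fastq(sub$read_id, sub$trimmed_sequence, sub$trimmed_qualities, path)
    files <- c(files, path)
  }
  summary <- dplyr::count(res, .data$sample_id, .data$status, name = "n")
  sum_path <- file.path(out_dir, "demux_summary.tsv")
  readr::write_tsv(summary, sum_path, progress = FALSE)
  invisible(list(results = res, summary = summary,
                 files = c(files, sum_path)))
}
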