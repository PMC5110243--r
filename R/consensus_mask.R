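#' Two-sequence gapped alignment
#'
#' @param seq_a Reference sequence, gapped (`-`), alphabet ACGTN-.
#' @param seq_b Second sequence, same length and alphabet.
#' @return A `PairwiseAlignment`: list with `seq_a`, `seq_b`.
#' @details Validation: equal lengths, alphabet respected, no column gapped in
#'   both sequences. Errors report the offending column (1-based).
#' @export
pairwise_alignment <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stop(sprintf("alignment sequences differ in length (%d vs %d)", length(a), length(b)))
  }
  if (length(a) == 0) stop("empty alignment")
  ok <- c("A", "C", "G", "T", "N", "-")
  bad <- which(!(a %in% ok) | !(b %in% ok))
  if (length(bad)) stop(sprintf("invalid character at alignment column %d", bad[1]))
  allgap <- which(a == "-" & b == "-")
  if (length(allgap)) stop(sprintf("column %d is gapped in both sequences", allgap[1]))
  structure(list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = "")),
            class = "PairwiseAlignment")
}

#' Read/write a two-record aligned FASTA
#'
#' @param path FASTA file with exactly two equal-length gapped records.
#' @return `read_alignment_fasta()` returns a `PairwiseAlignment`.
#' @export
read_alignment_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2) stop("aligned FASTA must contain exactly 2 records")
  pairwise_alignment(as.character(recs[[1]]), as.character(recs[[2]]))
}

#' @rdname read_alignment_fasta
#' @param aln A `PairwiseAlignment`.
#' @param names Record names.
#' @export
write_alignment_fasta <- function(aln, path, names = c("seq_a", "seq_b")) {
  recs <- Biostrings::BStringSet(c(aln$seq_a, aln$seq_b))
  names(recs) <- names
  Biostrings::writeXStringSet(recs, path)
  invisible(path)
}

#' Mask discordant sites and indel neighbourhoods in a consensus sequence
#'
#' Produces the consensus of a two-species alignment in reference (`seq_a`)
#' coordinates with two masking rules: (i) columns where both bases are
#' present but differ are masked; (ii) each maximal gap run — in either
#' sequence — masks the reference positions it overlaps plus `flank`
#' reference bases on each side (for an insertion in `seq_b`, which has zero
#' reference width, the flank extends from the insertion point both ways).
#' Masked bases are replaced with `N`. Intervals are 0-based half-open in the
#' ungapped reference frame, clipped to bounds and merged.
#'
#' @param aln A `PairwiseAlignment` (reference first).
#' @param flank Reference bases masked on each side of a gap run (default 6).
#' @return A `MaskedConsensus`: list with `sequence` (ungapped reference
#'   length, over ACGTN), `intervals` (matrix with columns `start`, `end`)
#'   and `flank`.
#' @export
mask_consensus <- function(aln, flank = 6) {
  if (!inherits(aln, "PairwiseAlignment")) {
    aln <- pairwise_alignment(aln$seq_a, aln$seq_b)
  }
  a <- strsplit(aln$seq_a, "")[[1]]
  b <- strsplit(aln$seq_b, "")[[1]]
  is_ref <- a != "-"
  L <- sum(is_ref)
  # 0-based reference position of each alignment column (for a-gap columns:
  # the number of reference bases to the left = the insertion point)
  ref_before <- cumsum(is_ref)          # ref bases up to and including column
  ref_pos <- ref_before - 1L            # position of the column's ref base

  iv <- matrix(numeric(0), ncol = 2)
  # rule (i): discordant substitution columns
  snp <- which(is_ref & b != "-" & a != b)
  if (length(snp)) iv <- rbind(iv, cbind(ref_pos[snp], ref_pos[snp] + 1L))
  # rule (ii): maximal gap runs in either sequence
  for (seq_gaps in list(a == "-", b == "-")) {
    r <- rle(seq_gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      cols <- starts[j]:ends[j]
      covered <- ref_pos[cols][is_ref[cols]]
      if (length(covered)) {            # gap in seq_b: spans reference bases
        lo <- min(covered) - flank
        hi <- max(covered) + 1L + flank
      } else {                          # gap in seq_a: zero-width insertion
        pt <- ref_before[starts[j]]     # ref bases before the run
        lo <- pt - flank
        hi <- pt + flank
      }
      iv <- rbind(iv, c(lo, hi))
    }
  }
  iv[, 1] <- pmax(iv[, 1], 0)
  iv[, 2] <- pmin(iv[, 2], L)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  iv <- merge_intervals(iv)

  cons <- a[is_ref]
  for (k in seq_len(nrow(iv))) {
    cons[(iv[k, 1] + 1):iv[k, 2]] <- "N"
  }
  structure(list(
    sequence = paste(cons, collapse = ""),
    intervals = iv,
    flank = flank
  ), class = "MaskedConsensus")
}

# sort and merge 0-based half-open intervals
merge_intervals <- function(iv) {
  colnames(iv) <- c("start", "end")
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[k, 2])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.MaskedConsensus <- function(x, ...) {
  cat(sprintf("MaskedConsensus: %d bp, %d masked interval(s), %d masked base(s)\n",
              nchar(x$sequence), nrow(x$intervals),
              if (nrow(x$intervals)) sum(x$intervals[, 2] - x$intervals[, 1]) else 0L))
  invisible(x)
}

#' Write masked consensus outputs
#'
#' `write_masked_fasta()` writes the masked consensus as FASTA;
#' `write_mask_bed()` writes the mask intervals as BED (0-based half-open).
#'
#' @param mc A `MaskedConsensus`.
#' @param path Output file.
#' @param name Sequence/chromosome name.
#' @export
write_masked_fasta <- function(mc, path, name = "consensus") {
  recs <- Biostrings::DNAStringSet(mc$sequence)
  names(recs) <- name
  Biostrings::writeXStringSet(recs, path)
  invisible(path)
}

#' @rdname write_masked_fasta
#' @export
write_mask_bed <- function(mc, path, name = "consensus") {
  iv <- mc$intervals
  lines <- if (nrow(iv)) {
    sprintf("%s\t%d\t%d", name, as.integer(iv[, 1]), as.integer(iv[, 2]))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
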