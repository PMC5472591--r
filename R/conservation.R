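#' Per-column conservation profile of a protein multiple alignment
#'
#' Scores each alignment column by the fraction of non-gap rows carrying the
#' column's modal (most frequent) residue, the simplest auditable
#' conservation measure for identifying invariant hydrophobic-core
#' positions. Gaps are excluded from the denominator; an all-gap column
#' scores 0 and is flagged. Columns are mapped onto the numbering of a
#' reference row.
#'
#' @param msa Aligned sequences: a named character vector, a
#'   [Biostrings::AAStringSet], or the path of an aligned FASTA file.
#' @param reference_id Name of the reference row used for residue numbering.
#' @param ref_start Residue number of the reference row's first non-gap
#'   position (795 for the R3 fragment).
#' @return Data frame with one row per column: `column`,
#'   `reference_residue` (NA where the reference is gapped), `score` in
#'   \[0,1\], `modal_residue`, `is_all_gap`.
#' @export
conservation_profile <- function(msa, reference_id, ref_start = 795L) {
  seqs <- as_aligned_strings(msa)
  if (is.null(names(seqs)) || !nzchar(reference_id) ||
      !(reference_id %in% names(seqs))) {
    stop("reference '", reference_id, "' is not present in the alignment")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: row lengths differ (",
         paste(unique(widths), collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  gap <- mat == "-" | mat == "."
  ncol_aln <- ncol(mat)

  score <- numeric(ncol_aln)
  modal <- character(ncol_aln)
  all_gap <- logical(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    res <- mat[!gap[, j], j]
    if (length(res) == 0) {
      score[j] <- 0; modal[j] <- NA_character_; all_gap[j] <- TRUE
      next
    }
    tab <- table(res)
    # deterministic tie-break: alphabetically first among maxima
    best <- sort(names(tab)[tab == max(tab)])[1]
    modal[j] <- best
    score[j] <- as.numeric(tab[best]) / length(res)
  }

  ref_row <- mat[which(names(seqs) == reference_id)[1], ]
  ref_gap <- ref_row == "-" | ref_row == "."
  ref_num <- rep(NA_integer_, ncol_aln)
  ref_num[!ref_gap] <- ref_start + seq_len(sum(!ref_gap)) - 1L

  data.frame(column = seq_len(ncol_aln), reference_residue = ref_num,
             score = score, modal_residue = modal, is_all_gap = all_gap)
}

as_aligned_strings <- function(msa) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    msa <- Biostrings::readAAStringSet(msa)
  }
  if (methods::is(msa, "XStringSet")) {
    out <- as.character(msa)
    names(out) <- names(msa)
    return(out)
  }
  if (is.character(msa)) return(msa)
  stop("msa must be a named character vector, an AAStringSet, or a FASTA path")
}
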