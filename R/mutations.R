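#' The four destabilizing core substitutions of the R3 subdomain
#'
#' The hydrophobic-core isoleucine/leucine residues mutated to serine, in
#' the cumulative order used to build the 1S-4S constructs:
#' I805S, I812S, L890S, L897S.
#'
#' @return Data frame with columns `resno`, `from`, `to`.
#' @export
r3_core_substitutions <- function() {
  data.frame(resno = c(805L, 812L, 890L, 897L),
             from  = c("I", "I", "L", "L"),
             to    = c("S", "S", "S", "S"))
}

#' Build a mutation set
#'
#' Either a canonical label (`"WT"`, `"1S"`, `"2S"`, `"3S"`, `"4S"`, taking
#' the first n substitutions of [r3_core_substitutions()] cumulatively) or an
#' explicit substitution table.
#'
#' @param label Construct label.
#' @param substitutions Optional data frame with columns `resno`, `from`,
#'   `to` (1-letter codes); overrides the canonical sets, in which case
#'   `label` is free text.
#' @return A `mutation_set`: data frame of substitutions with a `label`
#'   attribute.
#' @export
#' @examples
#' mutation_set("4S")
mutation_set <- function(label = "WT", substitutions = NULL) {
  if (is.null(substitutions)) {
    canon <- r3_core_substitutions()
    n <- switch(label, WT = 0L, `1S` = 1L, `2S` = 2L, `3S` = 3L, `4S` = 4L,
                stop("unknown canonical label '", label,
                     "'; pass substitutions= for a custom set"))
    substitutions <- canon[seq_len(n), , drop = FALSE]
  } else {
    stopifnot(all(c("resno", "from", "to") %in% names(substitutions)))
    if (anyDuplicated(substitutions$resno)) {
      stop("substitution residue numbers must be unique")
    }
    if (grepl("^[1-4]S$", label)) {
      n <- as.integer(substr(label, 1, 1))
      canon <- r3_core_substitutions()[seq_len(n), , drop = FALSE]
      same <- nrow(substitutions) == n &&
        all(substitutions$resno == canon$resno &
              substitutions$from == canon$from & substitutions$to == canon$to)
      if (!same) stop("label '", label, "' requires exactly the first ", n,
                      " canonical substitutions I805S, I812S, L890S, L897S")
    }
  }
  structure(substitutions, label = label,
            class = c("mutation_set", "data.frame"))
}

#' Apply point mutations to a numbered sequence
#'
#' @param sequence Single 1-letter amino-acid string.
#' @param muts A [mutation_set()] or data frame with `resno`, `from`, `to`.
#' @param start Residue number of the first sequence position (author
#'   numbering; the R3 fragment starts at 795).
#' @return The mutated sequence string.
#' @export
#' @examples
#' apply_mutations("IL", mutation_set("custom",
#'   data.frame(resno = 805, from = "I", to = "S")), start = 805)
apply_mutations <- function(sequence, muts, start = 795L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (nrow(muts) == 0) return(sequence)
  if (anyDuplicated(muts$resno)) stop("substitution residue numbers must be unique")
  for (i in seq_len(nrow(muts))) {
    pos <- muts$resno[i] - start + 1L
    if (pos < 1 || pos > n) {
      stop("residue ", muts$resno[i], " is outside the sequence range ",
           start, "-", start + n - 1L)
    }
    if (chars[pos] != muts$from[i]) {
      stop("residue ", muts$resno[i], ": sequence has '", chars[pos],
           "' but substitution expects '", muts$from[i], "'")
    }
    chars[pos] <- muts$to[i]
  }
  paste(chars, collapse = "")
}

#' Synthetic reference sequence for the R3 fragment (residues 795-911)
#'
#' A synthetic stand-in sequence for the mouse talin-1 R3 fragment used for
#' testing the mutation builder. It is NOT the database sequence: only the
#' residue identities fixed by the experimental design are honoured --
#' the pull anchors (Q800, T804, V808, S815; Q888, G896, A900, A904) and the
#' four mutated core residues (I805, I812, L890, L897). All other positions
#' carry a generic amphipathic helix pattern.
#'
#' @return 117-residue 1-letter string, numbering 795-911.
#' @export
r3_synthetic_sequence <- function() {
  n <- 911L - 795L + 1L
  base <- strsplit("AEKLAQA", "")[[1]]          # generic helical heptad
  chars <- rep(base, length.out = n)
  fixed <- c(`800` = "Q", `804` = "T", `808` = "V", `815` = "S",
             `805` = "I", `812` = "I", `890` = "L", `897` = "L",
             `888` = "Q", `896` = "G", `900` = "A", `904` = "A")
  chars[as.integer(names(fixed)) - 795L + 1L] <- unname(fixed)
  paste(chars, collapse = "")
}
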