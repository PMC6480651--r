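#' The amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in the fixed column order of PSI-BLAST
#' checkpoint matrices (`ARNDCQEGHILKMFPSTWYV`). All profile matrices,
#' k-mer encodings and feature indices use this order; an unknown residue
#' `X` is handled by the profile readers, not part of the alphabet.
#'
#' @return Character vector of length 20, one residue per element.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' The 13 sub-nuclear compartment labels
#'
#' The fixed label vocabulary for sub-nuclear localization, ordered by the
#' number of experimental annotations in the development data (largest
#' first). Annotation readers match these labels case-insensitively; all
#' outputs use this canonical spelling and order.
#'
#' @return Character vector of the 13 compartment labels.
#' @export
subnuclear_compartments <- function() {
  c("chromatin", "nucleolus", "nuclear speckle", "PML body",
    "nuclear lamina", "nuclear matrix", "nuclear envelope", "Cajal body",
    "nuclear pore complex", "nucleoplasm", "kinetochore",
    "spindle apparatus", "perinucleolar")
}

#' Encode a k-mer as a base-20 feature index
#'
#' Feature indices encode k-mers base-20 with the first residue as the most
#' significant digit and digit values given by position in [aa_alphabet()].
#' Indices are 0-based doubles in `[0, 20^k)` so that k up to 7 stays exact
#' in double precision.
#'
#' @param kmer Character scalar (e.g. `"ARND"`) or character vector of
#'   single residues.
#' @return 0-based numeric index of the k-mer.
#' @seealso [kmer_string()] for the inverse.
#' @export
kmer_index <- function(kmer) {
  if (length(kmer) == 1L && nchar(kmer) > 1L) {
    kmer <- strsplit(kmer, "")[[1]]
  }
  digits <- match(kmer, aa_alphabet()) - 1
  if (anyNA(digits)) {
    stop("kmer contains residues outside the 20-letter alphabet: ",
         paste(kmer[is.na(digits)], collapse = ", "))
  }
  sum(digits * 20^(rev(seq_along(digits)) - 1))
}

#' Decode a base-20 feature index back to its k-mer string
#'
#' @param index 0-based numeric index (vectorised).
#' @param k k-mer length.
#' @return Character vector of k-mer strings.
#' @export
kmer_string <- function(index, k) {
  stopifnot(all(index >= 0), all(index < 20^k))
  vapply(index, function(ix) {
    out <- character(k)
    for (j in seq_len(k)) {
      out[k - j + 1] <- aa_alphabet()[ix %% 20 + 1]
      ix <- ix %/% 20
    }
    paste(out, collapse = "")
  }, character(1))
}
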