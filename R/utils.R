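#' @importFrom stats rgeom rpois runif median setNames complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# the 61 sense codons, used when a stop-free reading frame must be guaranteed
sense_codons <- function(exclude = character()) {
  all64 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all64, c(STOP_CODONS, exclude))
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to protein
#'
#' Translates from the first base, truncating any trailing partial codon.
#' Stop codons appear as `*`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of peptides.
#' @export
translate_dna <- function(x) {
  if (length(x) == 0) return(character())
  n <- nchar(x)
  trimmed <- substr(x, 1L, 3L * (n %/% 3L))
  out <- rep("", length(x))
  ok <- nchar(trimmed) >= 3L
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed[ok]),
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains non-ACGT characters: ",
         paste(head(unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), ""))), 5),
               collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n_seq, len) {
  vapply(rep(len, length.out = n_seq), function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

# random stop-free open reading frame of n_codons codons
random_orf <- function(n_codons, exclude_codons = character()) {
  pool <- sense_codons(exclude_codons)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# count of character mismatches between equal-length string vectors,
# via a position matrix (fast for many short anchors)
mismatch_matrix <- function(strings, anchor) {
  k <- nchar(anchor)
  stopifnot(all(nchar(strings) == k))
  m <- matrix(unlist(strsplit(strings, "")), ncol = k, byrow = TRUE)
  a <- strsplit(anchor, "")[[1]]
  rowSums(m != matrix(a, nrow = nrow(m), ncol = k, byrow = TRUE))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
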