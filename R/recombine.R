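#' Junction-diversification parameters
#'
#' Controls exonucleolytic trimming, non-templated (N) additions and
#' palindromic (P) additions at each coding join. Defaults give a net CDR3
#' gain of roughly 0-3 amino acids per junction: trimming is geometric with
#' success probability `trim_p` capped at `trim_max` nt per end, N-insert
#' lengths are Poisson(`n_lambda`) capped at `n_max`, and P nucleotides (up
#' to `p_nuc_max`, the palindrome of the terminal bases) are added only to
#' untrimmed ends.
#'
#' @param trim_p geometric parameter for per-end trimming.
#' @param trim_max maximum trim per end (nt).
#' @param n_lambda mean non-templated nucleotides per junction.
#' @param n_max maximum N nucleotides per junction.
#' @param p_nuc_max maximum palindromic nucleotides on an untrimmed end.
#' @return a list of class `junction_params`.
#' @export
junction_params <- function(trim_p = 0.25, trim_max = 10L, n_lambda = 3,
                            n_max = 15L, p_nuc_max = 2L) {
  stopifnot(trim_p > 0, trim_p <= 1, trim_max >= 0, n_lambda >= 0,
            n_max >= 0, p_nuc_max >= 0,
            trim_max <= 20L, n_max <= 20L, p_nuc_max <= 20L)
  structure(list(trim_p = trim_p, trim_max = as.integer(trim_max),
                 n_lambda = n_lambda, n_max = as.integer(n_max),
                 p_nuc_max = as.integer(p_nuc_max)),
            class = "junction_params")
}

# vector of random DNA strings with given lengths (single draw, then split)
rand_dna_vec <- function(lens) {
  out <- character(length(lens))
  tot <- sum(lens)
  if (tot == 0L) return(out)
  bases <- sample(DNA_BASES, tot, replace = TRUE)
  idx <- rep.int(seq_along(lens), lens)
  nz <- lens > 0L
  out[nz] <- vapply(split(bases, factor(idx, levels = which(nz))),
                    paste, character(1), collapse = "")
  out
}

# palindromic addition: revcomp of the terminal k bases of the retained end.
# side "three" appends after a 3' end; side "five" prepends before a 5' end.
p_addition <- function(seqs, k, side) {
  out <- character(length(seqs))
  nz <- k > 0L
  if (!any(nz)) return(out)
  n <- nchar(seqs[nz])
  term <- if (side == "three") substr(seqs[nz], n - k[nz] + 1L, n)
          else substr(seqs[nz], 1L, k[nz])
  out[nz] <- revcomp(term)
  out
}

draw_trim <- function(n, params, cap = NULL) {
  t <- pmin(rgeom(n, params$trim_p), params$trim_max)
  if (!is.null(cap)) t <- pmin(t, cap)
  as.integer(t)
}

draw_n_insert <- function(n, params) {
  rand_dna_vec(pmin(rpois(n, params$n_lambda), params$n_max))
}

draw_p_len <- function(n, trims, params) {
  k <- integer(n)
  un <- trims == 0L
  if (any(un) && params$p_nuc_max > 0L) {
    k[un] <- sample.int(params$p_nuc_max + 1L, sum(un), replace = TRUE) - 1L
  }
  k
}

# one junction insert between a left (3'-cut) and right (5'-cut) segment end
build_insert <- function(left_kept, left_trim, right_seq, right_trim, params) {
  n <- length(left_kept)
  pl <- p_addition(left_kept, draw_p_len(n, left_trim, params), "three")
  nn <- draw_n_insert(n, params)
  pr <- p_addition(right_seq, draw_p_len(n, right_trim, params), "five")
  paste0(pl, nn, pr)
}

#' D-to-J recombination (batch)
#'
#' Draws `n` independent DJ joins: uniform D and J choice, 3' D trimming,
#' 5' J trimming (capped so the conserved Trp codon survives), and a P/N
#' insert between the retained ends. The D reading frame imposed by the join
#' (`d_rf_dj`, Ichihara numbering, anchored on the J frame as read by the
#' D-mu transcript) is recorded.
#'
#' @param n number of joins.
#' @param locus a [germline_locus].
#' @param params a [junction_params].
#' @return data frame with one row per join.
#' @export
draw_dj_batch <- function(n, locus, params) {
  d <- locus$d; j <- locus$j
  d_idx <- sample.int(nrow(d), n, replace = TRUE)
  j_idx <- sample.int(nrow(j), n, replace = TRUE)
  ld <- nchar(d$seq)[d_idx]
  d_trim3 <- draw_trim(n, params, cap = ld - 1L)
  j_trim5 <- draw_trim(n, params, cap = j$trp_offset[j_idx])
  d_kept <- substr(d$seq[d_idx], 1L, ld - d_trim3)
  dj_insert <- build_insert(d_kept, d_trim3, j$seq[j_idx], j_trim5, params)
  lj <- nchar(j$seq)[j_idx]
  j_kept <- substr(j$seq[j_idx], j_trim5 + 1L, lj)
  phi <- (nchar(d_kept) + nchar(dj_insert) +
            j$frame_offset[j_idx] - j_trim5) %% 3L
  data.frame(
    d_idx = d_idx, j_idx = j_idx,
    d_name = d$name[d_idx], j_name = j$name[j_idx],
    d_trim3 = d_trim3, j_trim5 = j_trim5,
    dj_insert = dj_insert, d_kept = d_kept, j_kept = j_kept,
    d_rf_dj = as.integer(phi) + 1L,
    stringsAsFactors = FALSE
  )
}

#' @rdname draw_dj_batch
#' @param d,j single rows of `locus$d` / `locus$j`.
#' @export
recombine_dj <- function(d, j, params) {
  loc <- new_germline_locus(v = data.frame(), d = d, j = j, name = "tmp")
  row <- draw_dj_batch(1L, loc, params)
  row$d_idx <- row$j_idx <- NULL
  as.list(row)
}

# --- allele evaluation -----------------------------------------------------
# Given assembled parts, computes sequence, frame shift, stop content, CDR3
# and D reading frame. The reading frame is anchored at position 0 of the V
# part; codon starts are read positions = 0 mod 3. The J frame is carried by
# frame_offset/trp_offset of the germline J; the stop scan runs through the
# conserved Trp codon for in-frame alleles and over the whole read-through
# for frame-shifted ones.
evaluate_alleles <- function(v_part, cys_offset, vd_insert, d_kept, d_trim5,
                             dj_insert, j_kept, j_idx, j_trim5, locus) {
  j <- locus$j
  seq <- paste0(v_part, vd_insert, d_kept, dj_insert, j_kept)
  z_d <- nchar(v_part) + nchar(vd_insert)                    # 0-based D start
  z_j <- z_d + nchar(d_kept) + nchar(dj_insert)              # 0-based J start
  frame_offset <- j$frame_offset[j_idx]
  trp_offset <- j$trp_offset[j_idx]
  frame_shift <- as.integer((z_j + frame_offset - j_trim5) %% 3L)
  wz <- z_j + trp_offset - j_trim5                           # 0-based W codon start
  aa <- translate_dna(seq)
  stop_at <- regexpr("*", aa, fixed = TRUE)                  # 1-based codon index
  w_codon <- wz %/% 3L + 1L
  has_stop <- stop_at > 0L & (frame_shift != 0L | stop_at <= w_codon)
  productive <- frame_shift == 0L & !has_stop
  d_rf <- as.integer((d_trim5 - z_d) %% 3L) + 1L
  # CDR3: residues strictly between the V-terminal Cys (96) and the J Trp
  cys_idx <- cys_offset %/% 3L + 1L
  cys_codon <- substr(v_part, cys_offset + 1L, cys_offset + 3L)
  cdr3_resolved <- frame_shift == 0L & !is.na(cys_offset) &
    cys_codon %in% c("TGT", "TGC") & (cys_offset + 3L) <= nchar(v_part)
  cdr3_aa <- ifelse(cdr3_resolved, substr(aa, cys_idx + 1L, w_codon - 1L),
                    NA_character_)
  junction_nt <- ifelse(!is.na(cys_offset),
                        substr(seq, cys_offset + 1L, wz + 3L), NA_character_)
  data.frame(seq = seq, frame_shift = frame_shift, has_stop = has_stop,
             productive = productive, d_rf = d_rf, cdr3_aa = cdr3_aa,
             cdr3_resolved = cdr3_resolved, junction_nt = junction_nt,
             stringsAsFactors = FALSE)
}

#' V-to-DJ recombination (batch)
#'
#' Joins chosen V segments onto DJ intermediates: 3' V trimming, a P/N
#' insert, 5' D trimming, then full-frame evaluation (frame shift relative
#' to the V reading frame, stop-codon scan through the conserved J Trp,
#' productivity, Ichihara D reading frame and CDR3 extraction).
#'
#' @param locus a [germline_locus].
#' @param v_idx integer vector of V row indices, one per DJ row.
#' @param dj data frame from [draw_dj_batch()].
#' @param params a [junction_params].
#' @return data frame with one row per allele.
#' @export
draw_vdj_batch <- function(locus, v_idx, dj, params) {
  v <- locus$v
  n <- nrow(dj)
  stopifnot(length(v_idx) == n)
  lv <- nchar(v$coding_seq)[v_idx]
  v_trim <- draw_trim(n, params)
  v_part <- substr(v$coding_seq[v_idx], 1L, lv - v_trim)
  ld_kept0 <- nchar(dj$d_kept)
  d_trim5 <- draw_trim(n, params, cap = ld_kept0 - 1L)
  vd_insert <- build_insert(v_part, v_trim, dj$d_kept, d_trim5, params)
  d_kept <- substr(dj$d_kept, d_trim5 + 1L, ld_kept0)
  ev <- evaluate_alleles(v_part, v$cys_offset[v_idx], vd_insert, d_kept,
                         d_trim5, dj$dj_insert, dj$j_kept, dj$j_idx,
                         dj$j_trim5, locus)
  cbind(
    data.frame(v_idx = v_idx, v_name = v$name[v_idx],
               d_name = dj$d_name, j_name = dj$j_name,
               v_trim = v_trim, v_part = v_part, vd_insert = vd_insert,
               d_trim5 = d_trim5, d_trim3 = dj$d_trim3, d_kept = d_kept,
               dj_insert = dj$dj_insert, j_kept = dj$j_kept,
               j_idx = dj$j_idx, j_trim5 = dj$j_trim5,
               d_rf_dj = dj$d_rf_dj, stringsAsFactors = FALSE),
    ev
  )
}

#' @rdname draw_vdj_batch
#' @param v a single row of `locus$v`.
#' @param dj1 a DJ intermediate from [recombine_dj()].
#' @export
recombine_vdj <- function(v, dj1, params, locus) {
  dj <- as.data.frame(dj1[c("d_name", "j_name", "d_trim3", "j_trim5",
                            "dj_insert", "d_kept", "j_kept", "d_rf_dj")],
                      stringsAsFactors = FALSE)
  dj$j_idx <- match(dj$j_name, locus$j$name)
  v_idx <- match(v$name, locus$v$name)
  out <- draw_vdj_batch(locus, v_idx, dj, params)
  as.list(out)
}
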