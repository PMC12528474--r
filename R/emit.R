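# --- read-level emitters ---------------------------------------------------
# Both library types are emitted with the same pairing convention: read 1 is
# sequenced from the reverse strand (the capture/primer side in the real
# chemistry), read 2 from the forward strand, so that merging read 1 with
# the reverse complement of read 2 and reverse-complementing the assembly
# restores the fragment in V->J (or FR3->junction) orientation.

apply_subst_errors <- function(seqs, err_rate) {
  if (err_rate <= 0) return(seqs)
  n <- nchar(seqs)
  k <- stats::rbinom(length(seqs), n, err_rate)
  hit <- which(k > 0L)
  for (i in hit) {
    pos <- sample.int(n[i], k[i])
    for (p in pos) {
      orig <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, orig), 1L)
    }
  }
  seqs
}

random_quals <- function(lens) {
  # Phred 30-40, Sanger offset
  vapply(lens, function(l) {
    intToUtf8(sample(63:73, l, replace = TRUE))
  }, character(1))
}

make_read_pair <- function(fragments, read_len, err_rate) {
  rc <- revcomp(fragments)
  r1 <- substr(rc, 1L, read_len)
  r2 <- substr(fragments, 1L, read_len)
  list(r1 = apply_subst_errors(r1, err_rate),
       r2 = apply_subst_errors(r2, err_rate))
}

reads_df <- function(ids, seqs, umi) {
  data.frame(id = ids, seq = seqs, qual = random_quals(nchar(seqs)),
             umi = umi, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param path output path (`.gz` accepted).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ into a data frame, parsing UMI header tokens
#'
#' @param path FASTQ path.
#' @return data frame with `id`, `seq`, `qual`, `umi` (`NA` when the header
#'   carries no `UMI:` token).
#' @export
read_fastq <- function(path) {
  # the reader attaches quality metadata columns that the quality-scaled
  # constructor then drops again, with a cosmetic warning
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ids <- names(x)
  umi <- ifelse(grepl("UMI:([ACGT]+)", ids),
                sub(".*UMI:([ACGT]+).*", "\\1", ids), NA_character_)
  data.frame(id = ids, seq = as.character(x),
             qual = as.character(Biostrings::quality(x)), umi = umi,
             stringsAsFactors = FALSE)
}

#' Emit a VDJseq-like paired-end library from a simulated population
#'
#' Each allele of the selected stages is sampled with probability
#' `sampling_rate` (molecular sampling; the real assay captures 5-10% of
#' molecules). A sampled allele yields one molecule carrying a random
#' 12-nt UMI, amplified into `1 + Poisson(dup_lambda)` PCR duplicates that
#' share the UMI, each read as a pair with uniform substitution errors.
#'
#' @param pop a `bcell_population`.
#' @param sampling_rate molecular sampling fraction in (0, 1].
#' @param read_len read length (nt).
#' @param err_rate per-base substitution probability.
#' @param dup_lambda mean extra PCR duplicates per molecule.
#' @param stages stages to include (default: the pro-B compartment).
#' @param seed optional seed.
#' @return list with `r1`, `r2` (read data frames) and `truth` (the
#'   ground-truth molecule table).
#' @export
emit_vdjseq_reads <- function(pop, sampling_rate, read_len = 150L,
                              err_rate = 0.001, dup_lambda = 0.6,
                              stages = c("pro-B", "arrested"), seed = NULL) {
  stopifnot(sampling_rate > 0, sampling_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  al <- pop$alleles
  al <- al[al$stage %in% stages, , drop = FALSE]
  take <- runif(nrow(al)) < sampling_rate
  mol <- al[take, , drop = FALSE]
  n <- nrow(mol)
  truth <- data.frame(
    molecule_id = sprintf("mol%06d", seq_len(n)),
    cell_id = mol$cell_id, allele_no = mol$allele_no, status = mol$status,
    v_call = mol$v_name, d_call = mol$d_name, j_call = mol$j_name,
    seq = mol$seq, length = nchar(mol$seq), stage = mol$stage,
    productive = mol$productive, frame_shift = mol$frame_shift,
    has_stop = mol$has_stop, d_rf = mol$d_rf, d_rf_dj = mol$d_rf_dj,
    cdr3_aa = mol$cdr3_aa,
    umi = rand_dna_vec(rep(12L, n)),
    stringsAsFactors = FALSE
  )
  dup <- 1L + rpois(n, dup_lambda)
  idx <- rep.int(seq_len(n), dup)
  ids <- sprintf("%s_dup%d UMI:%s", truth$molecule_id[idx],
                 sequence(dup), truth$umi[idx])
  pr <- make_read_pair(truth$seq[idx], read_len, err_rate)
  list(r1 = reads_df(ids, pr$r1, truth$umi[idx]),
       r2 = reads_df(ids, pr$r2, truth$umi[idx]), truth = truth)
}

# germline run-off molecule for one V: FR3 anchor through the conventional
# RSS into the 3' intergenic region
germline_runoff <- function(locus, v_idx) {
  v <- locus$v
  fr3_end <- ifelse(is.na(v$crss_offset[v_idx]), v$cys_offset[v_idx] - 3L,
                    v$crss_offset[v_idx])
  paste0(substr(v$coding_seq[v_idx], fr3_end - 60L + 1L,
                nchar(v$coding_seq[v_idx])),
         v$rss_heptamer[v_idx], v$intergenic_3p[v_idx])
}

# circle run-off molecule: FR3 of the recipient through the signal joint
# into the donor intergenic sequence (circle_seq starts at recipient base 1)
circle_runoff <- function(circles, locus) {
  v <- locus$v
  vi <- match(circles$recipient_v, v$name)
  fr3_start <- v$crss_offset[vi] - 60L # 0-based
  substr(circles$circle_seq, fr3_start + 1L, nchar(circles$circle_seq))
}

#' Emit an RCseq-like paired-end library
#'
#' Produces (a) `germline_background` molecules read from germline V
#' segments in the primer panel through their conventional RSS into the 3'
#' intergenic region - the dominant class in the real assay - and (b)
#' `per_circle_molecules` independent molecules traversing each excision
#' circle whose recipient V is in the panel (FR3, V 3' end, cryptic
#' heptamer, insertion, donor heptamer, donor intergenic). Circles with
#' recipients outside the panel yield no reads.
#'
#' @param circles circle table from [simulate_cohort()].
#' @param locus a [germline_locus].
#' @param primer_panel character vector of V names (subset of the locus).
#' @param germline_background number of background molecules.
#' @param read_len,err_rate as in [emit_vdjseq_reads()].
#' @param per_circle_molecules molecules per planted circle.
#' @param seed optional seed.
#' @return list with `r1`, `r2`, `truth`.
#' @export
emit_rcseq_reads <- function(circles, locus, primer_panel,
                             germline_background = 1000L, read_len = 150L,
                             err_rate = 0.001, per_circle_molecules = 3L,
                             seed = NULL) {
  if (length(primer_panel) == 0L) stop("primer_panel is empty", call. = FALSE)
  if (!all(primer_panel %in% locus$v$name)) {
    stop("primer_panel contains V names absent from the locus", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  panel_idx <- match(primer_panel, locus$v$name)
  bg_v <- sample(panel_idx, germline_background, replace = TRUE)
  bg <- data.frame(
    source = "germline", v_name = locus$v$name[bg_v],
    circle_id = NA_integer_, seq = germline_runoff(locus, bg_v),
    stringsAsFactors = FALSE
  )
  cc <- circles[circles$recipient_v %in% primer_panel, , drop = FALSE]
  circ <- NULL
  if (nrow(cc) > 0L) {
    idx <- rep.int(seq_len(nrow(cc)), per_circle_molecules)
    circ <- data.frame(
      source = "circle", v_name = cc$recipient_v[idx],
      circle_id = which(circles$recipient_v %in% primer_panel)[idx],
      seq = circle_runoff(cc, locus)[idx], stringsAsFactors = FALSE
    )
  }
  truth <- rbind(bg, circ)
  n <- nrow(truth)
  truth$molecule_id <- sprintf("rc%06d", seq_len(n))
  truth$umi <- rand_dna_vec(rep(12L, n))
  truth$length <- nchar(truth$seq)
  ids <- sprintf("%s UMI:%s", truth$molecule_id, truth$umi)
  pr <- make_read_pair(truth$seq, read_len, err_rate)
  list(r1 = reads_df(ids, pr$r1, truth$umi),
       r2 = reads_df(ids, pr$r2, truth$umi), truth = truth)
}
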