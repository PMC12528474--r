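#' Germline heavy-chain locus model
#'
#' A `germline_locus` is a list with three data frames (`v`, `d`, `j`) plus a
#' `name`. V segments are held in locus order: `locus_rank` 1 is the most
#' D-proximal gene, higher ranks are more distal. Coordinates are 0-based and
#' half-open throughout the package; exported tables convert where a standard
#' dictates otherwise.
#'
#' V segment columns:
#' \describe{
#'   \item{name, locus_rank, family, clan}{identity and locus position.}
#'   \item{coding_seq}{germline coding sequence; the reading frame starts at
#'     position 0 and the sequence ends at the edge abutting the conventional
#'     RSS heptamer.}
#'   \item{fr3_seq}{60 nt of framework-3 ending just before the cryptic
#'     heptamer region; the anchor used by the excision-circle search.}
#'   \item{rss_heptamer}{conventional RSS heptamer (CACAGTG with a degenerate
#'     fifth position in a minority of genes).}
#'   \item{crss_offset}{0-based start of the 3'-most exact TACTGTG within the
#'     last 30 nt of `coding_seq`, or `NA` when the gene has no cryptic RSS.}
#'   \item{intergenic_3p}{sequence immediately 3' of the conventional RSS,
#'     used as the donor-side anchor of the excision-circle search.}
#'   \item{ends_ta}{`TRUE` when the coding sequence ends with TA, the first
#'     two bases of a potential stop codon completed by the junction.}
#'   \item{cys_offset}{0-based, in-frame start of the terminal Cys codon
#'     (CDR3 residue 96).}
#' }
#'
#' @name germline_locus
NULL

new_germline_locus <- function(v, d, j, name) {
  structure(list(v = v, d = d, j = j, name = name), class = "germline_locus")
}

#' @export
print.germline_locus <- function(x, ...) {
  cat(sprintf("germline_locus '%s': %d V, %d D, %d J\n",
              x$name, nrow(x$v), nrow(x$d), nrow(x$j)))
  cat(sprintf("  V with cryptic RSS: %d; V ending TA: %d\n",
              sum(!is.na(x$v$crss_offset)), sum(x$v$ends_ta)))
  invisible(x)
}

# fixed segment tails that realise the CDR3 landmarks:
# ...Tyr Tyr Cys Ala Arg + 2 nt of the next codon. The cryptic-RSS variant
# spells TACTGTG across the Tyr/Cys codons, as in real V genes.
V_TAIL_CRSS <- "TATTACTGTGCAAGA" # Y Y C A R, contains TACTGTG at offset 3
V_TAIL_PLAIN <- "TATTATTGCGCAAGA" # Y Y C A R, no cryptic heptamer

#' Locate a cryptic RSS heptamer near the 3' end of a V segment
#'
#' Finds the 3'-most exact `TACTGTG` whose start lies within the terminal
#' `window` nucleotides of the sequence.
#'
#' @param v_seq DNA string (length >= 30).
#' @param window size of the 3'-terminal search window in nt (default 30).
#' @return 0-based start offset of the motif, or `NA_integer_` when absent.
#' @export
detect_crss <- function(v_seq, window = 30L) {
  check_dna(v_seq, "v_seq")
  vapply(v_seq, function(s) {
    n <- nchar(s)
    if (n < 30L) stop("v_seq must be at least 30 nt", call. = FALSE)
    hits <- gregexpr("TACTGTG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NA_integer_)
    hits0 <- hits - 1L # to 0-based
    hits0 <- hits0[hits0 >= n - window]
    if (length(hits0) == 0L) return(NA_integer_)
    max(hits0)
  }, integer(1), USE.NAMES = FALSE)
}

#' Does a V segment end with TA?
#'
#' V segments ending in TA contribute the first two bases of a potential stop
#' codon whose third base is supplied by the V-D junction.
#'
#' @param v_seq DNA string (length >= 2).
#' @return logical vector.
#' @export
ends_with_ta <- function(v_seq) {
  check_dna(v_seq, "v_seq")
  if (any(nchar(v_seq) < 2L)) stop("v_seq must be at least 2 nt", call. = FALSE)
  substr(v_seq, nchar(v_seq) - 1L, nchar(v_seq)) == "TA"
}

#' Clan lookup for a V gene
#'
#' Clans are evolutionary groupings of V genes (clans 1-3). Assignments come
#' from a configuration table rather than being hard-coded; a label absent
#' from the table resolves to `NA` ("unknown"), never an error.
#'
#' @param v_name V gene (or family) label.
#' @param clan_table named integer vector mapping labels to clans 1-3.
#' @return integer clan, or `NA_integer_` when unknown.
#' @export
clan_of <- function(v_name, clan_table) {
  out <- unname(clan_table[v_name])
  as.integer(out)
}

#' Default family-to-clan table
#'
#' Read from the packaged configuration file so that users can swap in their
#' own assignments.
#'
#' @param path optional path to a two-column tab-separated file (name, clan).
#' @return named integer vector.
#' @export
default_clan_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "clan_table.tsv", package = "ighrepsel")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.integer(tab$clan), tab$name)
}

#' Build a deterministic toy heavy-chain locus
#'
#' Generates a small germline locus whose segments satisfy all structural
#' invariants needed downstream: V genes end in the Tyr-Tyr-Cys-Ala-Arg
#' framework-3 motif (with or without the TACTGTG cryptic heptamer spelled
#' across the Tyr/Cys codons), D segments are forward-orientation only with
#' the canonical reading-frame properties (an ATG in RF2, stops permitted
#' only in RF3), and J segments carry a conserved in-frame Trp codon. J genes
#' alternate between long (4 CDR3 codons) and short (2 CDR3 codons)
#' contributions, so that with four J the second and third are two amino
#' acids shorter, as in the mouse locus.
#'
#' @param n_v,n_d,n_j segment counts (n_v >= 2, n_d >= 1, n_j >= 2).
#' @param crss_fraction fraction of V genes carrying a cryptic RSS.
#' @param seed integer seed; the same arguments and seed give a
#'   byte-identical locus.
#' @param ta_fraction fraction of V genes ending in TA.
#' @param clan_table optional named vector mapping families to clans;
#'   defaults to the packaged table.
#' @param name locus label.
#' @return a [germline_locus] object.
#' @export
build_toy_locus <- function(n_v, n_d, n_j, crss_fraction = 0.75, seed = 1L,
                            ta_fraction = 0.1, clan_table = NULL,
                            name = "toyIgH") {
  if (n_v < 2L || n_d < 1L || n_j < 2L) {
    stop("need n_v >= 2, n_d >= 1, n_j >= 2", call. = FALSE)
  }
  if (crss_fraction < 0 || crss_fraction > 1) {
    stop("crss_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(clan_table)) clan_table <- default_clan_table()

  ## --- V segments -----------------------------------------------------
  # proximal genes drawn from the families that dominate the D-proximal end
  fam_cycle <- c("VH5", "VH2", "VH3", "VH1", "VH6", "VH14")
  family <- rep(fam_cycle, length.out = n_v)
  n_crss <- round(n_v * crss_fraction)
  has_crss <- rep(FALSE, n_v)
  has_crss[sample.int(n_v, n_crss)] <- TRUE
  n_ta <- round(n_v * ta_fraction)
  is_ta <- rep(FALSE, n_v)
  if (n_ta > 0) is_ta[sample.int(n_v, n_ta)] <- TRUE

  v_core <- character(n_v)
  for (i in seq_len(n_v)) {
    repeat {
      core <- random_orf(sample(28:34, 1))
      # the core must not fake a cryptic heptamer or an RSS-like junction
      if (!grepl("TACTGTG", core, fixed = TRUE) &&
          !grepl("CACA[GAT]TG", core)) break
    }
    v_core[i] <- core
  }
  tail15 <- ifelse(has_crss, V_TAIL_CRSS, V_TAIL_PLAIN)
  tail2 <- ifelse(is_ta, "TA", "GG")
  coding <- paste0(v_core, tail15, tail2)
  crss_offset <- ifelse(has_crss, nchar(v_core) + 3L, NA_integer_)
  cys_offset <- nchar(v_core) + 6L # TGT/TGC codon inside the fixed tail
  # FR3 anchor: 60 nt ending just before the (actual or virtual) heptamer
  fr3_end <- nchar(v_core) + 3L # 0-based end (exclusive) of FR3 anchor
  fr3_seq <- substr(coding, fr3_end - 60L + 1L, fr3_end)
  rss5 <- sample(c("G", "A", "T"), n_v, replace = TRUE, prob = c(0.8, 0.1, 0.1))
  rss_heptamer <- paste0("CACA", rss5, "TG")
  intergenic <- character(n_v)
  for (i in seq_len(n_v)) {
    repeat {
      s <- random_dna(1, 80)
      if (!grepl("TACTGTG", s, fixed = TRUE) && !grepl("CACA[GAT]TG", s)) break
    }
    intergenic[i] <- s
  }
  v <- data.frame(
    name = sprintf("%s-%d", family, seq_len(n_v)),
    locus_rank = seq_len(n_v),
    family = family,
    clan = clan_of(family, clan_table),
    coding_seq = coding,
    fr3_seq = fr3_seq,
    rss_heptamer = rss_heptamer,
    crss_offset = as.integer(crss_offset),
    intergenic_3p = intergenic,
    ends_ta = is_ta,
    cys_offset = as.integer(cys_offset),
    stringsAsFactors = FALSE
  )

  ## --- D segments -----------------------------------------------------
  # first two D realise the canonical frame properties explicitly
  d_seqs <- c("GGTTACTATGGCTAC", # RF1 GYYGY, RF2 VTMA (ATG), RF3 no stop
              "GCTACTGACTAC")    # RF3 contains TGA
  if (n_d > 2L) {
    for (i in 3:n_d) {
      repeat {
        s <- random_dna(1, sample(12:15, 1))
        # forward orientation only; no stop may appear in RF1 or RF2
        p1 <- translate_dna(s)
        p2 <- translate_dna(substr(s, 2, nchar(s)))
        if (!grepl("*", p1, fixed = TRUE) && !grepl("*", p2, fixed = TRUE) &&
            !grepl("TACTGTG", s, fixed = TRUE) && !grepl("CACA[GAT]TG", s)) break
      }
      d_seqs <- c(d_seqs, s)
    }
  }
  d_seqs <- d_seqs[seq_len(n_d)]
  d <- data.frame(name = sprintf("DH%d", seq_len(n_d)), seq = d_seqs,
                  stringsAsFactors = FALSE)
  rfp <- d_rf_peptides(d_seqs)
  d$rf1_peptide <- rfp[, 1]; d$rf2_peptide <- rfp[, 2]; d$rf3_peptide <- rfp[, 3]
  d$rf1_has_stop <- grepl("*", d$rf1_peptide, fixed = TRUE)
  d$rf2_has_stop <- grepl("*", d$rf2_peptide, fixed = TRUE)
  d$rf3_has_stop <- grepl("*", d$rf3_peptide, fixed = TRUE)
  d$rf2_has_atg <- vapply(d_seqs, function(s) {
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    any(hits != -1L & (hits - 1L) %% 3L == 1L)
  }, logical(1), USE.NAMES = FALSE)

  ## --- J segments -----------------------------------------------------
  # long/short alternation: with 4 J, JH2/JH3 contribute two fewer codons
  contrib <- rep(c(4L, 2L, 2L, 4L), length.out = n_j)
  overhang <- rep(c(0L, 1L, 2L, 0L), length.out = n_j)
  j_seq <- character(n_j)
  for (i in seq_len(n_j)) {
    prefix <- random_orf(contrib[i], exclude_codons = "TGG")
    fr4 <- random_orf(10, exclude_codons = "TGG")
    j_seq[i] <- paste0(substr(random_dna(1, 2), 1, overhang[i]), prefix, "TGG", fr4)
  }
  j <- data.frame(
    name = sprintf("JH%d", seq_len(n_j)),
    seq = j_seq,
    frame_offset = overhang,
    cdr3_contribution_aa = contrib,
    trp_offset = overhang + 3L * contrib,
    stringsAsFactors = FALSE
  )

  loc <- new_germline_locus(v, d, j, name)
  validate_locus(loc)
  loc
}

# three reading-frame translations of D segments (Ichihara numbering:
# RF i starts at 0-based offset i-1)
d_rf_peptides <- function(d_seqs) {
  cbind(translate_dna(d_seqs),
        translate_dna(substr(d_seqs, 2, nchar(d_seqs))),
        translate_dna(substr(d_seqs, 3, nchar(d_seqs))))
}

validate_locus <- function(locus) {
  v <- locus$v
  stopifnot(nrow(v) >= 2, nrow(locus$d) >= 1, nrow(locus$j) >= 2)
  stopifnot(!anyDuplicated(v$locus_rank), all(nchar(v$coding_seq) >= 90))
  has <- !is.na(v$crss_offset)
  if (any(has)) {
    mot <- substr(v$coding_seq[has], v$crss_offset[has] + 1L, v$crss_offset[has] + 7L)
    stopifnot(all(mot == "TACTGTG"))
    stopifnot(all(v$crss_offset[has] >= nchar(v$coding_seq[has]) - 30L))
  }
  stopifnot(identical(v$ends_ta, unname(ends_with_ta(v$coding_seq))))
  cys <- substr(v$coding_seq, v$cys_offset + 1L, v$cys_offset + 3L)
  stopifnot(all(cys %in% c("TGT", "TGC")), all(v$cys_offset %% 3L == 0L))
  j <- locus$j
  w <- substr(j$seq, j$trp_offset + 1L, j$trp_offset + 3L)
  stopifnot(all(w == "TGG"), all((j$trp_offset - j$frame_offset) %% 3L == 0L))
  invisible(locus)
}

#' Write a locus to FASTA plus a metadata sidecar
#'
#' One FASTA record per segment with ids `V|name`, `VI|name` (3' intergenic),
#' `D|name`, `J|name`, and a tab-separated metadata table keyed by name.
#'
#' @param locus a [germline_locus].
#' @param fasta_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_locus <- function(locus, fasta_path, meta_path) {
  v <- locus$v; d <- locus$d; j <- locus$j
  seqs <- c(setNames(v$coding_seq, paste0("V|", v$name)),
            setNames(v$intergenic_3p, paste0("VI|", v$name)),
            setNames(d$seq, paste0("D|", d$name)),
            setNames(j$seq, paste0("J|", j$name)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  meta <- rbind(
    data.frame(name = v$name, type = "V", locus_rank = v$locus_rank,
               family = v$family, clan = v$clan, crss_offset = v$crss_offset,
               rss_heptamer = v$rss_heptamer, ends_ta = v$ends_ta,
               cys_offset = v$cys_offset, frame_offset = NA_integer_,
               trp_offset = NA_integer_, cdr3_contribution_aa = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(name = d$name, type = "D", locus_rank = NA_integer_,
               family = NA_character_, clan = NA_integer_,
               crss_offset = NA_integer_, rss_heptamer = NA_character_,
               ends_ta = NA, cys_offset = NA_integer_,
               frame_offset = NA_integer_, trp_offset = NA_integer_,
               cdr3_contribution_aa = NA_integer_, stringsAsFactors = FALSE),
    data.frame(name = j$name, type = "J", locus_rank = NA_integer_,
               family = NA_character_, clan = NA_integer_,
               crss_offset = NA_integer_, rss_heptamer = NA_character_,
               ends_ta = NA, cys_offset = NA_integer_,
               frame_offset = j$frame_offset, trp_offset = j$trp_offset,
               cdr3_contribution_aa = j$cdr3_contribution_aa,
               stringsAsFactors = FALSE)
  )
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, meta = meta_path))
}

#' Read a locus written by [write_locus()]
#'
#' @param fasta_path,meta_path paths produced by [write_locus()].
#' @param name locus label.
#' @return a [germline_locus].
#' @export
read_locus <- function(fasta_path, meta_path, name = "locus") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  seq_chr <- as.character(seqs)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  typ <- sub("\\|.*", "", ids)
  nm <- sub("^[^|]*\\|", "", ids)

  vm <- meta[meta$type == "V", ]
  vm <- vm[order(vm$locus_rank), ]
  coding <- seq_chr[typ == "V"][match(vm$name, nm[typ == "V"])]
  intergenic <- seq_chr[typ == "VI"][match(vm$name, nm[typ == "VI"])]
  fr3_end <- ifelse(is.na(vm$crss_offset), vm$cys_offset - 3L, vm$crss_offset)
  v <- data.frame(
    name = vm$name, locus_rank = vm$locus_rank, family = vm$family,
    clan = vm$clan, coding_seq = unname(coding),
    fr3_seq = substr(coding, fr3_end - 60L + 1L, fr3_end),
    rss_heptamer = vm$rss_heptamer,
    crss_offset = as.integer(vm$crss_offset),
    intergenic_3p = unname(intergenic), ends_ta = vm$ends_ta,
    cys_offset = as.integer(vm$cys_offset), stringsAsFactors = FALSE,
    row.names = NULL
  )
  v$fr3_seq <- unname(v$fr3_seq)
  dm <- meta[meta$type == "D", ]
  d_seq <- seq_chr[typ == "D"][match(dm$name, nm[typ == "D"])]
  d <- data.frame(name = dm$name, seq = unname(d_seq), stringsAsFactors = FALSE)
  rfp <- d_rf_peptides(d$seq)
  d$rf1_peptide <- rfp[, 1]; d$rf2_peptide <- rfp[, 2]; d$rf3_peptide <- rfp[, 3]
  d$rf1_has_stop <- grepl("*", d$rf1_peptide, fixed = TRUE)
  d$rf2_has_stop <- grepl("*", d$rf2_peptide, fixed = TRUE)
  d$rf3_has_stop <- grepl("*", d$rf3_peptide, fixed = TRUE)
  d$rf2_has_atg <- vapply(d$seq, function(s) {
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    any(hits != -1L & (hits - 1L) %% 3L == 1L)
  }, logical(1), USE.NAMES = FALSE)
  jm <- meta[meta$type == "J", ]
  j_seq <- seq_chr[typ == "J"][match(jm$name, nm[typ == "J"])]
  j <- data.frame(name = jm$name, seq = unname(j_seq),
                  frame_offset = as.integer(jm$frame_offset),
                  cdr3_contribution_aa = as.integer(jm$cdr3_contribution_aa),
                  trp_offset = as.integer(jm$trp_offset),
                  stringsAsFactors = FALSE)
  new_germline_locus(v, d, j, name)
}
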