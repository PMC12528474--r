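# --- VH-replacement excision-circle detection ------------------------------

CRSS_HEPTAMER <- "TACTGTG"
RSS_HEPTAMER_PATTERN <- "CACA[GAT]TG"

# first-hit starts of `pattern` in every molecule (0 rows where absent)
anchor_starts <- function(subj, pattern, max_mm) {
  m <- Biostrings::vmatchPattern(pattern, subj, max.mismatch = max_mm,
                                 fixed = TRUE)
  cnt <- S4Vectors::elementNROWS(m)
  idx <- which(cnt > 0L)
  if (length(idx) == 0L) {
    return(data.frame(mol = integer(), start = integer()))
  }
  st <- Biostrings::startIndex(m)
  data.frame(mol = idx,
             start = vapply(st[idx], `[[`, integer(1), 1L))
}

#' Main anchored search for VH-replacement excision circles
#'
#' For each molecule: the best recipient is the V whose 60-nt framework-3
#' anchor matches with at most `max_mm` mismatches; a donor is a different
#' V whose 60-nt 3'-intergenic anchor matches within `gap_range` nt
#' downstream of the recipient anchor. The gap must contain the cryptic
#' heptamer TACTGTG followed, after 0-4 nt of insertion, by a conventional
#' heptamer matching CACA[GAT]TG. At most one candidate is emitted per
#' molecule; molecules lacking either anchor are silently skipped (and
#' counted in the attributes).
#'
#' @param molecules data frame of merged, oriented, deduplicated molecules
#'   (`seq`, plus `id`).
#' @param locus a [germline_locus] providing `fr3_seq` and `intergenic_3p`.
#' @param anchor_len anchor length (nt; the assay convention is 60).
#' @param max_mm maximum mismatches per anchor.
#' @param gap_range allowed gap between the anchors (nt).
#' @param insertion_range allowed insertion lengths between the heptamers.
#' @return candidate data frame (one row per calling molecule).
#' @export
find_circles_main <- function(molecules, locus, anchor_len = 60L, max_mm = 2L,
                              gap_range = c(10L, 120L),
                              insertion_range = 0:4) {
  v <- locus$v
  subj <- Biostrings::DNAStringSet(molecules$seq)
  ids <- molecules$id %||% sprintf("mol%06d", seq_len(nrow(molecules)))
  fr3 <- substr(v$fr3_seq, nchar(v$fr3_seq) - anchor_len + 1L,
                nchar(v$fr3_seq))
  ig <- substr(v$intergenic_3p, 1L, anchor_len)
  rec <- do.call(rbind, lapply(seq_len(nrow(v)), function(k) {
    h <- anchor_starts(subj, fr3[k], max_mm)
    if (nrow(h)) h$v_idx <- k
    h
  }))
  don <- do.call(rbind, lapply(seq_len(nrow(v)), function(k) {
    h <- anchor_starts(subj, ig[k], max_mm)
    if (nrow(h)) h$v_idx <- k
    h
  }))
  empty <- data.frame(read_id = character(), recipient_v = character(),
                      donor_v = character(), insertion_nt = character(),
                      junction_string = character(),
                      recipient_match_len = integer(),
                      donor_match_len = integer(), source = character(),
                      stringsAsFactors = FALSE)
  if (is.null(rec) || is.null(don) || nrow(rec) == 0L || nrow(don) == 0L) {
    attr(empty, "skipped") <- nrow(molecules)
    return(empty)
  }
  # lowest locus rank wins when several recipient anchors match
  rec <- rec[order(rec$mol, rec$v_idx), ]
  rec <- rec[!duplicated(rec$mol), ]
  ins_pat <- sprintf("%s(.{%d,%d}?)(%s)", CRSS_HEPTAMER,
                     min(insertion_range), max(insertion_range),
                     RSS_HEPTAMER_PATTERN)
  out <- list()
  both <- merge(rec, don, by = "mol", suffixes = c("_r", "_d"))
  both <- both[both$v_idx_r != both$v_idx_d, , drop = FALSE]
  if (nrow(both)) {
    e <- both$start_r + anchor_len - 1L # recipient anchor end (1-based)
    gap <- both$start_d - e - 1L
    both <- both[gap >= gap_range[1] & gap <= gap_range[2], , drop = FALSE]
    if (nrow(both)) {
      e <- both$start_r + anchor_len - 1L
      gap_str <- substr(molecules$seq[both$mol], e + 1L, both$start_d - 1L)
      m <- regexpr(ins_pat, gap_str, perl = TRUE)
      ok <- m > 0L
      both <- both[ok, , drop = FALSE]
      if (nrow(both)) {
        gap_str <- gap_str[ok]
        m <- m[ok]
        jlen <- attr(regexpr(ins_pat, gap_str, perl = TRUE), "match.length")
        junction <- substr(gap_str, m, m + jlen - 1L)
        cand <- data.frame(
          read_id = ids[both$mol],
          recipient_v = v$name[both$v_idx_r], donor_v = v$name[both$v_idx_d],
          insertion_nt = substr(junction, 8L, nchar(junction) - 7L),
          junction_string = junction,
          recipient_match_len = anchor_len, donor_match_len = anchor_len,
          source = "main", stringsAsFactors = FALSE)
        # one call per molecule: keep the first (closest donor)
        cand <- cand[!duplicated(cand$read_id), , drop = FALSE]
        out[[1L]] <- cand
      }
    }
  }
  res <- if (length(out)) out[[1L]] else empty
  attr(res, "skipped") <- nrow(molecules) - nrow(res)
  rownames(res) <- NULL
  res
}

#' Grep-style fallback search for back-to-back heptamers
#'
#' Searches molecules directly for `TACTGTG`, up to `insertion_max` nt, then
#' `CACA[GAT]TG` - the signal-joint signature - for reads too short to
#' carry the 60-nt donor anchor. Recipient and donor are then identified
#' with reduced-length anchors (`short_anchor` nt each side, default 20).
#'
#' @param molecules data frame with `seq` (plus `id`).
#' @param locus a [germline_locus].
#' @param insertion_max maximum insertion between the heptamers (the
#'   published grep allowed up to 3 bp).
#' @param short_anchor reduced anchor length.
#' @param max_mm maximum mismatches per reduced anchor.
#' @return candidate data frame (same columns as [find_circles_main()]).
#' @export
find_circles_fallback <- function(molecules, locus, insertion_max = 3L,
                                  short_anchor = 20L, max_mm = 2L) {
  v <- locus$v
  ids <- molecules$id %||% sprintf("mol%06d", seq_len(nrow(molecules)))
  pat <- sprintf("%s(.{0,%d}?)(%s)", CRSS_HEPTAMER, insertion_max,
                 RSS_HEPTAMER_PATTERN)
  m <- regexpr(pat, molecules$seq, perl = TRUE)
  hit <- which(m > 0L)
  if (length(hit) == 0L) {
    return(data.frame(read_id = character(), recipient_v = character(),
                      donor_v = character(), insertion_nt = character(),
                      junction_string = character(),
                      recipient_match_len = integer(),
                      donor_match_len = integer(), source = character(),
                      stringsAsFactors = FALSE))
  }
  jlen <- attr(m, "match.length")[hit]
  jstart <- m[hit]
  seqs <- molecules$seq[hit]
  junction <- substr(seqs, jstart, jstart + jlen - 1L)
  # recipient: sequence just 5' of the cryptic heptamer vs each V's coding
  # sequence just 5' of its cryptic RSS; donor: sequence just 3' of the
  # conventional heptamer vs each V's intergenic prefix
  up <- substr(seqs, pmax(1L, jstart - short_anchor), jstart - 1L)
  down <- substr(seqs, jstart + jlen, jstart + jlen + short_anchor - 1L)
  rec_anch <- ifelse(is.na(v$crss_offset), NA_character_,
                     substr(v$coding_seq, v$crss_offset - short_anchor + 1L,
                            v$crss_offset))
  don_anch <- substr(v$intergenic_3p, 1L, short_anchor)
  pick <- function(x, anchors) {
    vapply(x, function(s) {
      if (nchar(s) < short_anchor) return(NA_integer_)
      mm <- vapply(anchors, function(a) {
        if (is.na(a)) return(Inf)
        hamming(s, a)
      }, numeric(1))
      k <- which.min(mm)
      if (mm[k] <= max_mm) k else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
  }
  ri <- pick(up, rec_anch)
  di <- pick(down, don_anch)
  data.frame(
    read_id = ids[hit], recipient_v = v$name[ri], donor_v = v$name[di],
    insertion_nt = substr(junction, 8L, nchar(junction) - 7L),
    junction_string = junction,
    recipient_match_len = ifelse(is.na(ri), 0L, short_anchor),
    donor_match_len = ifelse(is.na(di), 0L, short_anchor),
    source = "fallback", stringsAsFactors = FALSE)
}

#' Curate candidate circle calls
#'
#' Automated version of the published manual curation: a call is accepted
#' iff (i) the back-to-back heptamer junction is confirmed, (ii) both
#' anchors reach `min_anchor` nt, (iii) donor and recipient differ, and
#' (iv) the donor lies distal to the recipient in the locus. Rejected calls
#' carry a `reject_reason` in `no_junction`, `weak_anchor`, `self_match`,
#' `donor_not_distal`.
#'
#' @param candidates data frame from [find_circles_main()] or
#'   [find_circles_fallback()].
#' @param locus a [germline_locus].
#' @param min_anchor minimum accepted anchor length (nt).
#' @param insertion_range accepted insertion lengths.
#' @return `candidates` with `curated` and `reject_reason` columns.
#' @export
curate_calls <- function(candidates, locus, min_anchor = 20L,
                         insertion_range = 0:4) {
  v <- locus$v
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  jp <- sprintf("^%s.{%d,%d}%s$", CRSS_HEPTAMER, min(insertion_range),
                max(insertion_range), RSS_HEPTAMER_PATTERN)
  ok_j <- grepl(jp, candidates$junction_string, perl = TRUE)
  reason[!ok_j] <- "no_junction"
  rr <- v$locus_rank[match(candidates$recipient_v, v$name)]
  dr <- v$locus_rank[match(candidates$donor_v, v$name)]
  weak <- is.na(reason) &
    (is.na(candidates$recipient_v) | is.na(candidates$donor_v) |
       is.na(rr) | is.na(dr) |
       candidates$recipient_match_len < min_anchor |
       candidates$donor_match_len < min_anchor)
  reason[weak] <- "weak_anchor"
  self <- is.na(reason) & candidates$recipient_v == candidates$donor_v
  reason[self] <- "self_match"
  prox <- is.na(reason) & dr <= rr
  reason[prox] <- "donor_not_distal"
  candidates$curated <- is.na(reason)
  candidates$reject_reason <- reason
  candidates
}

#' @rdname curate_calls
#' @param candidate a single candidate (one-row data frame or list).
#' @export
curate_call <- function(candidate, locus, min_anchor = 20L,
                        insertion_range = 0:4) {
  as.list(curate_calls(as.data.frame(candidate, stringsAsFactors = FALSE),
                       locus, min_anchor, insertion_range))
}

#' Detect and curate circles in one step
#'
#' Runs the main anchored search, adds fallback hits for molecules the main
#' search did not call, and curates the union.
#'
#' @inheritParams find_circles_main
#' @param ... passed to the searches.
#' @return curated call data frame.
#' @export
detect_circles <- function(molecules, locus, max_mm = 2L, ...) {
  main <- find_circles_main(molecules, locus, max_mm = max_mm, ...)
  fb <- find_circles_fallback(molecules, locus, max_mm = max_mm)
  fb <- fb[!(fb$read_id %in% main$read_id), , drop = FALSE]
  curate_calls(rbind(main, fb), locus)
}

#' Summaries of curated circle calls
#'
#' Donor and recipient maps (counts by V and locus rank), the
#' insertion-length histogram, per-library totals and, when a reference
#' library is named, the ratio `count_ref / mean(count_others)`.
#'
#' @param calls curated calls (rows with `curated == FALSE` are dropped).
#' @param locus a [germline_locus].
#' @param library optional vector of library labels, one per call.
#' @param reference optional reference library for the ratio statistic.
#' @param insertion_range histogram support.
#' @return list with `donor_map`, `recipient_map`, `insertion_hist`,
#'   `library_counts`, `ratio`.
#' @export
summarize_circles <- function(calls, locus, library = NULL,
                              reference = NULL, insertion_range = 0:4) {
  if (!is.null(library)) {
    stopifnot(length(library) == nrow(calls))
    calls$library <- library
  }
  if ("curated" %in% names(calls)) {
    keep <- calls$curated %in% TRUE
    calls <- calls[keep, , drop = FALSE]
  }
  v <- locus$v
  count_map <- function(names) {
    tab <- table(factor(names, levels = v$name))
    data.frame(v_call = v$name, locus_rank = v$locus_rank,
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
  ins <- table(factor(nchar(calls$insertion_nt), levels = insertion_range))
  lib_counts <- NULL
  ratio <- NA_real_
  if (!is.null(calls$library)) {
    tab <- table(calls$library)
    lib_counts <- data.frame(library = names(tab), count = as.integer(tab),
                             stringsAsFactors = FALSE)
    if (!is.null(reference) && reference %in% lib_counts$library &&
        nrow(lib_counts) > 1L) {
      a <- lib_counts$count[lib_counts$library == reference]
      b <- lib_counts$count[lib_counts$library != reference]
      ratio <- a / mean(b)
    }
  }
  list(donor_map = count_map(calls$donor_v),
       recipient_map = count_map(calls$recipient_v),
       insertion_hist = data.frame(insertion = as.integer(names(ins)),
                                   count = as.integer(ins)),
       library_counts = lib_counts, ratio = ratio,
       n_curated = nrow(calls))
}
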