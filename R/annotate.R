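reverse_str <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Merge read pairs by ungapped overlap
#'
#' Read 1 is aligned against the reverse complement of read 2; the longest
#' ungapped overlap of at least `min_overlap` nt with a mismatch fraction
#' at most `max_mismatch_frac` is accepted. Within the overlap the
#' higher-quality base wins. The assembly is then reverse-complemented into
#' V-to-J (forward) orientation. Failure to merge is a normal outcome.
#'
#' Exact-overlap candidates are found with fast vectorised string equality;
#' only pairs without an exact overlap fall back to a mismatch-tolerant
#' per-pair scan.
#'
#' @param r1,r2 read data frames (`id`, `seq`, `qual`, optionally `umi`).
#' @param min_overlap minimum overlap (nt).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return list with `merged` (data frame `id`, `seq`, `qual`, `umi`) and
#'   `unmerged` (ids).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 30L, max_mismatch_frac = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  rc2 <- revcomp(r2$seq)
  rq2 <- reverse_str(r2$qual)
  n1 <- nchar(r1$seq); n2 <- nchar(rc2)
  omax <- pmin(n1, n2)
  seq_out <- rep(NA_character_, n)
  qual_out <- rep(NA_character_, n)
  open <- rep(TRUE, n)
  if (n > 0L) {
    for (o in seq(max(omax), min_overlap)) {
      cand <- which(open & omax >= o)
      if (length(cand) == 0L) next
      x <- substr(r1$seq[cand], n1[cand] - o + 1L, n1[cand])
      y <- substr(rc2[cand], 1L, o)
      hit <- cand[x == y]
      if (length(hit)) {
        seq_out[hit] <- paste0(r1$seq[hit], substr(rc2[hit], o + 1L, n2[hit]))
        qual_out[hit] <- paste0(r1$qual[hit], substr(rq2[hit], o + 1L, n2[hit]))
        open[hit] <- FALSE
      }
    }
    ## mismatch-tolerant fallback
    for (i in which(open)) {
      for (o in seq(omax[i], min_overlap)) {
        x <- substr(r1$seq[i], n1[i] - o + 1L, n1[i])
        y <- substr(rc2[i], 1L, o)
        mm <- hamming(x, y)
        if (mm / o <= max_mismatch_frac) {
          xq <- utf8ToInt(substr(r1$qual[i], n1[i] - o + 1L, n1[i]))
          yq <- utf8ToInt(substr(rq2[i], 1L, o))
          xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
          cons <- ifelse(xq >= yq, xs, ys)
          seq_out[i] <- paste0(substr(r1$seq[i], 1L, n1[i] - o),
                               paste(cons, collapse = ""),
                               substr(rc2[i], o + 1L, n2[i]))
          qual_out[i] <- paste0(substr(r1$qual[i], 1L, n1[i] - o),
                                intToUtf8(pmax(xq, yq)),
                                substr(rq2[i], o + 1L, n2[i]))
          open[i] <- FALSE
          break
        }
      }
    }
  }
  ok <- !open
  merged <- data.frame(id = r1$id[ok], seq = revcomp(seq_out[ok]),
                       qual = reverse_str(qual_out[ok]),
                       umi = if ("umi" %in% names(r1)) r1$umi[ok]
                             else rep(NA_character_, sum(ok)),
                       stringsAsFactors = FALSE)
  list(merged = merged, unmerged = r1$id[open])
}

#' Collapse reads to molecules by UMI and sequence length
#'
#' One representative is kept per (UMI, sequence length) key: the read with
#' the highest mean base quality, ties broken by lexicographic sequence.
#' Reads without a UMI token are routed to a sink and counted.
#'
#' @param reads data frame with `id`, `seq`, `qual`, `umi`.
#' @return list with `molecules` (representatives plus `duplicate_count`)
#'   and `sink` (reads lacking a UMI).
#' @export
dedup_by_umi <- function(reads) {
  no_umi <- is.na(reads$umi) | reads$umi == ""
  sink <- reads[no_umi, , drop = FALSE]
  r <- reads[!no_umi, , drop = FALSE]
  if (nrow(r) == 0L) {
    mol <- cbind(r, duplicate_count = integer(0))
    return(list(molecules = mol, sink = sink))
  }
  key <- paste(r$umi, nchar(r$seq), sep = "_")
  meanq <- vapply(r$qual, function(q) mean(utf8ToInt(q)), numeric(1),
                  USE.NAMES = FALSE)
  ord <- order(key, -meanq, r$seq)
  r <- r[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  mol <- r[first, , drop = FALSE]
  mol$duplicate_count <- as.integer(table(key)[key[first]])
  rownames(mol) <- NULL
  list(molecules = mol, sink = sink)
}

# --- segment assignment ----------------------------------------------------

best_anchor <- function(strings, anchors, max_mm) {
  # strings and anchors equal width; returns index of best anchor (ties ->
  # first, i.e. lowest locus rank), NA when above max_mm, plus tie flag
  mm <- vapply(anchors, function(a) mismatch_matrix(strings, a),
               numeric(length(strings)))
  if (length(strings) == 1L) mm <- matrix(mm, nrow = 1L)
  best <- max.col(-mm, ties.method = "first")
  bmm <- mm[cbind(seq_along(best), best)]
  ties <- rowSums(mm == bmm) > 1L
  best[bmm > max_mm] <- NA_integer_
  list(idx = best, mm = bmm, tie = ties & !is.na(best))
}

#' Assign V, D and J segments to merged molecules
#'
#' V and J are assigned by best ungapped anchor match: the first
#' `anchor_len` nt of each V coding sequence against the molecule prefix,
#' and the last `anchor_len` nt of each J against the molecule suffix, each
#' tolerating `max_mm` mismatches (molecules are assumed oriented V to J
#' and to span the segment boundaries, as run-off/full-length molecules
#' do). Ties take the lower locus rank and set an ambiguity flag. A
#' molecule with no J match is discarded to the sink (the capture is
#' J-anchored); no V match leaves a DJ-only row. D is assigned by the
#' longest exact match of at least 6 nt of any D segment inside the
#' junction window; the Ichihara reading frame of the D match is derived
#' from its offset relative to the translation frame.
#'
#' @param molecules data frame with `seq` (plus any carried columns).
#' @param locus a [germline_locus].
#' @param min_seed minimum matched anchor length.
#' @param max_mm maximum anchor mismatches.
#' @param anchor_len anchor length (>= `min_seed`).
#' @return list with `rows` (annotated) and `sink` (discarded molecules).
#' @export
assign_segments <- function(molecules, locus, min_seed = 20L, max_mm = 2L,
                            anchor_len = 30L) {
  stopifnot(anchor_len >= min_seed)
  v <- locus$v; j <- locus$j
  seqs <- molecules$seq
  n <- nchar(seqs)
  long_enough <- n >= anchor_len
  j_idx <- rep(NA_integer_, length(seqs))
  if (any(long_enough)) {
    j_anch <- substr(j$seq, nchar(j$seq) - anchor_len + 1L, nchar(j$seq))
    suf <- substr(seqs[long_enough], n[long_enough] - anchor_len + 1L,
                  n[long_enough])
    bj <- best_anchor(suf, j_anch, max_mm)
    j_idx[long_enough] <- bj$idx
  }
  keep <- !is.na(j_idx)
  sink <- molecules[!keep, , drop = FALSE]
  rows <- molecules[keep, , drop = FALSE]
  seqs <- seqs[keep]; n <- n[keep]; j_idx <- j_idx[keep]

  v_idx <- rep(NA_integer_, length(seqs))
  v_amb <- rep(FALSE, length(seqs))
  # a V is only plausible if the molecule extends well past the anchor
  v_cand <- n >= pmin(nchar(v$coding_seq)[1], 60L)
  if (any(v_cand)) {
    v_anch <- substr(v$coding_seq, 1L, anchor_len)
    pre <- substr(seqs[v_cand], 1L, anchor_len)
    bv <- best_anchor(pre, v_anch, max_mm)
    v_idx[v_cand] <- bv$idx
    v_amb[v_cand] <- bv$tie
  }

  rows$v_call <- v$name[v_idx]
  rows$v_family <- v$family[v_idx]
  rows$j_call <- j$name[j_idx]
  rows$v_idx <- v_idx
  rows$j_idx <- j_idx
  rows$v_ambiguous <- v_amb

  ## D assignment inside the junction window
  lv <- nchar(v$coding_seq)[v_idx]
  lj <- nchar(j$seq)[j_idx]
  win_start <- ifelse(is.na(v_idx), 1L, pmax(1L, lv - 20L))
  win_end <- pmax(win_start, n - lj + j$trp_offset[j_idx])
  windows <- substr(seqs, win_start, win_end)
  dd <- assign_d_in_windows(windows, locus)
  rows$d_call <- dd$d_call
  rows$d_off <- dd$d_off
  rows$d_abs_pos <- ifelse(is.na(dd$d_pos), NA_integer_,
                           win_start + dd$d_pos - 1L)
  rows$d_match_len <- dd$len
  rownames(rows) <- NULL
  list(rows = rows, sink = sink)
}

# longest exact >=6 nt match of any D within each window; leftmost wins at
# equal length, then the first D in locus order
assign_d_in_windows <- function(windows, locus, min_len = 6L) {
  d <- locus$d
  nw <- length(windows)
  d_call <- rep(NA_character_, nw)
  d_off <- rep(NA_integer_, nw)
  d_pos <- rep(NA_integer_, nw)
  len_out <- rep(NA_integer_, nw)
  if (nw == 0L) {
    return(data.frame(d_call = d_call, d_off = d_off, d_pos = d_pos,
                      len = len_out))
  }
  for (len in seq(max(nchar(d$seq)), min_len)) {
    open <- which(is.na(d_call) & nchar(windows) >= len)
    if (length(open) == 0L) next
    pats <- list()
    for (di in seq_len(nrow(d))) {
      ld <- nchar(d$seq[di])
      if (ld < len) next
      for (off in 0:(ld - len)) {
        pats[[length(pats) + 1L]] <- list(
          di = di, off = off, pat = substr(d$seq[di], off + 1L, off + len))
      }
    }
    if (length(pats) == 0L) next
    posm <- vapply(pats, function(p) {
      m <- regexpr(p$pat, windows[open], fixed = TRUE)
      ifelse(m > 0L, as.integer(m), NA_integer_)
    }, integer(length(open)))
    if (length(open) == 1L) posm <- matrix(posm, nrow = 1L)
    any_hit <- rowSums(!is.na(posm)) > 0L
    if (!any(any_hit)) next
    pick <- max.col(-replace(posm, is.na(posm), .Machine$integer.max),
                    ties.method = "first")
    hit_rows <- open[any_hit]
    pk <- pick[any_hit]
    d_call[hit_rows] <- d$name[vapply(pk, function(k) pats[[k]]$di, integer(1))]
    d_off[hit_rows] <- vapply(pk, function(k) pats[[k]]$off, integer(1))
    d_pos[hit_rows] <- posm[cbind(which(any_hit), pk)]
    len_out[hit_rows] <- len
  }
  data.frame(d_call = d_call, d_off = d_off, d_pos = d_pos, len = len_out,
             stringsAsFactors = FALSE)
}

#' Ichihara D reading frame of annotated rows
#'
#' The frame is anchored at the V reading frame when a V is assigned, and
#' propagated back from the J frame for DJ-only rows (the register the
#' D-mu transcript would use). Reading frame `i` is the translation
#' starting at 0-based D offset `i - 1`.
#'
#' @param rows output rows of [assign_segments()].
#' @param locus a [germline_locus].
#' @return `rows` with a `d_rf` column (NA where no D is assigned).
#' @export
assign_d_rf <- function(rows, locus) {
  j <- locus$j
  n <- nchar(rows$seq)
  lj <- nchar(j$seq)[rows$j_idx]
  phase0 <- ifelse(is.na(rows$v_idx),
                   (n - lj + j$frame_offset[rows$j_idx]) %% 3L, 0L)
  d_rf <- ((rows$d_off - (rows$d_abs_pos - 1L) + phase0) %% 3L) + 1L
  rows$d_rf <- as.integer(ifelse(is.na(rows$d_call), NA_integer_, d_rf))
  rows
}

#' Frame shift, stop codons and productivity
#'
#' For rows with both V and J: the frame shift is the read position of the
#' J frame anchor modulo 3 (0 = in frame with the V), and the stop scan
#' translates from the V start through the conserved J Trp codon (over the
#' whole read-through for frame-shifted rows). A row is productive iff in
#' frame and stop-free. DJ-only rows are never productive (`NA`).
#'
#' @param rows output rows of [assign_segments()].
#' @param locus a [germline_locus].
#' @return `rows` with `frame_shift`, `stop_codon`, `productive`.
#' @export
call_productivity <- function(rows, locus) {
  j <- locus$j
  n <- nchar(rows$seq)
  lj <- nchar(j$seq)[rows$j_idx]
  fs <- as.integer((n - lj + j$frame_offset[rows$j_idx]) %% 3L)
  wz <- n - lj + j$trp_offset[rows$j_idx] # 0-based W codon start
  aa <- translate_dna(rows$seq)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  w_codon <- wz %/% 3L + 1L
  has_stop <- stop_at > 0L & (fs != 0L | stop_at <= w_codon)
  has_v <- !is.na(rows$v_idx)
  rows$frame_shift <- ifelse(has_v, fs, NA_integer_)
  rows$stop_codon <- ifelse(has_v, has_stop, NA)
  rows$productive <- ifelse(has_v, fs == 0L & !has_stop, NA)
  rows
}

#' Extract the CDR3 between Cys96 and the conserved J Trp
#'
#' Translates in-frame rows from the V start, requires the germline
#' V-terminal Cys codon to have survived junctional trimming (checked at
#' its fixed germline position), and returns the residues strictly between
#' Cys (position 96) and the J-encoded Trp, numbered from 97.
#' Out-of-frame rows, and rows whose Cys was trimmed away, are unresolved.
#'
#' @param rows output rows of [call_productivity()].
#' @param locus a [germline_locus].
#' @return `rows` with `cdr3_aa`, `cdr3_resolved`, `junction`,
#'   `junction_aa`.
#' @export
extract_cdr3 <- function(rows, locus) {
  v <- locus$v; j <- locus$j
  n <- nchar(rows$seq)
  lj <- nchar(j$seq)[rows$j_idx]
  wz <- n - lj + j$trp_offset[rows$j_idx]
  cys_off <- v$cys_offset[rows$v_idx]
  cys_codon <- substr(rows$seq, cys_off + 1L, cys_off + 3L)
  resolved <- !is.na(rows$v_idx) & rows$frame_shift %in% 0L &
    cys_codon %in% c("TGT", "TGC") & wz > cys_off + 3L
  aa <- translate_dna(rows$seq)
  cys_idx <- cys_off %/% 3L + 1L
  w_codon <- wz %/% 3L + 1L
  rows$cdr3_aa <- ifelse(resolved, substr(aa, cys_idx + 1L, w_codon - 1L),
                         NA_character_)
  rows$cdr3_resolved <- resolved
  rows$junction <- ifelse(!is.na(rows$v_idx) & !is.na(cys_off),
                          substr(rows$seq, cys_off + 1L, wz + 3L),
                          NA_character_)
  rows$junction_aa <- ifelse(resolved, substr(aa, cys_idx, w_codon),
                             NA_character_)
  rows
}

#' IMGT to Ichihara D reading-frame transposition
#'
#' The conventions are cyclic permutations of one another: 1 -> 2, 2 -> 3,
#' 3 -> 1.
#'
#' @param rf reading frame(s) in 1..3.
#' @return transposed frame(s).
#' @export
transpose_rf_imgt_to_ichihara <- function(rf) {
  if (!all(rf %in% 1:3)) stop("reading frames must be 1, 2 or 3", call. = FALSE)
  (rf %% 3L) + 1L
}

#' Annotate merged, deduplicated molecules into AIRR-style rows
#'
#' Chains [assign_segments()], [assign_d_rf()], [call_productivity()] and
#' [extract_cdr3()], returning one row per molecule with AIRR schema names
#' where a field exists (`sequence_id`, `sequence`, `v_call`, `d_call`,
#' `j_call`, `junction`, `junction_aa`, `productive`, `stop_codon`,
#' `duplicate_count`) and bespoke extension columns (`d_rf`, `frame_shift`,
#' `cdr3_aa`, `stage`, `v_family`, `v_ambiguous`).
#'
#' @param molecules molecule data frame (with `seq`; `id`, `umi`,
#'   `duplicate_count` are carried if present).
#' @param locus a [germline_locus].
#' @param stage library stage label carried into the output.
#' @param min_seed,max_mm,anchor_len see [assign_segments()].
#' @return list with `rearrangements` and `sink`.
#' @export
annotate_molecules <- function(molecules, locus, stage = NA_character_,
                               min_seed = 20L, max_mm = 2L,
                               anchor_len = 30L) {
  as_res <- assign_segments(molecules, locus, min_seed = min_seed,
                            max_mm = max_mm, anchor_len = anchor_len)
  rows <- as_res$rows
  if (nrow(rows) > 0L) {
    rows <- assign_d_rf(rows, locus)
    rows <- call_productivity(rows, locus)
    rows <- extract_cdr3(rows, locus)
  } else {
    for (cn in c("d_rf", "frame_shift", "stop_codon", "productive",
                 "cdr3_aa", "cdr3_resolved", "junction", "junction_aa")) {
      rows[[cn]] <- logical(0)
    }
  }
  nr <- nrow(rows)
  out <- data.frame(
    sequence_id = rows$id %||% sprintf("seq%06d", seq_len(nr)),
    sequence = rows$seq,
    umi = rows$umi %||% rep(NA_character_, nr),
    v_call = rows$v_call, d_call = rows$d_call, j_call = rows$j_call,
    junction = rows$junction, junction_aa = rows$junction_aa,
    cdr3_aa = rows$cdr3_aa, cdr3_resolved = rows$cdr3_resolved,
    productive = rows$productive, stop_codon = rows$stop_codon,
    frame_shift = rows$frame_shift, d_rf = rows$d_rf,
    duplicate_count = rows$duplicate_count %||% rep(1L, nr),
    v_family = rows$v_family, v_ambiguous = rows$v_ambiguous,
    stage = rep(stage, nr), stringsAsFactors = FALSE
  )
  list(rearrangements = out, sink = as_res$sink)
}

#' Write / read AIRR-style rearrangement tables
#'
#' Tab-separated, one row per molecule, logicals encoded `T`/`F`.
#'
#' @param rows rearrangement data frame.
#' @param path file path.
#' @export
write_rearrangements <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rearrangements
#' @export
read_rearrangements <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
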