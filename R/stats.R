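# --- repertoire-level selection statistics ---------------------------------

filter_subset <- function(rows, stage = NULL, productive = NULL) {
  if (!is.null(stage)) rows <- rows[rows$stage %in% stage, , drop = FALSE]
  if (!is.null(productive)) {
    rows <- rows[rows$productive %in% productive, , drop = FALSE]
  }
  rows
}

#' Per-V frequency table
#'
#' Counts V usage within a subset (stage x productivity). V genes below
#' `min_freq` are flagged (`kept = FALSE`): they are excluded from per-V
#' plots but remain in every denominator, so frequencies always sum to 1.
#'
#' @param rows annotated rearrangement rows.
#' @param stage,productive optional subset filters.
#' @param min_freq retention threshold (the published analyses keep V
#'   detected at > 0.1% frequency).
#' @param key column to tabulate (default `v_call`; `v_family` or `j_call`
#'   also work).
#' @return data frame `key`, `count`, `freq`, `denominator`, `kept`.
#' @export
vh_frequency <- function(rows, stage = NULL, productive = NULL,
                         min_freq = 0.001, key = "v_call") {
  rows <- filter_subset(rows, stage, productive)
  rows <- rows[!is.na(rows[[key]]), , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning("empty subset", call. = FALSE)
    return(data.frame(key = character(), count = integer(), freq = numeric(),
                      denominator = integer(), kept = logical()))
  }
  tab <- table(rows[[key]])
  denom <- sum(tab)
  out <- data.frame(key = names(tab), count = as.integer(tab),
                    freq = as.numeric(tab) / denom, denominator = denom,
                    stringsAsFactors = FALSE)
  out$kept <- out$freq >= min_freq
  out[order(-out$count), ]
}

#' Fraction of productive VDJ per V gene
#'
#' @param rows annotated rows with productivity calls.
#' @param min_n V genes with fewer assignments are flagged `low_n`.
#' @return data frame `v_call`, `n`, `n_productive`, `frac_productive`,
#'   `low_n`.
#' @export
productivity_by_vh <- function(rows, min_n = 20L) {
  rows <- rows[!is.na(rows$v_call) & !is.na(rows$productive), , drop = FALSE]
  n <- tapply(rows$productive, rows$v_call, length)
  np <- tapply(rows$productive, rows$v_call, sum)
  data.frame(v_call = names(n), n = as.integer(n),
             n_productive = as.integer(np),
             frac_productive = as.numeric(np) / as.numeric(n),
             low_n = as.integer(n) < min_n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-key frequency change between two tables
#'
#' Fold change `freq_b / freq_a` and difference `freq_b - freq_a` per key.
#' A key absent from `b` gives fold 0; a zero baseline gives an undefined
#' fold (flagged, `NA`) while the difference is still reported.
#'
#' @param table_a,table_b outputs of [vh_frequency()].
#' @return data frame `key`, `freq_a`, `freq_b`, `fold`, `diff`,
#'   `fold_undefined`.
#' @export
selection_fold <- function(table_a, table_b) {
  keys <- union(table_a$key, table_b$key)
  fa <- table_a$freq[match(keys, table_a$key)]; fa[is.na(fa)] <- 0
  fb <- table_b$freq[match(keys, table_b$key)]; fb[is.na(fb)] <- 0
  undef <- fa == 0
  data.frame(key = keys, freq_a = fa, freq_b = fb,
             fold = ifelse(undef, NA_real_, fb / fa), diff = fb - fa,
             fold_undefined = undef, stringsAsFactors = FALSE)
}

#' VH-family by JH usage matrix
#'
#' Cell (family, JH) holds that combination's fraction of the entire VDJ
#' repertoire in the subset; row sums equal family totals.
#'
#' @param rows annotated rows.
#' @param families families to report (default: all observed).
#' @param stage,productive optional subset filters.
#' @return numeric matrix, families x JH.
#' @export
vh_family_by_jh <- function(rows, families = NULL, stage = NULL,
                            productive = NULL) {
  rows <- filter_subset(rows, stage, productive)
  rows <- rows[!is.na(rows$v_family) & !is.na(rows$j_call), , drop = FALSE]
  if (is.null(families)) families <- sort(unique(rows$v_family))
  tab <- table(factor(rows$v_family, levels = families), rows$j_call)
  m <- unclass(tab) / nrow(rows)
  dimnames(m) <- dimnames(tab)
  m
}

#' Frequency of a residue at a CDR3 position
#'
#' For each group, the number of rows with `residue` at `position` over the
#' number of rows resolving that position (CDR3 long enough and resolved).
#' Positions are numbered from 97 (the first CDR3 residue after Cys96).
#'
#' @param rows annotated rows with `cdr3_aa`.
#' @param position CDR3 position (>= 97).
#' @param residue single amino-acid letter.
#' @param group_by optional column name to group by.
#' @param exclude_v V names excluded before counting (e.g. the single
#'   family member that germline-encodes the residue).
#' @return data frame `group`, `n_resolved`, `n_residue`, `freq`.
#' @export
residue_freq_at <- function(rows, position, residue, group_by = NULL,
                            exclude_v = NULL) {
  stopifnot(position >= 97L)
  if (!is.null(exclude_v)) {
    rows <- rows[!(rows$v_call %in% exclude_v), , drop = FALSE]
  }
  i <- position - 96L
  resolved <- rows$cdr3_resolved %in% TRUE & !is.na(rows$cdr3_aa) &
    nchar(rows$cdr3_aa) >= i
  grp <- if (is.null(group_by)) rep("all", nrow(rows)) else rows[[group_by]]
  groups <- unique(grp[!is.na(grp)])
  out <- lapply(groups, function(g) {
    sel <- resolved & grp %in% g
    n <- sum(sel)
    if (n == 0L) {
      warning("position ", position, " never resolved in group ", g,
              "; group omitted", call. = FALSE)
      return(NULL)
    }
    k <- sum(substr(rows$cdr3_aa[sel], i, i) == residue)
    data.frame(group = g, n_resolved = n, n_residue = k, freq = k / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Positional amino-acid frequency change between two repertoires
#'
#' Per (family, position, amino acid): the difference in resolved-position
#' frequency between repertoires `b` and `a`. Deltas sum to zero within
#' each (family, position) block whenever both repertoires resolve it.
#'
#' @param rows_a,rows_b annotated rows (e.g. pro-B vs small pre-B).
#' @param families families to analyse (default: shared observed families).
#' @param positions CDR3 positions (default 97:103, the first seven).
#' @return data frame `family`, `position`, `aa`, `freq_a`, `freq_b`,
#'   `delta`.
#' @export
positional_delta <- function(rows_a, rows_b, families = NULL,
                             positions = 97:103) {
  if (is.null(families)) {
    families <- intersect(unique(rows_a$v_family), unique(rows_b$v_family))
    families <- sort(families[!is.na(families)])
  }
  pos_freqs <- function(rows, fam, pos) {
    i <- pos - 96L
    sel <- rows$v_family %in% fam & rows$cdr3_resolved %in% TRUE &
      !is.na(rows$cdr3_aa) & nchar(rows$cdr3_aa) >= i
    if (!any(sel)) return(NULL)
    aa <- substr(rows$cdr3_aa[sel], i, i)
    tab <- table(aa)
    as.numeric(tab) / sum(tab) -> f
    setNames(f, names(tab))
  }
  out <- list()
  for (fam in families) {
    for (pos in positions) {
      fa <- pos_freqs(rows_a, fam, pos)
      fb <- pos_freqs(rows_b, fam, pos)
      if (is.null(fa) || is.null(fb)) next
      aas <- union(names(fa), names(fb))
      va <- ifelse(aas %in% names(fa), fa[aas], 0)
      vb <- ifelse(aas %in% names(fb), fb[aas], 0)
      out[[length(out) + 1L]] <- data.frame(
        family = fam, position = pos, aa = aas, freq_a = as.numeric(va),
        freq_b = as.numeric(vb), delta = as.numeric(vb - va),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' D reading-frame and stop-codon summaries
#'
#' Two tables: the relative frequency of D reading frames (over rows with a
#' D frame call), and, among in-frame rows of each reading frame, the
#' fraction carrying a stop codon (stops in RF1/RF2 arise de novo at the
#' junctions, RF3 stops are largely germline-encoded).
#'
#' @param rows annotated rows.
#' @param group_by optional grouping column (e.g. `stage`).
#' @return list with `rf_freq` and `stop_by_rf` data frames.
#' @export
rf_and_stop_summary <- function(rows, group_by = NULL) {
  grp <- if (is.null(group_by)) rep("all", nrow(rows)) else rows[[group_by]]
  d <- !is.na(rows$d_rf)
  rf_freq <- do.call(rbind, lapply(unique(grp[d]), function(g) {
    sel <- d & grp %in% g
    tab <- table(factor(rows$d_rf[sel], levels = 1:3))
    data.frame(group = g, d_rf = 1:3, n = as.integer(tab),
               freq = as.integer(tab) / sum(tab), stringsAsFactors = FALSE)
  }))
  inf <- d & rows$frame_shift %in% 0L & !is.na(rows$stop_codon)
  stop_by_rf <- do.call(rbind, lapply(unique(grp[inf]), function(g) {
    sel <- inf & grp %in% g
    n <- tapply(rows$stop_codon[sel], factor(rows$d_rf[sel], levels = 1:3),
                length)
    k <- tapply(rows$stop_codon[sel], factor(rows$d_rf[sel], levels = 1:3),
                sum)
    n[is.na(n)] <- 0L; k[is.na(k)] <- 0L
    data.frame(group = g, d_rf = 1:3, n_inframe = as.integer(n),
               n_stop = as.integer(k),
               frac_stop = ifelse(n > 0, as.numeric(k) / as.numeric(n), NA),
               stringsAsFactors = FALSE)
  }))
  list(rf_freq = rf_freq, stop_by_rf = stop_by_rf)
}

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

#' CDR3 biophysical indices
#'
#' Net charge `(R + K) - (D + E)` (histidine contributes `his_charge`,
#' 0 by default), the Kyte-Doolittle GRAVY mean hydropathy, and the
#' aliphatic index `100 * (fA + 2.9 fV + 3.9 (fI + fL))` over mole
#' fractions. Non-standard residues are excluded from the means and
#' flagged.
#'
#' @param cdr3 character vector of peptides.
#' @param his_charge charge contribution per histidine.
#' @return data frame `net_charge`, `gravy`, `aliphatic_index`, `length`,
#'   `nonstandard`.
#' @export
cdr3_biophysics <- function(cdr3, his_charge = 0) {
  one <- function(p) {
    ch <- strsplit(p, "")[[1]]
    std <- ch[ch %in% names(KD_HYDROPATHY)]
    n <- length(std)
    data.frame(
      net_charge = sum(std %in% c("R", "K")) - sum(std %in% c("D", "E")) +
        his_charge * sum(std == "H"),
      gravy = if (n > 0) mean(KD_HYDROPATHY[std]) else NA_real_,
      aliphatic_index = if (n > 0) {
        100 * (sum(std == "A") + 2.9 * sum(std == "V") +
                 3.9 * (sum(std == "I") + sum(std == "L"))) / n
      } else NA_real_,
      length = nchar(p), nonstandard = length(std) < length(ch))
  }
  out <- do.call(rbind, lapply(cdr3, one))
  rownames(out) <- NULL
  out
}

#' Usage-weighted amino-acid logo matrix for D segments
#'
#' Per CDR3-relative position, the amino-acid frequencies of the D-segment
#' translations in reading frame `rf`, weighted by each segment's usage.
#' Stop codons appear as `X`. Columns sum to at most 1: shorter D segments
#' contribute no residue beyond their length.
#'
#' @param d_segments D table (as in `locus$d`).
#' @param usage_weights numeric weights (named by D or positional), summing
#'   to 1.
#' @param rf reading frame 1..3 (Ichihara).
#' @return matrix, amino acids x positions.
#' @export
weighted_logo <- function(d_segments, usage_weights, rf) {
  stopifnot(rf %in% 1:3)
  if (!is.null(names(usage_weights))) {
    usage_weights <- usage_weights[d_segments$name]
  }
  if (length(usage_weights) != nrow(d_segments) ||
      anyNA(usage_weights) || abs(sum(usage_weights) - 1) > 1e-9) {
    stop("usage_weights must cover every D segment and sum to 1",
         call. = FALSE)
  }
  peps <- gsub("*", "X", d_segments[[paste0("rf", rf, "_peptide")]],
               fixed = TRUE)
  maxlen <- max(nchar(peps))
  aas <- sort(unique(unlist(strsplit(peps, ""))))
  m <- matrix(0, nrow = length(aas), ncol = maxlen,
              dimnames = list(aas, seq_len(maxlen)))
  for (i in seq_along(peps)) {
    ch <- strsplit(peps[i], "")[[1]]
    for (p in seq_along(ch)) m[ch[p], p] <- m[ch[p], p] + usage_weights[i]
  }
  m
}

#' Coefficient of determination of a simple linear regression
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return R^2, or `NA` (with a warning) when either variable has zero
#'   variance.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  # for simple ordinary least squares, R^2 is the squared correlation
  stats::cor(x, y)^2
}

#' Welch's unpaired two-tailed t test
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df` (Satterthwaite) and two-sided `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Association between cryptic-RSS possession and per-V productivity
#'
#' Splits per-V productivity into V genes with and without a cryptic RSS,
#' reports group medians and a Welch test, and flags TA-terminal V genes
#' (intrinsically stop-prone) in the output.
#'
#' @param v_meta V table with `name`, `crss_offset`, `ends_ta` (e.g.
#'   `locus$v`).
#' @param productivity_table output of [productivity_by_vh()].
#' @return list with `per_v`, `median_crss`, `median_no_crss`, `test`
#'   (`NULL` when either group has fewer than 2 members).
#' @export
crss_productivity_association <- function(v_meta, productivity_table) {
  per_v <- merge(productivity_table,
                 data.frame(v_call = v_meta$name,
                            has_crss = !is.na(v_meta$crss_offset),
                            ends_ta = v_meta$ends_ta,
                            stringsAsFactors = FALSE),
                 by = "v_call")
  a <- per_v$frac_productive[per_v$has_crss]
  b <- per_v$frac_productive[!per_v$has_crss]
  test <- if (length(a) >= 2L && length(b) >= 2L) welch_t(a, b) else NULL
  list(per_v = per_v,
       median_crss = if (length(a)) median(a) else NA_real_,
       median_no_crss = if (length(b)) median(b) else NA_real_,
       test = test)
}
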