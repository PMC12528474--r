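#' Developmental-selection parameters
#'
#' Parameters of the selection model layered on top of VDJ recombination:
#' D-mu arrest of cells carrying a reading-frame-2 DJ allele in the second
#' recombination wave, surrogate-light-chain (SLC) pairing of mu-chains, and
#' VH-replacement (VHR) of stalled cells.
#'
#' The composed pairing probability for a productive allele is
#' `clip(base_pair_p * vh_pair_mult[v] * jh_short_mult * prod(residue_mults))`
#' where the JH multiplier applies only to the designated families
#' (`short_jh_families`) recombined to the short JH (`short_jh`), and residue
#' multipliers are keyed `"position:aa"` over CDR3 positions numbered from
#' 97. `base_pair_p` defaults to 0.5: about half of new mu-chains fail to
#' pair with the SLC.
#'
#' @param dmu_arrest_p probability that an RF2 DJ allele arrests the cell in
#'   wave 2 (no arrest in wave 1, never in muMT mode).
#' @param base_pair_p baseline SLC-pairing probability.
#' @param vh_pair_mult named per-V pairing multipliers (missing V = 1).
#' @param jh_short_mult multiplier for the short JH on designated families.
#' @param short_jh,short_jh_families the JH and families the multiplier
#'   applies to.
#' @param residue_mults named multipliers keyed `"position:aa"`.
#' @param vhr_rate per-step VH-replacement attempt probability for stalled
#'   cells.
#' @param vhr_rate_nonproductive_mult relative VHR propensity of
#'   non-productive alleles (which exit quickly via the NMD shortcut).
#' @param insertion_range allowed signal-joint insertion lengths (nt).
#' @param mumt_mode muMT mice: membrane mu cannot signal, so all
#'   signalling-dependent transitions (pairing, progression, arrest, death
#'   of double-non-productive cells, allelic exclusion) are blocked and VHR
#'   proceeds at `vhr_rate * mumt_vhr_mult` in a single window.
#' @param mumt_vhr_mult calibration multiplier for the muMT VHR rate.
#' @param tau1 decay constant (in locus ranks) of the wave-1 proximal bias.
#' @param large_preb_frac fraction of progressed cells sampled while still
#'   large pre-B.
#' @param allow_repeat_replacement may a replaced allele be replaced again?
#' @return list of class `selection_params`.
#' @export
selection_params <- function(dmu_arrest_p = 0.9, base_pair_p = 0.5,
                             vh_pair_mult = numeric(), jh_short_mult = 0.3,
                             short_jh = c("JH2", "JH3"),
                             short_jh_families = c("VH2", "VH3", "VH5"),
                             residue_mults = c("97:G" = 0.3, "98:S" = 0.5,
                                               "98:K" = 0.5, "99:H" = 1.8,
                                               "101:Y" = 1.6, "101:T" = 0.4),
                             vhr_rate = 0.15,
                             vhr_rate_nonproductive_mult = 0.25,
                             insertion_range = 0:4, mumt_mode = FALSE,
                             mumt_vhr_mult = 0.4, tau1 = 2.0,
                             large_preb_frac = 0.35,
                             allow_repeat_replacement = FALSE) {
  stopifnot(dmu_arrest_p >= 0, dmu_arrest_p <= 1,
            base_pair_p >= 0, base_pair_p <= 1,
            vhr_rate >= 0, vhr_rate <= 1, all(vh_pair_mult >= 0),
            all(residue_mults >= 0), all(insertion_range >= 0))
  structure(as.list(environment()), class = "selection_params")
}

#' Selection parameters with the default planted effects for a locus
#'
#' The baseline study conditions: the most D-proximal V gene is given a
#' strong pairing deficit (multiplier 0.05, the VH5-2/81X analogue); all
#' other selection acts through the generic defaults of
#' [selection_params()].
#'
#' @param locus a [germline_locus].
#' @param ... passed to [selection_params()].
#' @return a `selection_params` object.
#' @export
default_selection_params <- function(locus, ...) {
  v <- locus$v
  mult <- setNames(rep(1, nrow(v)), v$name)
  mult[v$name[v$locus_rank == 1L]] <- 0.05
  selection_params(vh_pair_mult = mult, ...)
}

# vectorised pairing probability; NA-safe on cdr3
pairing_prob_vec <- function(v_name, j_name, cdr3, params, locus) {
  v <- locus$v
  fam <- v$family[match(v_name, v$name)]
  p <- rep(params$base_pair_p, length(v_name))
  vm <- params$vh_pair_mult
  if (length(vm)) {
    m <- unname(vm[v_name]); m[is.na(m)] <- 1
    p <- p * m
  }
  short <- !is.na(fam) & fam %in% params$short_jh_families &
    j_name %in% params$short_jh
  p[short] <- p[short] * params$jh_short_mult
  rm_ <- params$residue_mults
  if (length(rm_)) {
    for (k in names(rm_)) {
      kp <- strsplit(k, ":", fixed = TRUE)[[1]]
      i <- as.integer(kp[1]) - 96L
      hit <- !is.na(cdr3) & nchar(cdr3) >= i & substr(cdr3, i, i) == kp[2]
      p[hit] <- p[hit] * rm_[[k]]
    }
  }
  pmin(pmax(p, 0), 1)
}

#' SLC-pairing probability of a productive allele
#'
#' @param allele a single allele (list or one-row data frame) with `v_name`,
#'   `j_name` and `productive`.
#' @param cdr3 CDR3 peptide (positions numbered from 97), or `NA`.
#' @param params a [selection_params].
#' @param locus a [germline_locus].
#' @return probability in `[0, 1]`.
#' @export
slc_pairing_prob <- function(allele, cdr3, params, locus) {
  if (!isTRUE(allele$productive)) {
    stop("slc_pairing_prob requires a productive allele", call. = FALSE)
  }
  pairing_prob_vec(allele$v_name, allele$j_name, cdr3, params, locus)
}

#' D-mu arrest of a cell
#'
#' A cell carrying a DJ allele in reading frame 2 expresses the truncated
#' D-mu protein and arrests, but only once D-mu has had time to accumulate:
#' wave 1 never arrests, wave 2 arrests with probability `dmu_arrest_p`.
#' muMT cells never arrest (D-mu selection requires membrane signalling).
#'
#' @param cell list with `stage` and `alleles` (data frame with `status` and
#'   `d_rf_dj`).
#' @param params a [selection_params].
#' @param wave 1 or 2.
#' @return the cell, possibly with `stage = "arrested"`.
#' @export
apply_dmu_arrest <- function(cell, params, wave) {
  if (wave < 2L || params$mumt_mode) return(cell)
  has_rf2_dj <- any(cell$alleles$status == "dj" & cell$alleles$d_rf_dj == 2L)
  if (has_rf2_dj && runif(1) < params$dmu_arrest_p) cell$stage <- "arrested"
  cell
}

# --- VH replacement --------------------------------------------------------
# Batch replacement over allele-table rows `idx`. A recipient is eligible
# when its V carries a cryptic RSS that survived junctional trimming and a
# more distal donor exists. The donor is drawn uniformly from strictly
# distal V genes; the new allele keeps the recipient's V-D insert and D-J
# junction exactly, prefixed by the donor coding sequence plus the recipient
# remnant 3' of the cryptic heptamer (the footprint). A signal-joint
# excision circle is emitted for every replacement.
vhr_batch <- function(al, idx, rate, locus, params) {
  empty <- list(al = al, circles = NULL, replaced = integer())
  if (length(idx) == 0L || all(rate == 0)) return(empty)
  v <- locus$v
  vi <- al$v_idx[idx]
  crss <- v$crss_offset[vi]
  eligible <- !is.na(crss) & nchar(al$v_part[idx]) >= crss + 7L &
    v$locus_rank[vi] < max(v$locus_rank) &
    (params$allow_repeat_replacement | is.na(al$replaced_from[idx]))
  do <- eligible & runif(length(idx)) < rate
  sel <- idx[do]
  if (length(sel) == 0L) return(empty)
  vi <- al$v_idx[sel]
  crss <- v$crss_offset[vi]
  rank <- v$locus_rank[vi]
  donor_rank <- rank + vapply(max(v$locus_rank) - rank,
                              function(k) sample.int(k, 1L), integer(1))
  donor <- match(donor_rank, v$locus_rank)
  remnant <- substr(al$v_part[sel], crss + 8L, nchar(al$v_part[sel]))
  new_vpart <- paste0(v$coding_seq[donor], remnant)
  ev <- evaluate_alleles(new_vpart, v$cys_offset[donor], al$vd_insert[sel],
                         al$d_kept[sel], al$d_trim5[sel], al$dj_insert[sel],
                         al$j_kept[sel], al$j_idx[sel], al$j_trim5[sel], locus)
  ins_len <- sample(params$insertion_range, length(sel), replace = TRUE)
  ins <- rand_dna_vec(ins_len)
  circles <- data.frame(
    cell_id = al$cell_id[sel],
    recipient_v = al$v_name[sel], donor_v = v$name[donor],
    recipient_rank = rank, donor_rank = donor_rank,
    insertion = ins, insertion_len = ins_len,
    circle_seq = paste0(substr(v$coding_seq[vi], 1L, crss + 7L), ins,
                        v$rss_heptamer[donor], v$intergenic_3p[donor]),
    stringsAsFactors = FALSE
  )
  al$replaced_from[sel] <- al$v_name[sel]
  al$v_idx[sel] <- donor
  al$v_name[sel] <- v$name[donor]
  al$v_part[sel] <- new_vpart
  al$v_trim[sel] <- 0L
  for (cn in colnames(ev)) al[[cn]][sel] <- ev[[cn]]
  list(al = al, circles = circles, replaced = sel)
}

#' Attempt VH replacement on one allele
#'
#' With probability `vhr_rate` (times `vhr_rate_nonproductive_mult` for a
#' non-productive allele) the allele's V is replaced by a donor drawn
#' uniformly from strictly more distal V genes, invading at the cryptic RSS.
#' A recipient without a (surviving) cryptic RSS, or with no distal donor
#' available, is always returned unchanged.
#'
#' @param cell list with at least `stage` and `cell_id`.
#' @param allele one-row allele data frame (as produced by
#'   [draw_vdj_batch()], with a `cell_id` column).
#' @param locus a [germline_locus].
#' @param params a [selection_params].
#' @return list with `allele` (possibly replaced), `circle` (one-row data
#'   frame or `NULL`) and `replaced` (logical).
#' @export
attempt_vh_replacement <- function(cell, allele, locus, params) {
  if (cell$stage %in% c("arrested", "dead")) {
    return(list(allele = allele, circle = NULL, replaced = FALSE))
  }
  rate <- params$vhr_rate *
    if (isTRUE(allele$productive)) 1 else params$vhr_rate_nonproductive_mult
  if (is.null(allele$cell_id)) allele$cell_id <- cell$cell_id %||% NA_integer_
  if (is.null(allele$replaced_from)) allele$replaced_from <- NA_character_
  res <- vhr_batch(allele, 1L, rate, locus, params)
  list(allele = res$al, circle = res$circles,
       replaced = length(res$replaced) > 0L)
}

# placeholder allele-2 rows: DJ-only state
dj_placeholder <- function(dj, cell_id) {
  data.frame(
    v_idx = NA_integer_, v_name = NA_character_, d_name = dj$d_name,
    j_name = dj$j_name, v_trim = NA_integer_, v_part = "",
    vd_insert = "", d_trim5 = 0L, d_trim3 = dj$d_trim3, d_kept = dj$d_kept,
    dj_insert = dj$dj_insert, j_kept = dj$j_kept, j_idx = dj$j_idx,
    j_trim5 = dj$j_trim5, d_rf_dj = dj$d_rf_dj,
    seq = paste0(dj$d_kept, dj$dj_insert, dj$j_kept),
    frame_shift = NA_integer_, has_stop = NA, productive = NA,
    d_rf = NA_integer_, cdr3_aa = NA_character_, cdr3_resolved = FALSE,
    junction_nt = NA_character_, cell_id = cell_id, allele_no = 2L,
    status = "dj", wave = 1L, replaced_from = NA_character_, pairing = NA,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of developing B cells
#'
#' Runs the full generative model: DJ joining on both alleles, a
#' proximal-biased first wave of V-to-DJ recombination (weights
#' proportional to `exp(-locus_rank / tau1)`), SLC-pairing of productive
#' mu-chains, D-mu arrest at wave-2 entry, the NMD shortcut routing
#' non-productive first alleles to a flat-weight second-allele attempt,
#' stalling of productive non-pairing cells with VH-replacement
#' eligibility over `n_steps` attempts, allelic exclusion on pairing, and
#' death of cells exhausting both alleles. In muMT mode all
#' signalling-dependent transitions are blocked: cells recombine both
#' alleles, stay pro-B, and attempt VHR once at a reduced rate.
#'
#' @param locus a [germline_locus].
#' @param jparams a [junction_params].
#' @param sparams a [selection_params].
#' @param n_cells number of cells.
#' @param n_steps stall duration (VHR attempts) for non-pairing cells.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a `bcell_population`: list with `cells`, `alleles`, `circles`.
#' @export
simulate_cohort <- function(locus, jparams = junction_params(),
                            sparams = selection_params(), n_cells,
                            n_steps = 3L, seed = 1L) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  n <- as.integer(n_cells)
  v <- locus$v
  n_v <- nrow(v)
  w1 <- exp(-v$locus_rank / sparams$tau1)
  mumt <- sparams$mumt_mode

  dj1 <- draw_dj_batch(n, locus, jparams)
  dj2 <- draw_dj_batch(n, locus, jparams)
  v1 <- sample.int(n_v, n, replace = TRUE, prob = w1)
  a1 <- draw_vdj_batch(locus, v1, dj1, jparams)
  a1$cell_id <- seq_len(n); a1$allele_no <- 1L; a1$status <- "vdj"
  a1$wave <- 1L; a1$replaced_from <- NA_character_; a1$pairing <- NA
  a2 <- dj_placeholder(dj2, seq_len(n))

  stage <- rep("pro-B", n)
  stalled <- logical(n)
  excluded <- logical(n)
  circles <- list()

  progress <- function(cells_idx) {
    k <- length(cells_idx)
    if (k == 0L) return()
    st <- ifelse(runif(k) < sparams$large_preb_frac, "large pre-B", "small pre-B")
    stage[cells_idx] <<- st
    excluded[cells_idx] <<- TRUE
    stalled[cells_idx] <<- FALSE
  }
  pair_and_route <- function(al, rows) {
    # draws pairing for productive alleles among `rows`; progresses pairers
    if (length(rows) == 0L) return(al)
    pp <- pairing_prob_vec(al$v_name[rows], al$j_name[rows],
                           al$cdr3_aa[rows], sparams, locus)
    ok <- al$productive[rows] %in% TRUE
    pair <- ok & runif(length(rows)) < pp
    al$pairing[rows] <- ifelse(ok, pair, NA)
    progress(al$cell_id[rows][pair])
    al
  }

  if (!mumt) {
    ## wave 1: pairing of productive first alleles
    a1 <- pair_and_route(a1, seq_len(n))
    ## wave-2 entry: D-mu arrest for cells with an RF2 DJ second allele
    rem <- which(stage == "pro-B")
    rf2 <- a2$d_rf_dj[rem] == 2L
    arr <- rem[rf2 & runif(length(rem)) < sparams$dmu_arrest_p]
    stage[arr] <- "arrested"
    ## stall loop on allele 1: productive non-pairing cells attempt VHR
    for (step in seq_len(n_steps)) {
      st <- which(stage == "pro-B" & a1$productive %in% TRUE &
                    a1$pairing %in% FALSE)
      stalled[st] <- TRUE
      res <- vhr_batch(a1, st, sparams$vhr_rate, locus, sparams)
      a1 <- res$al
      circles <- c(circles, list(res$circles))
      a1 <- pair_and_route(a1, res$replaced)
    }
    ## NMD shortcut: non-productive first alleles get one brief VHR window
    nmd <- which(stage == "pro-B" & !(a1$productive %in% TRUE))
    res <- vhr_batch(a1, nmd,
                     sparams$vhr_rate * sparams$vhr_rate_nonproductive_mult,
                     locus, sparams)
    a1 <- res$al
    circles <- c(circles, list(res$circles))
    a1 <- pair_and_route(a1, res$replaced)
    ## second-allele recombination, flat wave-2 weights
    sec <- which(stage == "pro-B" & !(a1$productive %in% TRUE))
    if (length(sec)) {
      v2 <- sample.int(n_v, length(sec), replace = TRUE)
      a2v <- draw_vdj_batch(locus, v2, dj2[sec, , drop = FALSE], jparams)
      a2v$cell_id <- sec; a2v$allele_no <- 2L; a2v$status <- "vdj"
      a2v$wave <- 2L; a2v$replaced_from <- NA_character_; a2v$pairing <- NA
      a2[sec, ] <- a2v[, colnames(a2)]
      a2 <- pair_and_route(a2, sec)
      for (step in seq_len(n_steps)) {
        st <- which(stage == "pro-B" & a2$status == "vdj" &
                      a2$productive %in% TRUE & a2$pairing %in% FALSE)
        stalled[st] <- TRUE
        res <- vhr_batch(a2, st, sparams$vhr_rate, locus, sparams)
        a2 <- res$al
        circles <- c(circles, list(res$circles))
        a2 <- pair_and_route(a2, res$replaced)
      }
      ## one VHR window for non-productive second alleles, then death
      np2 <- which(stage == "pro-B" & a2$status == "vdj" &
                     !(a2$productive %in% TRUE))
      res <- vhr_batch(a2, np2,
                       sparams$vhr_rate * sparams$vhr_rate_nonproductive_mult,
                       locus, sparams)
      a2 <- res$al
      circles <- c(circles, list(res$circles))
      a2 <- pair_and_route(a2, res$replaced)
      dead <- which(stage == "pro-B" & !(a1$productive %in% TRUE) &
                      a2$status == "vdj" & !(a2$productive %in% TRUE))
      stage[dead] <- "dead"
    }
  } else {
    ## muMT: no signalling; both alleles recombine, everything stays pro-B
    v2 <- sample.int(n_v, n, replace = TRUE)
    a2v <- draw_vdj_batch(locus, v2, dj2, jparams)
    a2v$cell_id <- seq_len(n); a2v$allele_no <- 2L; a2v$status <- "vdj"
    a2v$wave <- 2L; a2v$replaced_from <- NA_character_; a2v$pairing <- NA
    a2 <- a2v[, colnames(a2)]
    for (al_name in c("a1", "a2")) {
      al <- get(al_name)
      rate <- sparams$vhr_rate * sparams$mumt_vhr_mult *
        ifelse(al$productive %in% TRUE, 1, sparams$vhr_rate_nonproductive_mult)
      res <- vhr_batch(al, seq_len(n), rate, locus, sparams)
      assign(al_name, res$al)
      circles <- c(circles, list(res$circles))
    }
  }

  alleles <- rbind(a1, a2)
  alleles$stage <- stage[alleles$cell_id]
  circles <- do.call(rbind, circles[!vapply(circles, is.null, logical(1))])
  if (is.null(circles)) {
    circles <- data.frame(cell_id = integer(), recipient_v = character(),
                          donor_v = character(), recipient_rank = integer(),
                          donor_rank = integer(), insertion = character(),
                          insertion_len = integer(), circle_seq = character(),
                          stringsAsFactors = FALSE)
  }
  cells <- data.frame(cell_id = seq_len(n), stage = stage, stalled = stalled,
                      allelically_excluded = excluded,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, alleles = alleles, circles = circles,
                 locus_name = locus$name, seed = seed, mumt_mode = mumt,
                 n_steps = n_steps),
            class = "bcell_population")
}

#' @export
print.bcell_population <- function(x, ...) {
  tab <- table(x$cells$stage)
  cat(sprintf("bcell_population: %d cells (seed %d%s)\n", nrow(x$cells),
              x$seed, if (x$mumt_mode) ", muMT" else ""))
  for (s in names(tab)) cat(sprintf("  %-12s %d\n", s, tab[[s]]))
  cat(sprintf("  VH-replacement circles: %d\n", nrow(x$circles)))
  invisible(x)
}

#' Extract the VDJ (or DJ) repertoire of chosen stages
#'
#' @param pop a `bcell_population`.
#' @param stages stage labels to include; the default pro-B snapshot
#'   includes arrested cells, which remain in the pro-B compartment.
#' @param status `"vdj"`, `"dj"` or both.
#' @return allele data frame.
#' @export
repertoire <- function(pop, stages = c("pro-B", "arrested"),
                       status = "vdj") {
  al <- pop$alleles
  al[al$stage %in% stages & al$status %in% status & al$stage != "dead", ,
     drop = FALSE]
}
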