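mini_rows <- function(v, j = "JH1", productive = TRUE, cdr3 = "ARHY",
                      stage = "pro-B", d_rf = 1L, stop = FALSE, fs = 0L,
                      family = sub("-.*", "", v)) {
  data.frame(v_call = v, j_call = j, v_family = family,
             productive = productive, stop_codon = stop, frame_shift = fs,
             d_rf = d_rf, cdr3_aa = cdr3, cdr3_resolved = !is.na(cdr3),
             stage = stage, stringsAsFactors = FALSE)
}

test_that("V frequency tables count, threshold and sum to one", {
  rows <- mini_rows(c("A", "A", "B", "C"))
  f <- vh_frequency(rows, min_freq = 0)
  expect_equal(setNames(f$freq, f$key), c(A = 0.5, B = 0.25, C = 0.25))
  expect_equal(sum(f$freq), 1)
  expect_true(all(f$denominator == 4))
  # threshold marks low-frequency V but keeps them in the denominator
  f2 <- vh_frequency(rows, min_freq = 0.3)
  expect_identical(f2$key[f2$kept], "A")
  expect_true(all(f2$denominator == 4))
  expect_equal(sum(f2$freq), 1)
  expect_warning(vh_frequency(rows, stage = "nonexistent"), "empty")
})

test_that("frequency statistics are merge-invariant over replicates", {
  loc <- toy_locus()
  pro <- truth_rows(repertoire(wt_pop()), loc)
  set.seed(41)
  idx <- runif(nrow(pro)) < 0.5
  rep1 <- pro[idx, ]; rep2 <- pro[!idx, ]
  pooled <- vh_frequency(pro)
  merged <- vh_frequency(rbind(rep1, rep2))
  expect_equal(merged, pooled)
  expect_equal(vh_family_by_jh(rbind(rep1, rep2)), vh_family_by_jh(pro))
  expect_equal(rf_and_stop_summary(rbind(rep1, rep2)),
               rf_and_stop_summary(pro))
})

test_that("selection fold handles drops, identities and absent keys", {
  a <- data.frame(key = c("V1", "V2", "V3"), freq = c(0.123, 0.5, 0.377))
  b <- data.frame(key = c("V1", "V2"), freq = c(0.005, 0.995))
  sf <- selection_fold(a, b)
  v1 <- sf[sf$key == "V1", ]
  expect_equal(v1$fold, 0.005 / 0.123, tolerance = 1e-12)
  expect_equal(v1$diff, -0.118)
  expect_equal(sf$fold[sf$key == "V3"], 0)
  same <- selection_fold(a, a)
  expect_true(all(same$fold == 1) && all(same$diff == 0))
  z <- selection_fold(data.frame(key = "V9", freq = 0), b)
  expect_true(z$fold_undefined[z$key == "V9"])
})

test_that("family-by-JH matrix is a partition of the repertoire", {
  rows <- mini_rows(rep("F1-1", 4))
  m <- vh_family_by_jh(rows)
  expect_equal(unname(m["F1", "JH1"]), 1)
  loc <- toy_locus()
  pro <- truth_rows(repertoire(wt_pop()), loc)
  m2 <- vh_family_by_jh(pro)
  expect_equal(sum(m2), 1)
  fam_tot <- vh_frequency(pro, key = "v_family", min_freq = 0)
  expect_equal(rowSums(m2)[fam_tot$key], setNames(fam_tot$freq, fam_tot$key))
})

test_that("residue frequencies use resolved positions and exclusions", {
  rows <- rbind(mini_rows(rep("V1", 3), cdr3 = c("GRH", "ARH", "AR")),
                mini_rows("V2", cdr3 = "GKHY"))
  r <- residue_freq_at(rows, 97, "G")
  expect_equal(r$freq, 0.5) # 2 of 4 resolve G at 97
  r2 <- residue_freq_at(rows, 100, "Y")
  expect_equal(r2$n_resolved, 1) # only the 4-mer reaches position 100
  r3 <- residue_freq_at(rows, 97, "G", exclude_v = "V2")
  expect_equal(r3$n_residue, 1)
  expect_warning(
    residue_freq_at(rows[nchar(rows$cdr3_aa) < 3, ], 99, "H",
                    group_by = "v_call"),
    "never resolved")
})

test_that("positional deltas are zero-sum and recover a planted shift", {
  rows_a <- rbind(mini_rows(rep("V5-1", 50), cdr3 = "ARHY", family = "VH5"),
                  mini_rows(rep("V5-1", 50), cdr3 = "ARGY", family = "VH5"))
  pd0 <- positional_delta(rows_a, rows_a, families = "VH5")
  expect_true(all(pd0$delta == 0))
  rows_b <- rbind(mini_rows(rep("V5-1", 80), cdr3 = "ARHY", family = "VH5"),
                  mini_rows(rep("V5-1", 20), cdr3 = "ARGY", family = "VH5"))
  pd <- positional_delta(rows_a, rows_b, families = "VH5")
  h99 <- pd[pd$position == 99 & pd$aa == "H", ]
  expect_gt(h99$delta, 0)
  for (p in unique(pd$position)) {
    expect_equal(sum(pd$delta[pd$position == p]), 0, tolerance = 1e-9)
  }
})

test_that("reading-frame and stop summaries compute simple fractions", {
  rows <- mini_rows(rep("V1", 10), d_rf = 2L,
                    stop = c(TRUE, rep(FALSE, 9)))
  s <- rf_and_stop_summary(rows)
  expect_equal(s$rf_freq$freq[s$rf_freq$d_rf == 2], 1)
  expect_equal(s$stop_by_rf$frac_stop[s$stop_by_rf$d_rf == 2], 0.1)
  # a junction model with no N additions and stop-free segments in RF1
  # produces no de novo stops
  loc <- toy_locus()
  zero <- junction_params(trim_p = 1, trim_max = 0, n_lambda = 0,
                          n_max = 0, p_nuc_max = 0)
  set.seed(17)
  dj <- draw_dj_batch(400, loc, zero)
  vdj <- draw_vdj_batch(loc, rep(2L, 400), dj, zero)
  rows2 <- data.frame(v_call = vdj$v_name, j_call = vdj$j_name,
                      v_family = "VH2", productive = vdj$productive,
                      stop_codon = vdj$has_stop,
                      frame_shift = vdj$frame_shift, d_rf = vdj$d_rf,
                      cdr3_aa = vdj$cdr3_aa,
                      cdr3_resolved = vdj$cdr3_resolved, stage = "pro-B")
  s2 <- rf_and_stop_summary(rows2)
  rf1 <- s2$stop_by_rf[s2$stop_by_rf$d_rf == 1, ]
  expect_equal(rf1$n_stop, 0L)
})

test_that("CDR3 biophysics match the standard definitions", {
  b <- cdr3_biophysics(c("RR", "AAAA", "AV", "DKE"))
  expect_equal(b$net_charge, c(2, 0, 0, -1))
  expect_equal(b$aliphatic_index[2], 100)
  expect_equal(b$gravy[3], (1.8 + 4.2) / 2)
  x <- cdr3_biophysics("AXA")
  expect_true(x$nonstandard)
  expect_equal(x$gravy, 1.8)
})

test_that("weighted logos mix D translations by usage", {
  loc <- toy_locus()
  d <- loc$d
  m1 <- weighted_logo(d[1, ], c(1), rf = 1)
  pep <- strsplit(d$rf1_peptide[1], "")[[1]]
  for (p in seq_along(pep)) expect_equal(unname(m1[pep[p], p]), 1)
  expect_true(all(colSums(m1) <= 1 + 1e-12))
  # equal weights split a differing position 0.5/0.5
  m2 <- weighted_logo(d[1:2, ], c(0.5, 0.5), rf = 1)
  expect_true(all(abs(colSums(m2)[1:4] - 1) < 1e-12))
  p1 <- strsplit(d$rf1_peptide[1], "")[[1]]
  p2 <- strsplit(d$rf1_peptide[2], "")[[1]]
  diffpos <- which(p1[seq_along(p2)] != p2)[1]
  expect_equal(unname(m2[p1[diffpos], diffpos]), 0.5)
  # a stop codon in the frame renders an X column
  m3 <- weighted_logo(d[2, ], c(1), rf = 3)
  expect_true("X" %in% rownames(m3))
  expect_error(weighted_logo(d[1:2, ], c(0.9, 0.2), rf = 1), "sum to 1")
})

test_that("linear R^2 and the Welch test match their closed forms", {
  x <- 1:20
  expect_equal(linear_r2(x, 2 * x + 1), 1)
  expect_warning(r <- linear_r2(x, rep(3, 20)), "zero variance")
  expect_true(is.na(r))
  set.seed(30)
  xn <- rnorm(10000); yn <- rnorm(10000)
  expect_lt(linear_r2(xn, yn), 0.05)

  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welch_t(a, b)
  # direct Welch formulas
  se2 <- var(a) / 3 + var(b) / 5
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(w$t, t_manual)
  expect_equal(w$df, df_manual)
  expect_equal(w$p, p_manual)
  w0 <- welch_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_lt(welch_t(a, b + 1000)$p, 1e-6)
  expect_error(welch_t(1, b), "n >= 2")
})

test_that("cRSS-productivity association reports groups and degenerate cases", {
  v_meta <- data.frame(name = c("V1", "V2", "V3", "V4"),
                       crss_offset = c(10L, 12L, NA, NA),
                       ends_ta = c(FALSE, FALSE, TRUE, FALSE))
  pt <- data.frame(v_call = c("V1", "V2", "V3", "V4"), n = rep(100L, 4),
                   n_productive = c(20L, 25L, 60L, 70L),
                   frac_productive = c(0.2, 0.25, 0.6, 0.7),
                   low_n = rep(FALSE, 4))
  res <- crss_productivity_association(v_meta, pt)
  expect_lt(res$median_crss, res$median_no_crss)
  expect_true(res$per_v$ends_ta[res$per_v$v_call == "V3"])
  # all V in one group: comparison absent
  res1 <- crss_productivity_association(v_meta[1:2, ], pt[1:2, ])
  expect_null(res1$test)
})
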