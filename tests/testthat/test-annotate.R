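test_that("UMI deduplication keys on UMI and sequence length", {
  r <- data.frame(
    id = paste0("r", 1:6),
    seq = c("ACGTACGT", "ACGTACGT", "ACGTACGA", "ACGTACGTA", "TTTT", "GGGG"),
    qual = c("IIIIIIII", "IIIIIIII", "AAAAAAAA", "IIIIIIIII", "IIII", "IIII"),
    umi = c("AAAA", "AAAA", "AAAA", "AAAA", NA, "CCCC"),
    stringsAsFactors = FALSE)
  dd <- dedup_by_umi(r)
  # three same-UMI same-length reads collapse to one with count 3;
  # the 9-mer with the same UMI stays a separate molecule
  expect_identical(nrow(dd$molecules), 3L)
  m8 <- dd$molecules[nchar(dd$molecules$seq) == 8 &
                       dd$molecules$umi == "AAAA", ]
  expect_identical(m8$duplicate_count, 3L)
  # representative: highest mean quality, ties by lexicographic sequence
  expect_identical(m8$seq, "ACGTACGT")
  expect_identical(nrow(dd$sink), 1L)
})

test_that("pair merging reconstructs the fragment and rejects bad overlaps", {
  set.seed(10)
  frag <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  r1 <- data.frame(id = "p1", seq = substr(revcomp(frag), 1, 140),
                   qual = strrep("I", 140), umi = "ACGTACGTACGT",
                   stringsAsFactors = FALSE)
  r2 <- data.frame(id = "p1", seq = substr(frag, 1, 140),
                   qual = strrep("I", 140), stringsAsFactors = FALSE)
  mg <- merge_pairs(r1, r2, min_overlap = 30)
  expect_identical(mg$merged$seq, frag)
  expect_identical(mg$merged$umi, "ACGTACGTACGT")

  # disjoint mates never merge
  a <- data.frame(id = "x", seq = strrep("A", 50), qual = strrep("I", 50),
                  stringsAsFactors = FALSE)
  b <- data.frame(id = "x", seq = strrep("C", 50), qual = strrep("I", 50),
                  stringsAsFactors = FALSE)
  mg2 <- merge_pairs(a, b, min_overlap = 30)
  expect_identical(nrow(mg2$merged), 0L)
  expect_identical(mg2$unmerged, "x")

  # heavy mismatch in the only possible overlap stays unmerged at the
  # default 10% threshold
  x <- substr(frag, 1, 60)
  y <- x
  pos <- seq(2, 60, by = 2)
  for (p in pos) {
    substr(y, p, p) <- setdiff(c("A", "C", "G", "T"), substr(y, p, p))[1]
  }
  r1b <- data.frame(id = "z", seq = revcomp(y), qual = strrep("I", 60),
                    stringsAsFactors = FALSE)
  r2b <- data.frame(id = "z", seq = x, qual = strrep("I", 60),
                    stringsAsFactors = FALSE)
  mg3 <- merge_pairs(r1b, r2b, min_overlap = 60)
  expect_identical(nrow(mg3$merged), 0L)
})

test_that("reading-frame transposition is the expected cyclic permutation", {
  expect_identical(transpose_rf_imgt_to_ichihara(1L), 2L)
  expect_identical(transpose_rf_imgt_to_ichihara(2L), 3L)
  expect_identical(transpose_rf_imgt_to_ichihara(3L), 1L)
  x <- c(1L, 2L, 3L)
  expect_identical(
    transpose_rf_imgt_to_ichihara(
      transpose_rf_imgt_to_ichihara(transpose_rf_imgt_to_ichihara(x))), x)
  expect_error(transpose_rf_imgt_to_ichihara(4), "1, 2 or 3")
})

test_that("constructed rows annotate with the expected landmarks", {
  loc <- toy_locus()
  zero <- junction_params(trim_p = 1, trim_max = 0, n_lambda = 0, n_max = 0,
                          p_nuc_max = 0)
  set.seed(12)
  dj <- draw_dj_batch(60, loc, zero)
  vdj <- draw_vdj_batch(loc, rep(3L, 60), dj, zero)
  mol <- data.frame(id = sprintf("m%02d", 1:60), seq = vdj$seq,
                    stringsAsFactors = FALSE)
  ann <- annotate_molecules(mol, loc)
  rows <- ann$rearrangements
  expect_identical(rows$v_call, rep(loc$v$name[3], 60))
  expect_identical(rows$j_call, vdj$j_name)
  expect_identical(rows$frame_shift, vdj$frame_shift)
  expect_identical(rows$productive, vdj$productive)
  expect_identical(rows$cdr3_aa, vdj$cdr3_aa)

  # a DJ-only molecule keeps its J but has no V or productivity
  djm <- data.frame(id = "dj1",
                    seq = paste0(dj$d_kept[1], dj$dj_insert[1], dj$j_kept[1]),
                    stringsAsFactors = FALSE)
  rdj <- annotate_molecules(djm, loc)$rearrangements
  expect_true(is.na(rdj$v_call))
  expect_identical(rdj$j_call, dj$j_name[1])
  expect_true(is.na(rdj$productive))
  expect_identical(rdj$d_rf, dj$d_rf_dj[1])

  # scrambled sequence goes to the sink
  set.seed(13)
  scram <- data.frame(id = "s1",
                      seq = paste(sample(c("A", "C", "G", "T"), 150,
                                         replace = TRUE), collapse = ""),
                      stringsAsFactors = FALSE)
  sres <- annotate_molecules(scram, loc)
  expect_identical(nrow(sres$rearrangements), 0L)
  expect_identical(nrow(sres$sink), 1L)

  # trimming away the V-terminal Cys leaves the CDR3 unresolved
  v3 <- loc$v$coding_seq[3]
  cut <- substr(v3, 1, loc$v$cys_offset[3] - 1) # Cys codon destroyed
  molc <- data.frame(id = "c1",
                     seq = paste0(cut, dj$d_kept[1], dj$dj_insert[1],
                                  dj$j_kept[1]),
                     stringsAsFactors = FALSE)
  rc <- annotate_molecules(molc, loc)$rearrangements
  expect_false(rc$cdr3_resolved)
  expect_true(is.na(rc$cdr3_aa))
})

test_that("the full read path reproduces simulator truth", {
  loc <- toy_locus()
  pop <- wt_pop()
  reads <- emit_vdjseq_reads(pop, sampling_rate = 0.08, err_rate = 0.001,
                             dup_lambda = 0.6, seed = 3)
  truth <- reads$truth
  mg <- merge_pairs(reads$r1, reads$r2)
  dd <- dedup_by_umi(mg$merged)
  # dedup recovers the generator's molecule multiset
  expect_identical(nrow(dd$molecules), nrow(truth))
  expect_identical(sort(strip_umi(sub("_dup.*", "", dd$molecules$id))),
                   sort(truth$molecule_id))
  ann <- annotate_molecules(dd$molecules, loc, stage = "pro-B")
  rows <- ann$rearrangements
  m <- match(strip_umi(sub("_dup.*", "", rows$sequence_id)),
             truth$molecule_id)
  vdj <- truth$status[m] == "vdj"
  expect_gte(mean(rows$v_call[vdj] == truth$v_call[m][vdj], na.rm = TRUE),
             0.99)
  expect_gte(mean(rows$j_call == truth$j_call[m]), 0.99)
  hasd <- vdj & !is.na(truth$d_call[m]) & !is.na(rows$d_call)
  expect_gte(mean(rows$d_call[hasd] == truth$d_call[m][hasd]), 0.95)
  ok <- hasd & rows$d_call == truth$d_call[m]
  expect_gte(mean(rows$d_rf[ok] == truth$d_rf[m][ok]), 0.95)
  expect_gte(mean(rows$productive[vdj] == truth$productive[m][vdj],
                  na.rm = TRUE), 0.99)
  # substitution errors occasionally fall inside the CDR3 itself, so exact
  # identity is checked on error-free molecules elsewhere
  sel <- vdj & !is.na(truth$cdr3_aa[m]) & !is.na(rows$cdr3_aa)
  expect_gte(mean(rows$cdr3_aa[sel] == truth$cdr3_aa[m][sel]), 0.97)
  # every output row satisfies the productivity invariant
  pr <- rows$productive %in% TRUE
  expect_true(all(rows$frame_shift[pr] == 0L))
  expect_true(all(!rows$stop_codon[pr]))
})

test_that("error-free emission reconstructs source alleles exactly", {
  pop <- wt_pop()
  reads <- emit_vdjseq_reads(pop, sampling_rate = 0.01, err_rate = 0,
                             dup_lambda = 0, seed = 4)
  expect_identical(nrow(reads$r1), nrow(reads$truth))
  mg <- merge_pairs(reads$r1, reads$r2)
  m <- match(strip_umi(sub("_dup.*", "", mg$merged$id)),
             reads$truth$molecule_id)
  expect_identical(mg$merged$seq, reads$truth$seq[m])
  # duplicates enabled: more reads than distinct UMIs
  reads2 <- emit_vdjseq_reads(pop, sampling_rate = 0.01, err_rate = 0,
                              dup_lambda = 2, seed = 5)
  expect_gt(nrow(reads2$r1), length(unique(reads2$truth$umi)))
})

test_that("rearrangement tables round-trip through TSV", {
  loc <- toy_locus()
  pop <- wt_pop()
  reads <- emit_vdjseq_reads(pop, sampling_rate = 0.002, err_rate = 0,
                             seed = 6)
  mg <- merge_pairs(reads$r1, reads$r2)
  dd <- dedup_by_umi(mg$merged)
  rows <- annotate_molecules(dd$molecules, loc, stage = "pro-B")$rearrangements
  path <- tempfile(fileext = ".tsv")
  write_rearrangements(rows, path)
  back <- read_rearrangements(path)
  expect_identical(nrow(back), nrow(rows))
  expect_identical(back$v_call, rows$v_call)
  expect_identical(back$productive, rows$productive)
  expect_equal(back$duplicate_count, rows$duplicate_count)
})
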