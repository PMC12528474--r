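# --- configuration, manifests and end-to-end runs --------------------------

#' Default pipeline configuration
#'
#' Nested list of all tunable parameters; [load_config()] validates user
#' files against this structure and rejects unknown keys.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    locus = list(n_v = 12L, n_d = 3L, n_j = 4L, crss_fraction = 0.75,
                 ta_fraction = 0.1),
    junction = list(trim_p = 0.25, trim_max = 10L, n_lambda = 3,
                    n_max = 15L, p_nuc_max = 2L),
    selection = list(dmu_arrest_p = 0.9, base_pair_p = 0.5,
                     jh_short_mult = 0.3, vhr_rate = 0.15,
                     vhr_rate_nonproductive_mult = 0.25, mumt_mode = FALSE,
                     mumt_vhr_mult = 0.4, tau1 = 2.0,
                     large_preb_frac = 0.35, proximal_pair_mult = 0.05),
    sim = list(n_cells = 20000L, n_steps = 3L),
    vdjseq = list(sampling_rate = 0.05, read_len = 150L, err_rate = 0.001,
                  dup_lambda = 0.6),
    rcseq = list(germline_background = 20000L, per_circle_molecules = 3L,
                 read_len = 150L, err_rate = 0.001),
    detect = list(anchor_len = 60L, max_mm = 2L)
  )
}

#' Load and validate a configuration file
#'
#' YAML (or any nested mapping `yaml::read_yaml` accepts). Values override
#' the defaults; unknown keys raise an error naming them.
#'
#' @param path config file path, or `NULL` for the defaults.
#' @return nested list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- character()
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      unknown <- c(unknown, section)
      next
    }
    for (k in names(user[[section]])) {
      if (!k %in% names(cfg[[section]])) {
        unknown <- c(unknown, paste(section, k, sep = "."))
      } else {
        cfg[[section]][[k]] <- user[[section]][[k]]
      }
    }
  }
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

config_objects <- function(cfg, locus) {
  jp <- do.call(junction_params, cfg$junction)
  sl <- cfg$selection
  mult <- setNames(rep(1, nrow(locus$v)), locus$v$name)
  mult[locus$v$name[locus$v$locus_rank == 1L]] <- sl$proximal_pair_mult
  sp <- selection_params(
    dmu_arrest_p = sl$dmu_arrest_p, base_pair_p = sl$base_pair_p,
    vh_pair_mult = mult, jh_short_mult = sl$jh_short_mult,
    vhr_rate = sl$vhr_rate,
    vhr_rate_nonproductive_mult = sl$vhr_rate_nonproductive_mult,
    mumt_mode = isTRUE(sl$mumt_mode), mumt_vhr_mult = sl$mumt_vhr_mult,
    tau1 = sl$tau1, large_preb_frac = sl$large_preb_frac)
  list(jparams = jp, sparams = sp)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(outdir, command, cfg, seed, counts = list(),
                           files = character()) {
  manifest <- list(
    command = command,
    config_hash = config_hash(cfg),
    seed = seed,
    tool_version = as.character(utils::packageVersion("ighrepsel")),
    mumt_mode = isTRUE(cfg$selection$mumt_mode),
    files = as.list(files),
    counts = counts,
    config = cfg
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a cohort and write the library plus ground truth
#'
#' Deterministic per seed: writes the locus (FASTA + metadata), the
#' VDJseq-like paired FASTQ of the pro-B compartment, ground-truth tables
#' (cells, alleles, circles, molecules) and a run manifest echoing the
#' effective configuration, its hash and the seed.
#'
#' @param config nested config list (see [default_config()]) or a path.
#' @param seed integer seed (mandatory; the only entropy source).
#' @param outdir output directory (created).
#' @return invisibly, a list with the population, locus and file paths.
#' @export
cli_simulate <- function(config = NULL, seed, outdir) {
  cfg <- if (is.character(config)) load_config(config)
         else config %||% default_config()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  locus <- do.call(build_toy_locus, c(cfg$locus, list(seed = seed)))
  obj <- config_objects(cfg, locus)
  pop <- simulate_cohort(locus, obj$jparams, obj$sparams,
                         n_cells = cfg$sim$n_cells,
                         n_steps = cfg$sim$n_steps, seed = seed + 1L)
  reads <- do.call(emit_vdjseq_reads,
                   c(list(pop = pop), cfg$vdjseq, list(seed = seed + 2L)))
  paths <- c(
    locus_fasta = file.path(outdir, "locus.fasta"),
    locus_meta = file.path(outdir, "locus_meta.tsv"),
    r1 = file.path(outdir, "vdjseq_R1.fastq"),
    r2 = file.path(outdir, "vdjseq_R2.fastq"),
    cells = file.path(outdir, "truth_cells.tsv"),
    alleles = file.path(outdir, "truth_alleles.tsv"),
    circles = file.path(outdir, "truth_circles.tsv"),
    molecules = file.path(outdir, "truth_molecules.tsv")
  )
  write_locus(locus, paths["locus_fasta"], paths["locus_meta"])
  write_fastq(reads$r1, paths["r1"])
  write_fastq(reads$r2, paths["r2"])
  write.table(pop$cells, paths["cells"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  keep <- setdiff(colnames(pop$alleles), c("v_part", "d_kept", "j_kept"))
  write.table(pop$alleles[, keep], paths["alleles"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pop$circles, paths["circles"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(reads$truth, paths["molecules"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts <- list(cells = nrow(pop$cells),
                 stages = as.list(table(pop$cells$stage)),
                 molecules = nrow(reads$truth), circles = nrow(pop$circles))
  write_manifest(outdir, "simulate", cfg, seed, counts, paths)
  invisible(list(population = pop, locus = locus, reads = reads,
                 paths = paths))
}

#' Annotate a simulated library from disk
#'
#' Reads the paired FASTQ, merges mates, deduplicates by UMI and sequence
#' length, annotates against the locus reference and writes an AIRR-style
#' TSV plus per-stage count logs.
#'
#' @param outdir directory produced by [cli_simulate()].
#' @param stage stage label stored in the output rows.
#' @return invisibly, the rearrangement data frame.
#' @export
cli_annotate <- function(outdir, stage = "pro-B") {
  locus <- read_locus(file.path(outdir, "locus.fasta"),
                      file.path(outdir, "locus_meta.tsv"))
  r1 <- read_fastq(file.path(outdir, "vdjseq_R1.fastq"))
  r2 <- read_fastq(file.path(outdir, "vdjseq_R2.fastq"))
  mg <- merge_pairs(r1, r2)
  dd <- dedup_by_umi(mg$merged)
  ann <- annotate_molecules(dd$molecules, locus, stage = stage)
  write_rearrangements(ann$rearrangements,
                       file.path(outdir, "rearrangements.tsv"))
  counts <- data.frame(
    stage_label = stage, reads = nrow(r1), merged = nrow(mg$merged),
    unmerged = length(mg$unmerged), molecules = nrow(dd$molecules),
    no_umi = nrow(dd$sink), annotated = nrow(ann$rearrangements),
    discarded_no_j = nrow(ann$sink))
  write.table(counts, file.path(outdir, "annotate_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(ann$rearrangements)
}

#' Repertoire statistics bundle
#'
#' Writes per-V frequencies, per-V productivity, the reading-frame and
#' stop-codon summaries and the family-by-JH matrix for an annotated
#' rearrangement table.
#'
#' @param outdir directory holding `rearrangements.tsv`.
#' @return invisibly, the list of tables.
#' @export
cli_stats <- function(outdir) {
  rows <- read_rearrangements(file.path(outdir, "rearrangements.tsv"))
  vf <- vh_frequency(rows)
  pv <- productivity_by_vh(rows)
  rf <- rf_and_stop_summary(rows)
  fj <- vh_family_by_jh(rows)
  write.table(vf, file.path(outdir, "vh_frequency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pv, file.path(outdir, "productivity_by_vh.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rf$rf_freq, file.path(outdir, "rf_frequency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rf$stop_by_rf, file.path(outdir, "stop_by_rf.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(fj), file.path(outdir, "family_by_jh.tsv"),
              sep = "\t", quote = FALSE)
  invisible(list(vh_frequency = vf, productivity = pv, rf = rf,
                 family_by_jh = fj))
}

#' Excision-circle detection on an RCseq-like library
#'
#' Emits the RCseq library for the simulated circles, merges/deduplicates,
#' runs the main and fallback searches, curates, and writes the calls and
#' summaries.
#'
#' @param sim result of [cli_simulate()] (in memory) or its `outdir`.
#' @param outdir output directory.
#' @param seed integer seed.
#' @param config nested config list.
#' @return invisibly, the curated calls.
#' @export
cli_circles <- function(sim, outdir, seed, config = NULL) {
  cfg <- config %||% default_config()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  locus <- sim$locus
  circles <- sim$population$circles
  panel <- locus$v$name[!is.na(locus$v$crss_offset)]
  reads <- do.call(emit_rcseq_reads,
                   c(list(circles = circles, locus = locus,
                          primer_panel = panel), cfg$rcseq,
                     list(seed = seed)))
  mg <- merge_pairs(reads$r1, reads$r2)
  dd <- dedup_by_umi(mg$merged)
  calls <- detect_circles(dd$molecules, locus,
                          max_mm = cfg$detect$max_mm,
                          anchor_len = cfg$detect$anchor_len)
  summ <- summarize_circles(calls, locus)
  write.table(calls, file.path(outdir, "circle_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summ$recipient_map, file.path(outdir, "recipient_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summ$donor_map, file.path(outdir, "donor_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summ$insertion_hist, file.path(outdir, "insertion_hist.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Full pipeline: simulate, annotate, statistics, circle detection
#'
#' Runs every stage into `outdir` and stops with the failing stage's name
#' on error. A small set of in-run invariants is checked at the end (every
#' curated call donor-distal; planted circles with panel recipients
#' recovered); violation raises an error so that scripted runs exit
#' non-zero.
#'
#' @param config config list or path (see [load_config()]).
#' @param seed integer seed.
#' @param outdir output directory.
#' @return invisibly, a list with all stage outputs.
#' @export
cli_run_all <- function(config = NULL, seed, outdir) {
  cfg <- if (is.character(config)) load_config(config)
         else config %||% default_config()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  sim <- run_stage("simulate", cli_simulate(cfg, seed, outdir))
  rows <- run_stage("annotate", cli_annotate(outdir))
  stats <- run_stage("stats", cli_stats(outdir))
  calls <- run_stage("circles", cli_circles(sim, outdir, seed + 3L, cfg))
  cur <- calls[calls$curated %in% TRUE, , drop = FALSE]
  v <- sim$locus$v
  if (nrow(cur)) {
    dr <- v$locus_rank[match(cur$donor_v, v$name)]
    rr <- v$locus_rank[match(cur$recipient_v, v$name)]
    if (!all(dr > rr)) {
      stop("invariant violated: curated call with non-distal donor",
           call. = FALSE)
    }
  }
  truth_n <- nrow(sim$population$circles)
  if (truth_n > 0L && nrow(cur) == 0L && cfg$rcseq$err_rate == 0) {
    stop("invariant violated: planted circles present but none recovered",
         call. = FALSE)
  }
  invisible(list(sim = sim, rearrangements = rows, stats = stats,
                 calls = calls))
}
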