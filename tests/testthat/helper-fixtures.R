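# Shared fixtures, built once per session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

toy_locus <- function() {
  fixture("locus", build_toy_locus(n_v = 12, n_d = 3, n_j = 4,
                                   crss_fraction = 0.75, seed = 1))
}

wt_pop <- function() {
  fixture("wt_pop", simulate_cohort(toy_locus(), junction_params(),
                                    default_selection_params(toy_locus()),
                                    n_cells = 50000, seed = 7))
}

mumt_pop <- function() {
  fixture("mumt_pop", simulate_cohort(
    toy_locus(), junction_params(),
    default_selection_params(toy_locus(), mumt_mode = TRUE),
    n_cells = 50000, seed = 8))
}

# stats-ready rows straight from simulator truth (bypasses read emission)
truth_rows <- function(al, locus) {
  data.frame(
    v_call = al$v_name, d_call = al$d_name, j_call = al$j_name,
    v_family = locus$v$family[match(al$v_name, locus$v$name)],
    productive = al$productive, stop_codon = al$has_stop,
    frame_shift = al$frame_shift, d_rf = al$d_rf, cdr3_aa = al$cdr3_aa,
    cdr3_resolved = al$cdr3_resolved, stage = al$stage,
    stringsAsFactors = FALSE
  )
}

strip_umi <- function(ids) sub(" .*", "", ids)
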