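# Recovery cells shared between the acceptance tests.  Cells are computed on
# first use and cached for the session, so several tests can interrogate the
# same cell without re-running the MCMC.  Seeds are fixed so results are
# reproducible across runs.

cell_cache <- new.env(parent = emptyenv())

acceptance_grid_config <- function(reps = 30) {
  grid_config(reps = reps, seed = 20260101)
}

cached_cell <- function(s_true, recall_prob, reps = 30) {
  key <- sprintf("s%.4g_pr%.4g_r%d", s_true, recall_prob, reps)
  if (!is.null(cell_cache[[key]])) return(cell_cache[[key]])
  cfg <- acceptance_grid_config(reps)
  cseed <- as.integer((round(s_true * 1e4) * 131 + round(recall_prob * 100) * 17 + 7) %% 2147483629)
  cell <- suppressWarnings(run_cell(s_true, recall_prob, cfg, cseed = cseed))
  cell_cache[[key]] <- cell
  cell
}
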