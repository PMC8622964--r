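# Lazily computed full-sweep tables shared by the scaled-experiment tests
# (they are the expensive part of the suite; computing them once keeps the
# run short). Study conditions: interior width n = 8, horizon and penalty
# 2^8, 10 replicates per rule, 20 universality intervals, base seed 1.

.sweep_cache <- new.env(parent = emptyenv())

scaled_study_sweeps <- function() {
  if (is.null(.sweep_cache$sync)) {
    cfg <- measure_config(n = 8, runs = 10, seed = 1)
    .sweep_cache$cfg <- cfg
    .sweep_cache$sync <- sweep_all_rules("sync", cfg)
    .sweep_cache$at <- sweep_all_rules("at", cfg)
  }
  list(cfg = .sweep_cache$cfg, sync = .sweep_cache$sync,
       at = .sweep_cache$at)
}

scaled_async_fractions <- function() {
  if (is.null(.sweep_cache$async_grid)) {
    s <- scaled_study_sweeps()
    .sweep_cache$async_grid <-
      break_fraction_grid(s$sync, s$cfg, p_grid = seq(0.05, 1, by = 0.05),
                          m = 20)
  }
  .sweep_cache$async_grid
}
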