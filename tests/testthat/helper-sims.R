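# Shared expensive simulations, memoised across test files. The default-sheet
# S1-S2 runs take minutes each; every test that needs one draws it from here.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

default_mesh <- function() {
  cached("mesh", build_idealized_infarct_sheet(infarct_spec()))
}

# full default-sheet S1-S2 run at coupling interval `ci`. The 220 run needs a
# tail long enough for the re-entrant wave to reach the proximal mouth; the
# 250 run only needs to confirm capture.
sheet_sim <- function(ci) {
  cached(paste0("sheet_", ci), {
    prot <- pacing_protocol(s2_coupling = ci)
    run_monodomain(default_mesh(), tissue_params(), prot,
                   t_total = 1000 + ci + (if (ci <= 220) 1000 else 450))
  })
}

sheet_markers <- function(ci) {
  cached(paste0("markers_", ci), markers_from_crossings(sheet_sim(ci)))
}
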