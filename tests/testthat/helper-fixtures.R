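# Shared fixtures, all generated in code.

table_params <- function(i) {
  tr <- voi_microparameters()
  micro_params(tr$K1[i], tr$k2[i], tr$k3[i], tr$Vb[i])
}

default_aif <- function() feng_params(850, 22, 21, 4, 0.12, 0.01, 0)

# six-region phantom used by the clustering contract tests: equal-sized
# compact slabs, moderate voxel noise
clustering_phantom <- function(noise_scale = 0.05, seed = 7) {
  tissues <- c("GM", "GM", "GM", "WM", "WM", "WM")
  regions <- lapply(1:6, function(i)
    list(label = paste0("VOI", i), params = table_params(i),
         voxel_count = 240L, tissue = tissues[i]))
  spec <- phantom_spec(regions, default_aif(), human_frame_grid(),
                       noise_scale = noise_scale, seed = seed)
  generate_phantom_image(spec, shape = c(24, 10, 6))
}

assignment_accuracy <- function(cs, img) {
  lab <- cs$labels[img$masks$WB]
  truth <- img$labels[img$masks$WB]
  sum(apply(table(truth, lab), 1, max)) / length(truth)
}

# The full MDIF-SIME fit of the reference simulation is the most expensive
# computation in the suite; run it once and share the result.
.sime_cache <- new.env(parent = emptyenv())

reference_sime_fit <- function() {
  if (is.null(.sime_cache$fit)) {
    sim <- reference_simulation()
    prob <- sime_problem(sim$wb_tac, sim$region_tacs, sim$anchors,
                         R = sim$R, mode = "mdif")
    .sime_cache$sim <- sim
    .sime_cache$fit <- fit_sime_mdif(prob, n_starts = 8, seed = 1)
    w <- make_weights(sim$wb_tac$grid, sim$wb_tac)
    .sime_cache$refits <- lapply(sim$region_tacs, fit_standalone,
                                 cp = .sime_cache$fit$input_function,
                                 weights = w, R = 1)
  }
  .sime_cache
}
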