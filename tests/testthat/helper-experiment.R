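# The study-scale round-trip experiment shared by the self-validation and
# noise-robustness acceptance tests: default synthetic torso (3190 nodes,
# 128 electrodes, 740-sample beat), default pipeline.  Computed once per
# test run and cached.

study_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config()
    mesh <- build_synthetic_torso(cfg)
    K <- assemble_stiffness(mesh)
    layout <- synthetic_electrode_layout(mesh)
    gt <- simulate_epicardial_activation(mesh)
    fop <- forward_operator(mesh, K, gt$nodes)
    rec0 <- synthesize_recordings(mesh, gt, layout, forward_op = fop)
    M <- assemble_lumped_mass(mesh, "volume")
    basis <- solve_eigenpairs(K, M, k_modes = 240)
    res0 <- run_pipeline(mesh, rec0, layout, pipeline_config(),
                         basis = basis, K = K, verbose = FALSE)
    noise_sd <- 0.05 * sqrt(mean(rec0^2))
    rec5 <- synthesize_recordings(mesh, gt, layout, noise_sd = noise_sd,
                                  seed = 20260928L, forward_op = fop)
    res5 <- run_pipeline(mesh, rec5, layout, pipeline_config(),
                         basis = basis, K = K, verbose = FALSE)
    cache <<- list(mesh = mesh, K = K, layout = layout, gt = gt,
                   basis = basis, rec0 = rec0, res0 = res0,
                   rec5 = rec5, res5 = res5, noise_sd = noise_sd)
    cache
  }
})
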