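# The default simulated fixture (seed 7), computed once per test run and
# shared by the tests that interrogate it.
.fixture_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- sim_config(seed = 7)
    run <- run_pipeline(cfg)
    .fixture_env$fx <- list(config = cfg, run = run, calls = run$calls)
  }
  .fixture_env$fx
}
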