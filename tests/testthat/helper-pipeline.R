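## Shared full-model pipeline for the acceptance tests: run once per test
## session and cached. The three conditions (reference, acute LBBB,
## chronic LBBB), each with resting convergence and hyperemia, take
## several minutes together.

.pipeline_cache <- new.env(parent = emptyenv())

acceptancePipeline <- function() {
  if (!exists("runs", envir = .pipeline_cache)) {
    model <- coroModel(defaultConfig())
    ref <- runReference(model, quiet = TRUE)
    ac <- runAcuteLbbb(model, ref, quiet = TRUE)
    ch <- runChronicLbbb(model, ac, quiet = TRUE)
    assign("runs", list(model = model, ref = ref, ac = ac, ch = ch),
           envir = .pipeline_cache)
  }
  get("runs", envir = .pipeline_cache)
}
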