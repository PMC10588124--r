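# Heavy desk-scale experiments are trained once per test session and
# shared across the property blocks that examine them.

.exp_cache <- new.env(parent = emptyenv())

exp_get <- function(name, fun) {
  if (is.null(.exp_cache[[name]])) .exp_cache[[name]] <- fun()
  .exp_cache[[name]]
}

ctx_timing <- function() exp_get("timing", function()
  experiment_timing_recovery(seed = 1))

ctx_e2e <- function() exp_get("e2e", function()
  experiment_end_to_end(seed = 1, timing_model = ctx_timing()$model))

ctx_mixed <- function() exp_get("mixed", function()
  experiment_attention_localization(seed = 1))

ctx_dann <- function() exp_get("dann", function()
  experiment_domain_confusion(seed = 1))
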