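# Shared small trained pipeline, built lazily once per test run and reused
# by the model-dependent tests (LOSO structure, saliency, ON/OFF recovery).

.fixture_env <- new.env(parent = emptyenv())

fixture_pipeline <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  cc <- cohort_config(n_hc = 10, n_pd = 10, n_sessions_per_subject = 60, seed = 101)
  cohort <- sample_cohort(cc)
  inputs <- prepare_inputs(cohort$sessions)
  pre <- sample_cohort(cohort_config(n_hc = 8, n_pd = 4,
                                     n_sessions_per_subject = 40, seed = 202))
  pre_inputs <- prepare_inputs(pre$sessions)
  ae <- pretrain_autoencoder(pre_inputs,
                             autoencoder_config(epochs = 12, seed = 11))
  model31 <- fit_hybrid(inputs, cohort$subjects, ae,
                        finetune_config(31, epochs = 40, seed = 12))
  .fixture_env$fx <- list(config = cc, cohort = cohort, inputs = inputs,
                          encoder = ae, model31 = model31)
  .fixture_env$fx
}
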