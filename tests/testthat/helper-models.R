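## Shared micro-scale trained fixture: a small dataset and a model trained
## for a handful of epochs, built once per test run and reused by tests that
## need realistic (non-random) predictions. Sizes are deliberately tiny so
## the whole unit-test suite stays fast.

.fixtureEnv <- new.env(parent = emptyenv())

microSpec <- function() lesionSpec(imageSize = 64L, artifactProb = 0.5, seed = 1L)

microFixture <- function() {
    if (!is.null(.fixtureEnv$micro)) return(.fixtureEnv$micro)
    ds <- generateSamples(microSpec(), 40, seed = 400)
    mc <- modelConfig(cropSize = 48L, context = "aspp", seed = 5L)
    tc <- trainConfig(epochs = 8L, seed = 6L, cropSize = 48L, maxJitter = 20L)
    tr <- trainSBox(ds, initModel(mc), tc)
    mined <- mineHardExamples(tr$model, ds)
    tcc <- tc
    tcc@epochs <- 6L
    trained <- if (length(mined$subset) > 0L)
        trainClick(mined$subset, tr$model, tcc)$model else tr$model
    .fixtureEnv$micro <- list(dataset = ds, model = trained,
                              sboxModel = tr$model, mined = mined,
                              mc = mc, tc = tc, history = tr$history)
    .fixtureEnv$micro
}
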