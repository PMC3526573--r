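## Shared fixtures: a desk-scale generator configuration and a memoised
## small classifier so the pipeline tests train the forest only once.

# small frames with proportionally scaled colonies, strokes and cleanup
# thresholds so the full chain runs in well under a second per image
smallConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(size = c(128L, 128L), nColonies = c(1L, 3L),
         radiusRange = c(16, 34), strokeLength = c(10, 25),
         strokeWidth = c(2, 4), strokeDensity = 8e-4, seed = seed),
    list(...))
  do.call(generatorConfig, args)
}

smallFeatureArgs <- list(scales = 0.7 * c(1, 2, 4), epsilon = 0.11,
                        window = 13L)

smallPipelineConfig <- function() {
  pipelineConfig(scales = smallFeatureArgs$scales,
                 epsilon = smallFeatureArgs$epsilon,
                 window = smallFeatureArgs$window,
                 minObject = 200L, minHoleFill = 300L)
}

.fixtureCache <- new.env(parent = emptyenv())

# classifier trained on three small synthetic frames; built on first use
smallModel <- function() {
  if (is.null(.fixtureCache$model)) {
    ts <- makeTrainingSet(lapply(1:3, smallConfig), pixelsPerImage = 3000L,
                          scales = smallFeatureArgs$scales,
                          epsilon = smallFeatureArgs$epsilon,
                          window = smallFeatureArgs$window)
    .fixtureCache$model <- trainColonyClassifier(ts, seed = 7L)
  }
  .fixtureCache$model
}

smallFeatures <- function(img) {
  pixelFeatures(img, smallFeatureArgs$scales, smallFeatureArgs$epsilon,
                smallFeatureArgs$window)
}
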