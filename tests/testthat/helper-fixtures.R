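# Small pullback configurations used across the suite. Frame counts and
# image sizes are kept modest so every test builds its fixtures at run time.

# replace defaults wholesale by name (modifyList would merge into unnamed
# list elements such as normalRanges)
replaceArgs <- function(defaults, dots) {
  defaults[names(dots)] <- dots
  defaults
}

smallConfig <- function(...) {
  args <- replaceArgs(list(
    nFrames = 60L, nAlines = 96L, depthSamples = 96L,
    lumenRadiusMean = 1.05, lumenEccentricity = 0.1, lumenDrift = 0.05,
    plaqueRange = c(15L, 45L),
    normalRanges = list(c(0L, 10L), c(50L, 60L)),
    landmarkFrames = c(5L, 30L, 55L)), list(...))
  do.call(simConfig, args)
}

# minimal pipeline-sized simulation arguments (64 x 64 frames with the wall
# comfortably inside the depth range)
tinySimArgs <- function(...) {
  replaceArgs(list(
    nAlines = 64L, depthSamples = 64L, pixelPitch = 0.015,
    lumenRadiusMean = 0.9, lumenEccentricity = 0.1, lumenDrift = 0.05),
    list(...))
}

# deterministic variant: no detector noise, fixed per-frame amplitudes
cleanConfig <- function(...) {
  smallConfig(plaqueAmpSD = 0, normalAmpSD = 0, noiseSD = 0, octNoiseSD = 0,
              ...)
}

# frames x nA matrix whose per-frame maximum over A-lines equals maxima[f]
frameMaxMatrix <- function(maxima, nA = 8L) {
  t(vapply(maxima, function(v) v * c(1, rep(0.5, nA - 1L)), numeric(nA)))
}

defaultCurve <- function(mu = 1.5, dMax = 3) {
  compensationCurve(mu = mu, range = c(0, dMax))
}
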