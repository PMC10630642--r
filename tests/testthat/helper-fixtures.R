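# Shared fixtures, built in code.

# Small noiseless circle lesion scene.
circleScene <- function(radius = 10, size = 128L, gradient = 0) {
  scene <- sceneSpec(height = size, width = size, speckleSigma = 0,
                     illuminationGradient = gradient, seed = 1L)
  spec <- lesionSpec(center = c(size / 2, size / 2), radii = c(radius, radius),
                     borderIrregularity = 0, textureAmp = 0)
  c(renderLesion(spec, scene), list(spec = spec, scene = scene))
}

# A deterministic low-frequency test image in [0,1] (not flat, not noisy).
wavyImage <- function(nr = 64L, nc = 64L) {
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  0.5 + 0.25 * sin(r / 6) * cos(cc / 9)
}

# One shared backbone per test run (weights are seeded; building is the
# expensive part).
sharedBackbone <- local({
  bb <- NULL
  function() {
    if (is.null(bb)) bb <<- buildBackbone(backboneSpec(seed = 1L))
    bb
  }
})
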