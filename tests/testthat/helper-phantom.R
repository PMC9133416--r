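# Shared fixtures: reduced phantom parameter sets for fast unit tests
# (the acceptance tests use the package defaults).

smallParams <- function(seed = 42L, ...) {
  phantomParams(nPatients = 2L, energies = "80kV",
                noiseSdPerEnergy = c("80kV" = 20),
                contrastPerEnergy = c("80kV" = 1.0), seed = seed, ...)
}

# a rigid transform with a known axis-angle rotation (degrees) + translation
mkTransform <- function(axis, angleDeg, translation = c(0, 0, 0)) {
  RigidTransform(rotationAboutAxis(axis, angleDeg * pi / 180), translation)
}

rotationErrDeg <- function(a, b) {
  rotationAngle(t(a@rotation) %*% b@rotation) * 180 / pi
}

translationErr <- function(a, b) sqrt(sum((a@translation - b@translation)^2))
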