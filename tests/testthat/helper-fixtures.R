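# Fixtures are built in code; no binary data anywhere.

# Known [M-H]- m/z of common plant-phenolic reference standards, as printed
# by a 15 T FT-ICR instrument (5 dp).
standardIonMz <- function() {
  c("gentisic acid" = 153.01933,
    "gallic acid" = 169.01425,
    "caffeic acid" = 179.03498,
    "luteolin" = 285.04046,
    "kaempferol" = 285.04046,
    "quercetin" = 301.03538,
    "dihydroquercetin" = 303.05103,
    "chlorogenic acid" = 353.08781,
    "quercitrin" = 447.09329,
    "quercetin-3-o-glucoside" = 463.08820,
    "rutin" = 609.14611)
}

standardsTable <- function() {
  readFormulaTable(system.file("extdata", "antioxidant-standards.tsv",
                               package = "scampr"))
}

# A small deterministic peak set spread over a few fractions.
toyFractionSet <- function(seed = 7, n = 100, nFractions = 5) {
  withr::with_seed(seed, {
    FractionSet(data.frame(
      fraction = sample.int(nFractions, n, replace = TRUE),
      mz = runif(n, 120, 1200),
      intensity = rlnorm(n, 8, 1),
      snr = runif(n, 1, 50)), nFractions = nFractions)
  })
}

# Spectrum with known monoisotopic peaks and their 13C satellites, for the
# de-isotoping ground-truth check. Returns the FractionSet plus the set of
# monoisotopic m/z values that must survive.
isotopeSpectrum <- function(seed = 11, nCompounds = 30) {
  withr::with_seed(seed, {
    mz <- sort(runif(nCompounds, 150, 900))
    carbon <- pmax(1L, round(mz / 22))
    intensity <- rlnorm(nCompounds, 9, 0.8)
    mono <- data.frame(fraction = 1L, mz = mz, intensity = intensity)
    sat1 <- data.frame(fraction = 1L, mz = mz + carbon13Shift(1),
                       intensity = intensity * carbon * 0.0107)
    sat2 <- data.frame(fraction = 1L, mz = mz + carbon13Shift(2),
                       intensity = intensity * choose(carbon, 2) * 0.0107^2)
    list(fset = FractionSet(rbind(mono, sat1, sat2)), monoMz = mz)
  })
}

# Two coeluting isomers sharing one m/z bin: the classic two-bump mass
# profile. `activityBoth` has comparable activity over both elution
# regions (different actives elute in each), which is the regime where the
# whole-profile correlation overstates both components; `activityOne` is
# concentrated on the first region only.
twoIsomerProfile <- function() {
  m <- c(0, 2, 30, 80, 30, 2, 0, 0, 0, 1, 25, 70, 25, 1, 0)
  aBoth <- c(0, 1, 28, 75, 28, 1, 0, 0, 0, 2, 30, 80, 30, 2, 0)
  aOne <- c(0, 1, 28, 75, 28, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  list(profile = m, activityBoth = aBoth, activityOne = aOne)
}
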