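# Shared fixtures: a small simulated allotetraploid used across tests.

smallParams <- function(seed = 101L, ...) {
  simulationParams(nChromosomePairs = 2L, chromosomeLength = 3e6,
                   siteDensity = 0.005, repeatFraction = 0.4,
                   coveragePerCopy = 2, sequencingError = 0.001,
                   seed = seed, ...)
}

# Simulate one accession with a given event list and return the scan input.
simScanInput <- function(events = NULL, params = smallParams(),
                         accession = "test") {
  ref <- simulateReference(params)
  truth <- injectKaryotype(ref, events, accessions = accession)
  obs <- simulateObservables(ref, truth, params,
                             accessions = c("reference", accession))
  list(ref = ref, truth = truth,
       siteDepth = obs[[accession]]$siteDepth,
       coverage = obs[[accession]]$coverage,
       refCoverage = obs$reference$coverage)
}

# Brute-force per-site chi-square oracle, written independently of
# rohHStatistic: explicit per-site expected counts under p = 0.5.
chisqOracle <- function(a, b) {
  keep <- (a + b) > 0
  a <- a[keep]
  b <- b[keep]
  tot <- 0
  for (i in seq_along(a)) {
    n <- a[i] + b[i]
    e <- n / 2
    tot <- tot + (a[i] - e)^2 / e + (b[i] - e)^2 / e
  }
  list(chi2 = tot, df = length(a))
}
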