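seed: 42
out: homoeoscan-demo
stages: [simulate, windows, genotype, karyotype, diversity, report]
simulate:
  nChromosomePairs: 2
  chromosomeLength: 2000000
  siteDensity: 0.005
  repeatFraction: 0.4
  coveragePerCopy: 3
  sequencingError: 0.001
  panelPi: 0.0003
  introgressionPiMultiplier: 10
  nAccessions: 8
  referenceAccession: reference
  events:
    - accession: demo1
      pair: 1
      start: 1
      end: 800000
      cRef: 3
      cOther: 1
  introgression:
    - accession: 2
      pair: 2
      start: 500000
      end: 1500000
windows:
  W: 100000
genotype:
  ruleset: wgs
karyotype:
  alpha: 0.05
  minEventSize: 200000
diversity:
  k: 10
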