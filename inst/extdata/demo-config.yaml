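# Demo configuration: small three-population genome scan with two
# injected sweeps targeted at the southern population.
seed: 20210101
genome:
  chrom_lengths:
    chr1: 1540000
    chr2: 1540000
  snps_per_chrom: 800
  sweeps:
    n: 2
    length: 100000
    target: SC
populations:
  sizes: {NC: 20, MC: 20, SC: 20}
  fst: {NC: 0.02, MC: 0.02, SC: 0.3}
scan:
  pairs:
    - [SC, NC]
    - [SC, MC]
  q: 0.99
  valley_q: 0.05
het:
  pop_a: NC
  pop_b: SC
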