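# Siphonaria gigas microsatellite fixture

Worked dataset from a field study of the pair-living, hermaphroditic
intertidal limpet *Siphonaria gigas* at Punta Culebra, Panama. Adults and
the pooled embryos of their egg masses were genotyped at four polymorphic
microsatellite loci (alleles are PCR fragment lengths in base pairs).

Files:

- `loci.csv` — the four-locus panel with repeat motifs.
- `adults.csv` — multilocus genotypes of the 16 printed adults: the 14
  sampled maternal limpets (IDs `M<mass>`, named for the egg mass each
  deposited) and the two sampled social partners that did not themselves
  deposit a sampled mass (`PP20`, `PP33`). The partners of the mothers of
  masses 27 and 30 are each other, so their genotypes appear once. The
  original study genotyped 19 adults; three (including carriers of egg-mass
  alleles 269 at MS-26, 234 at MS-34 and 53/63 at MS-31) are present only
  in the archived full dataset, not in the printed tables this fixture
  transcribes. Shell lengths were not printed per individual and are blank.
- `masses.csv` — per egg mass, the union of alleles detected in a pooled
  sample of ~500 embryos at each locus (semicolon-separated), the maternal
  identity (`NS` = mother never sampled), maternal social status, and the
  putative sire (the mother's social partner) where that partner was
  genotyped. `ND` = no data (locus dropped for that mass by low read
  depth).
- `published_calls.csv` — the reported per-mass conservative minimum
  number of sires and, for the four fully genotyped pairs, the reported
  monogamy (MO) / extra-pair (EP) classification; used by
  `reproduce_reference_tables()` to diff recomputed calls against the
  reported ones.

Allele values are categorical labels; no arithmetic on fragment lengths is
ever performed. Bold/plain typography distinguishing non-maternal alleles
in the source tables is not encoded: non-maternal status is recomputed.
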