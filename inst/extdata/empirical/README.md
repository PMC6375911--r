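# Deposited cytochrome-b data (not redistributed)

The empirical mitochondrial sequences are public GenBank records
MK113717–MK113815 and are not bundled with the package. To run the
empirical reproduction checks, place here:

* `cytb_alignment.fasta` — the records, aligned and trimmed to the region
  resolved in all samples (e.g. with `mafft --auto`, then
  `read_fasta_alignment(..., trim = TRUE)`);
* `cytb_popmap.tsv` — three tab-separated columns `sample colony group`,
  with colonies `CHA CHB IGA AZA AZB ILV ISG` grouped as
  `CHR CHR IGA AZR AZR PER PER` (the GenBank `isolate`/`country`
  qualifiers identify the colony of each record).

The test suite computes segregating sites, nucleotide diversity, Tajima's
D and the four-group hierarchical AMOVA from these files and compares
them with the published values.
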