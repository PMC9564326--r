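Synthetic glycosidic strain curves for testing and demonstration.

These grids are smooth periodic toy potentials (sums of cosine wells),
NOT fitted to any quantum-mechanical or experimental data. Use them to
exercise the CHI scoring machinery; substitute real curve grids (same
CSV layout: columns angle, energy) for production analyses.
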