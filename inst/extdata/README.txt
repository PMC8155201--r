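demo_taxonomy.nwk: synthetic demonstration taxonomy of nine metazoan species
with round-number node ages (millions of years) in the style of published
divergence-time estimates: vertebrate crown 615, Olfactores 676,
Deuterostomia 684, Bilateria 688, Metazoa root 800. Branch lengths are age
differences, so the tree is an ultrametric chronogram. The vertebrate stem
branch (Olfactores -> Vertebrata) spans 676-615 mya. Intended for examples
and pipeline tests; it is a demonstration object, not a published phylogeny.
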