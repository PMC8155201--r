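(((((Homo_sapiens:615,Danio_rerio:615,Petromyzon_marinus:615)Vertebrata:61,Ciona_intestinalis:676)Olfactores:8,Strongylocentrotus_purpuratus:684)Deuterostomia:4,(Drosophila_melanogaster:632,Caenorhabditis_elegans:632)Protostomia:56)Bilateria:112,Nematostella_vectensis:800)Metazoa;
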