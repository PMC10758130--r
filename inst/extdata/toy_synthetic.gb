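LOCUS       TOYSYN1              120 bp    DNA     circular VRT
DEFINITION  synthetic toy mitogenome fragment for parser tests.
ACCESSION   TOYSYN1
SOURCE      mitochondrion
  ORGANISM  Toyus syntheticus
FEATURES             Location/Qualifiers
     source          1..120
     CDS             1..15
                     /gene="COX1"
                     /codon_start=1
     tRNA            complement(20..40)
                     /gene="tRNA-Gln"
     rRNA            45..80
                     /product="12S ribosomal RNA"
     D-loop          85..120
ORIGIN
        1 atgaaacccg ggtaactgtc actaaaccgc tccggccaaa cgggagatgg atgacgtcga
       61 agggcgggca gaagctgtca agtgtattac gggtgaagcg gatatcatag gtgtacctag
//
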