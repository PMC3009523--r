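LOCUS       SYNMINI01     90 bp    DNA     linear   SYN 01-JAN-2026
DEFINITION  Synthetic minigene used to demonstrate GenBank flat-file input;
            a 30-codon GCA repeat flanked by arbitrary sequence.
ACCESSION   SYNMINI01
FEATURES             Location/Qualifiers
     source          1..90
ORIGIN
        1 ttacgtagca gcagcagcag cagcagcagc agcagcagca gcagcagcag cagcagcagc
       61 agcagcagca gcagcatgca ccgtaatgcc
//
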