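LOCUS       SYN0001              120 bp    DNA     circular BCT 01-JAN-2020
DEFINITION  synthetic mini genome for parser tests.
ACCESSION   SYN0001
FEATURES             Location/Qualifiers
     source          1..120
                     /organism="synthetic construct"
     CDS             1..9
                     /locus_tag="mini_0001"
                     /product="toy protein MK"
     CDS             complement(10..18)
                     /locus_tag="mini_0002"
                     /product="toy protein MK, minus strand"
     CDS             join(19..27,31..36)
                     /locus_tag="mini_0003"
                     /product="spliced toy protein MEEG"
     rRNA            40..60
                     /locus_tag="mini_r16"
                     /product="16S ribosomal RNA"
     rRNA            complement(61..80)
                     /locus_tag="mini_r23"
                     /product="23S ribosomal RNA"
     CDS             85..94
                     /locus_tag="mini_0004"
                     /product="frame-broken CDS"
ORIGIN
        1 atgaaataat tatttcatat ggaagaaccc gggtaaacga cgtacgtacg tacgtacgta
       61 ggggccccaa aattttggcc ttttatgaaa ataaacgtac gtacgtacgt acgtacgtac
//
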