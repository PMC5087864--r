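chrom	centromere_start	centromere_end
chr1	249500	250500
chr2	249500	250500
chr3	249500	250500
chr4	249500	250500
chrX	99500	100500
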