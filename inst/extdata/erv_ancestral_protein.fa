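>erv_ancestral_protein reconstructed ERV protein homologous to poxvirus MC132 (293 aa)
MAPPEAPPAXVTERETATSSDPCLLGPNVRRLDFFPHLASKVIPARQDQDSLFRSLKFLG
WRPEDPCSWCPPGFRQVSPFDGYFEGPVPHHSVWSPTSGQFKDRSVIFMWIVEALGHFLH
CSPDRLSPSLGPLKYNLWCMGTALRAVELLFQPFNNWYWKEENIVSWDTGYWYRLERGAY
SFDGKWGQKARVQQLFSRPWPRGHPPPPLSLLSLLSLIQRFLLEGQFYGQAHVNWALACK
HQWCPRPRPCHPGTGRTRWQKDHNKSNSPCAPFSGQWAHGRGKGSFHPAGKHG
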