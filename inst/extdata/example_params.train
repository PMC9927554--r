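# ervfossils DNA-protein alignment parameters
scale 0.23338265884431636
gap_open_del 40
gap_extend_del 9
gap_open_ins 31
gap_extend_ins 13
frameshift_penalty 29
codon_freq 0.015082956259426848 0.017194570135746608 0.015686274509803921 0.014479638009049774 0.018099547511312219 0.018401206636500755 0.01478129713423831 0.015384615384615385 0.016892911010558068 0.014479638009049774 0.014177978883861238 0.01900452488687783 0.018401206636500755 0.017797888386123679 0.018401206636500755 0.018702865761689291 0.015082956259426848 0.016591251885369532 0.015987933634992461 0.012368024132730015 0.017194570135746608 0.016892911010558072 0.013273001508295627 0.015082956259426848 0.013273001508295626 0.019909502262443438 0.018099547511312219 0.017194570135746608 0.016289592760180997 0.01297134238310709 0.015987933634992457 0.015987933634992457 0.014177978883861237 0.014177978883861237 0.01297134238310709 0.016591251885369532 0.016591251885369532 0.020512820512820513 0.012066365007541479 0.017496229260935144 0.012669683257918552 0.014177978883861237 0.015987933634992457 0.014479638009049774 0.016892911010558068 0.018099547511312215 0.016591251885369532 0.017797888386123679 0.011764705882352941 0.017194570135746608 0.011764705882352941 0.017194570135746608 0.014479638009049774 0.013574660633484163 0.013574660633484163 0.017496229260935144 0.01085972850678733 0.015082956259426848 0.013876319758672701 0.014479638009049774 0.014781297134238312 0.011463046757164405 0.014781297134238312 0.017194570135746608
aa_freq 0.060030165912518856 0.07571644042232277 0.042232277526395176 0.039819004524886882 0.038914027149321267 0.037104072398190045 0.037104072398190045 0.057315233785822019 0.040120663650075418 0.053996983408748117 0.072699849170437411 0.037104072398190045 0.030769230769230771 0.037707390648567124 0.058521870286576169 0.073001508295625947 0.062745098039215685 0.026847662141779791 0.040422322775263954 0.058521870286576169 0.019306184012066366
# subst_score: rows AAA..TTT, columns ARNDCQEGHILKMFPSTWYV*
AAA -7 -8 5 -4 -4 3 3 -2 0 -6 -1 13 -3 -4 -2 -8 -3 -2 -4 -7 0
AAC -8 -5 13 5 -5 -5 0 -7 2 0 -9 0 -3 -5 -7 -5 -4 -3 6 -7 -1
AAG -7 1 -1 -4 -4 5 3 -7 -5 -6 -8 13 1 -4 -7 -1 -1 2 -5 -7 0
AAT -7 -4 13 -4 -4 1 -4 -2 0 1 -8 1 -2 -4 -2 -1 -7 -2 3 -6 0
ACA 3 -9 -6 -5 -5 -1 -5 -8 -5 -7 -9 4 -4 -5 -3 -2 12 -3 -1 -8 -1
ACC 1 -3 1 -5 -5 -5 -5 -3 -6 -3 -9 -5 -4 -5 1 1 12 -3 -6 -8 -1
ACG 3 -4 0 -4 -4 -4 -4 -6 -4 -6 1 5 2 -4 0 -4 9 -2 -4 -7 0
ACT -7 -8 2 -4 -4 -4 -4 -2 -4 1 -4 0 1 -4 0 2 10 -2 -4 -7 0
AGA -7 9 -5 -5 -5 0 -5 1 -5 0 -9 0 -3 0 -3 0 1 2 -5 -3 0
AGC -7 1 6 -4 0 -4 -4 -2 -4 -6 -3 -4 -2 1 -6 8 0 -2 -4 0 0
AGG -6 9 -4 -4 -4 1 -3 2 -4 -1 -8 1 -2 -4 -6 1 -2 5 -4 -6 1
AGT -4 2 1 -1 -1 -5 -5 -4 -6 -3 -5 -5 -4 -5 -1 9 4 -3 -6 -8 -1
ATA -8 -5 -2 -5 -5 -5 -5 -8 -6 13 1 -1 5 -5 -8 -5 -2 -3 -6 -1 -1
ATC -8 -9 3 -5 -5 -5 -5 -8 -5 12 -5 -5 3 2 -8 -5 -1 -3 -5 2 -1
ATG -8 -9 -2 -5 -1 2 -5 -8 -1 3 5 -5 15 -5 -8 -5 -2 -3 -6 -8 -1
ATT -8 -10 1 -6 -5 -5 -5 -8 -1 11 -5 -5 0 3 -4 2 0 -3 -6 2 -1
CAA -7 -4 -5 -4 -4 15 -4 -7 2 -6 -8 0 -3 -4 2 -1 -7 -2 -4 -7 0
CAC -7 -5 5 -5 -5 4 -4 -7 13 -7 0 -4 -3 -5 -3 -9 -3 -2 5 -7 0
CAG -7 -4 -1 -5 -4 11 0 -3 5 -2 2 0 -3 -4 4 -8 -7 -2 -5 0 0
CAT -6 -3 3 4 -3 2 -3 -5 13 -5 -7 -3 -1 -3 -1 -7 -6 -1 -3 -5 1
CCA -1 -9 -5 -5 -5 -5 -5 -3 -1 -7 -9 -5 1 -5 12 -2 3 -3 -5 -7 -1
CCC 1 1 1 -5 -5 -5 -5 -3 -1 -7 -2 -5 -3 -5 11 -9 1 -3 -5 -7 0
CCG 1 -1 -4 -3 -3 1 -3 -6 -4 -5 -3 -3 -2 -3 11 -3 1 -1 -4 -6 1
CCT -3 3 -5 -4 -4 -4 -4 -7 0 -6 1 -4 4 -4 9 -4 4 -2 -4 -7 0
CGA -2 10 -4 -3 -3 -3 -3 1 3 -5 -3 -3 -2 -3 -2 -7 -6 -1 -4 -6 1
CGC -4 9 -6 -6 -2 -1 -6 0 5 -4 -3 -6 -4 -6 4 0 -9 -4 -6 -8 -1
CGG -8 11 -6 -5 -5 -1 -5 1 -1 -7 -5 -1 -4 -5 -1 -5 -8 -3 -5 -3 -1
CGT -3 9 -5 -5 4 -5 0 3 3 -7 -2 -5 -3 -5 1 -5 -4 -3 -5 -7 -1
CTA -7 -4 -1 -5 -5 6 0 -7 -5 0 10 -4 -3 -4 1 -4 -8 -2 -5 -7 0
CTC -6 3 -4 -3 -3 -3 -3 -1 -3 3 8 -3 -2 -3 1 -7 -2 -1 -3 -1 1
CTG -7 -2 -5 -5 -4 0 -4 -7 -5 -6 10 -4 1 4 0 -2 -7 2 -5 -7 0
CTT -3 -2 -5 -5 -4 -4 -4 -3 -5 2 11 -4 -3 0 -3 -4 -7 -2 -5 -7 0
GAA 4 -8 0 0 1 -3 13 -6 -4 -6 -8 3 -2 -4 -6 -8 -7 -1 0 2 1
GAC -2 -8 -4 14 -4 1 1 -6 3 -6 -8 -3 -2 -4 -6 -8 -2 -1 3 1 1
GAG 1 -7 -4 -3 -3 1 14 1 -3 -5 -3 1 -2 -3 -6 -7 -6 -1 -3 -6 1
GAT -3 -9 -1 13 -5 -4 2 0 5 -2 -9 -4 -3 -5 -7 -9 -8 -2 4 1 0
GCA 12 -9 -5 -5 -5 -4 0 1 -5 -7 -2 -4 -3 -5 0 -2 -3 -2 -5 0 0
GCC 12 -10 -7 1 -6 -6 -6 0 -2 -8 -6 -6 -5 -2 0 -1 0 -4 -6 -2 -2
GCG 8 -7 -3 1 -3 -2 2 -1 -3 -5 -2 -2 -1 -3 -1 3 1 0 -3 -5 2
GCT 12 -9 -1 -1 -5 -5 -5 1 -5 -7 -9 -5 -4 -5 -1 -5 3 -3 -5 -3 -1
GGA 1 -3 -4 -3 -3 -3 2 12 -3 -5 -7 -3 -2 -3 -6 -7 -6 -1 1 -6 1
GGC -2 1 -4 -4 -4 -3 -3 12 -4 -1 -8 -3 -2 -4 -6 -1 -7 -1 -4 -2 1
GGG -7 6 -5 0 0 -4 0 11 -5 -6 -4 -4 -3 -4 -3 -8 -7 -2 -5 0 0
GGT 2 -8 -4 0 5 -4 1 10 -4 -6 -8 -4 -2 -4 -6 -3 -7 -2 -4 5 0
GTA 1 -5 -5 -1 -5 -5 2 1 -5 2 2 -5 -3 -5 -7 -9 -8 -3 -5 11 0
GTC -4 -9 -6 3 -5 -5 -1 -1 -5 5 -5 -5 0 -1 -8 -9 -8 -3 -1 12 -1
GTG -1 -9 -5 4 -5 -4 4 3 -5 -2 0 -4 -3 -5 -7 -9 -8 -2 -5 11 0
GTT -1 -9 -6 6 -5 -5 -5 2 -5 -3 0 -5 1 2 -8 -5 -8 -3 -5 11 -1
TAA -1 -7 1 2 -3 -2 6 -5 -3 -5 0 8 -1 -2 -5 0 -6 4 6 -5 2
TAC -8 -5 -5 5 2 0 2 -7 -1 -7 -9 0 -3 6 -7 -2 -4 -3 12 -7 -1
TAG -5 -7 -3 2 -3 5 5 -1 2 -5 0 6 -1 -2 -5 0 -1 0 4 -1 2
TAT -8 -5 5 2 5 -5 -5 -7 3 -7 -5 0 -3 4 -7 -5 -8 -3 12 -3 -1
TCA 0 -8 -4 -4 -4 -4 -4 -6 -4 -6 -1 -4 -2 -4 0 11 -3 -2 0 -6 0
TCC -6 -8 -4 -4 6 -3 -3 -6 -4 -1 -7 -3 -2 -3 -6 9 2 -1 5 -2 1
TCG -2 -8 -4 -4 -3 -3 4 1 -4 -5 -3 1 -2 -3 -2 10 -2 -1 -4 -6 1
TCT -1 -9 -6 -5 5 -5 -5 -7 -5 -7 -5 -5 -4 -5 1 10 -1 2 2 -8 -1
TGA -5 -2 -3 -2 5 -2 -2 2 -2 -4 1 2 -1 -2 0 -2 -1 10 -2 -5 2
TGC -3 4 -5 -4 12 -4 -4 -2 -4 -6 -4 -4 -3 3 -7 -1 -7 5 0 -7 0
TGG -6 2 -4 -4 5 -3 -3 -2 0 -6 -3 -3 2 3 -6 -3 -2 14 -4 -6 1
TGT -7 -1 -4 -4 13 -4 -4 -6 -4 -6 -3 -4 -2 5 -2 -1 -7 3 3 -6 0
TTA -2 -8 -4 -4 0 -4 -4 -6 -4 1 9 -4 2 3 -7 -1 -7 -2 3 2 0
TTC -5 -7 1 2 6 -2 -2 -5 -3 0 -2 -2 -1 12 -5 -6 -5 0 -3 -1 2
TTG -7 -8 -4 -4 -4 -4 -4 -6 -4 -2 9 -4 2 6 -7 -1 -7 3 0 3 0
TTT -8 -5 -1 -5 2 -5 -5 -7 -5 3 -2 -5 1 13 -3 -5 -8 -3 2 4 -1
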