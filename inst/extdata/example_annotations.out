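   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat
score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID

  2150  18.2   4.1   2.0  host           1001     2200   (97800) + HERV17          LTR/ERV1                101  1300 (2200)      1
  1800  21.5   6.0   3.3  host           2501     3500   (96500) + HERV17          LTR/ERV1               1601  2600  (900)      2
   950  25.0   2.2   1.1  host           4001     4800   (95200) C HERV9           LTR/ERV1             (2500)  1000    201      3
   640  30.1   8.8   4.4  host           6001     6900   (93100) + MER41B          LTR/ERV1                 11   910   (90)      4
  1200  19.9   5.5   2.8  host           9001    10500   (89500) C HERV17          LTR/ERV1                (0)  3500   2001      5
   400  12.3   1.0   0.5  chr_other       501      900    (1100) + AluY            SINE/Alu                  1   400   (10)      6
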