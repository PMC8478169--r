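HMMER3/f [3.4 | Aug 2023]
NAME  toy
LENG  10
ALPH  amino
RF    no
MM    no
CONS  yes
CS    no
MAP   yes
DATE  Thu Sep 24 07:01:40 2026
NSEQ  3
EFFN  3.000000
CKSUM 1716897390
STATS LOCAL MSV       -5.5166  0.74641
STATS LOCAL VITERBI   -5.6608  0.74641
STATS LOCAL FORWARD   -2.9711  0.74641
HMM          A        C        D        E        F        G        H        I        K        L        M        N        P        Q        R        S        T        V        W        Y   
            m->m     m->i     m->d     i->m     i->i     d->m     d->d
  COMPO   1.73403  5.47813  4.77943  4.53467  4.46055  4.27889  5.16582  2.96243  1.76092  3.03004  2.49142  4.65695  4.90612  2.39980  2.32005  3.14809  2.87399  3.93501  5.99810  2.44215
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.00000        *
      1   4.25112  5.66746  5.45821  5.25250  4.25670  4.83375  5.75580  3.58523  4.98633  2.78386  0.25191  5.37670  5.38471  5.32431  5.04119  4.64540  4.62574  3.69840  6.12261  4.97173      1 M - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      2   4.39942  6.12840  4.64246  4.17909  5.79396  4.61603  4.88629  5.35693  0.20070  4.71863  5.71531  4.51427  5.11690  4.08594  3.28682  4.43275  4.61403  5.03784  6.46104  5.51309      2 K - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      3   2.82226  4.75057  4.45323  4.24678  5.20522  3.53596  5.19258  4.63902  4.26698  4.35226  5.15855  4.14752  4.35484  4.51755  4.48372  1.23026  0.78715  3.94903  6.55132  5.39868      3 t - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      4   0.19989  5.09609  4.90943  4.86817  5.47834  3.87778  5.69414  4.82779  4.92219  4.62846  5.59295  4.64391  4.70631  5.15250  5.00494  3.47075  3.81778  4.24261  6.74111  5.74319      4 A - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      5   4.99618  6.06306  5.50145  5.47688  3.03415  5.14289  4.56794  4.93796  5.34433  4.11379  5.49786  5.19187  5.62424  5.36166  5.27931  4.99638  5.30063  4.85723  4.68580  0.17648      5 Y - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      6   4.07199  5.25510  6.05594  5.54710  3.76372  5.58299  6.03565  0.81884  5.42162  1.09098  3.50501  5.75354  5.63977  5.39710  5.43156  5.02811  4.30131  2.45342  6.02867  5.00518      6 i - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      7   0.19989  5.09609  4.90943  4.86817  5.47834  3.87778  5.69414  4.82779  4.92219  4.62846  5.59295  4.64391  4.70631  5.15250  5.00494  3.47075  3.81778  4.24261  6.74111  5.74319      7 A - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      8   4.39942  6.12840  4.64246  4.17909  5.79396  4.61603  4.88629  5.35693  0.20070  4.71863  5.71531  4.51427  5.11690  4.08594  3.28682  4.43275  4.61403  5.03784  6.46104  5.51309      8 K - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
      9   4.35880  6.08879  4.24423  4.12749  5.45318  4.52614  5.23927  5.41737  3.90825  4.77483  5.88352  4.55474  5.15318  0.18323  4.11886  4.42002  4.71010  5.09350  6.51335  5.39771      9 Q - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.01083  4.92694  5.64929  0.61958  0.77255  0.48576  0.95510
     10   4.63269  6.17031  5.23627  4.65723  5.83104  4.75957  5.16203  5.57076  3.40946  4.88757  5.93594  4.90413  5.28406  4.40770  0.15346  4.72514  4.87591  5.25930  6.52707  5.64972     10 R - - -
          2.68618  4.42225  2.77519  2.73123  3.46354  2.40513  3.72494  3.29354  2.67741  2.69355  4.24690  2.90347  2.73739  3.18146  2.89801  2.37887  2.77519  2.98518  4.58477  3.61503
          0.00730  4.92341        *  0.61958  0.77255  0.00000        *
//
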