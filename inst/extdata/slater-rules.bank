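# radial-function databank: slater-rules
ELEM H 1 0 1 2
CORE
VAL
  0.31830988618379069 0 2
DEF l=0 n=0 zeta=2
DEF l=1 n=1 zeta=2
DEF l=2 n=2 zeta=2
ELEM C 6 2 4 4
CORE
  117.89752550406951 0 11.4
VAL
  4.8090101143732991 2 3.25
DEF l=0 n=0 zeta=3.25
DEF l=1 n=2 zeta=3.25
DEF l=2 n=2 zeta=3.25
DEF l=3 n=3 zeta=3.25
DEF l=4 n=4 zeta=3.25
ELEM N 7 2 5 4
CORE
  191.47167259659091 0 13.4
VAL
  14.957945059746708 2 3.8999999999999999
DEF l=0 n=0 zeta=3.8999999999999999
DEF l=1 n=2 zeta=3.8999999999999999
DEF l=2 n=2 zeta=3.8999999999999999
DEF l=3 n=3 zeta=3.8999999999999999
DEF l=4 n=4 zeta=3.8999999999999999
ELEM O 8 2 6 4
CORE
  290.63793453828902 0 15.4
VAL
  38.796015836290572 2 4.5499999999999998
DEF l=0 n=0 zeta=4.5499999999999998
DEF l=1 n=2 zeta=4.5499999999999998
DEF l=2 n=2 zeta=4.5499999999999998
DEF l=3 n=3 zeta=4.5499999999999998
DEF l=4 n=4 zeta=4.5499999999999998
ELEM Mg 12 10 2 4
CORE
  1019.6185034809588 0 23.399999999999999
  790.70987927096667 2 7.8499999999999996
VAL
  0.019758903576666455 4 1.8999999999999999
DEF l=0 n=0 zeta=1.8999999999999999
DEF l=1 n=4 zeta=1.8999999999999999
DEF l=2 n=4 zeta=1.8999999999999999
DEF l=3 n=4 zeta=1.8999999999999999
DEF l=4 n=4 zeta=1.8999999999999999
ELEM Cl 17 10 7 4
CORE
  2965.0330348704324 0 33.399999999999999
  9293.6116250878549 2 12.85
VAL
  14.230681910422952 4 4.0666666666666664
DEF l=0 n=0 zeta=4.0666666666666664
DEF l=1 n=4 zeta=4.0666666666666664
DEF l=2 n=4 zeta=4.0666666666666664
DEF l=3 n=4 zeta=4.0666666666666664
DEF l=4 n=4 zeta=4.0666666666666664
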