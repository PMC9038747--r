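combo,inputs
w1,Ir;P_e;RH_avg;T_emp;S_sh
w2,Ir;P_e;RH_avg;S_sh
w3,Ir;P_e;T_emp;S_sh
w4,Ir;P_e;RH_avg;T_emp
w5,Ir;T_emp;RH_avg;S_sh
w6,T_emp;P_e;S_sh
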