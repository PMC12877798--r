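patient_id,d_lmca_mm,d_lad_mm,d_lcx_mm,stenosed_branch,stenosis_pct,stenosis_len_mm
1,4.10,3.50,3.00,LAD,63,20.45
2,4.40,2.90,2.81,LCX,71,22.70
3,4.70,3.30,3.10,LAD,75,28.40
4,5.00,3.20,3.38,LAD,28,3.00
5,4.80,4.30,2.90,LAD,44,6.00
6,4.10,2.90,2.70,LAD,65,17.00
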