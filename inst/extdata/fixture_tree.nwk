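(A-M91,(C-M130,E1b-M215,(G-M201,H-M69)GH-F871,((I1-M253,I2-M223)I-M170,(J1-M267,J2-M172)J-M304,(NO-M214,(Q-M242,(R1a-M420,R1b-M343)R-M207)P-M45)K2-M526)IJK-S137)F-M89)Y;
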