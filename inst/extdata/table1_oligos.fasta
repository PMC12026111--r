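>anneal_sensor_F label5=TEX chirality=L role=anneal_sensor
ACTGGGTTTTACAAACCTGTGA
>anneal_sensor_Q label3=BHQ2 chirality=L role=anneal_sensor
TCACAGGTTTGTAAAACCCAGTTCCAT
>melt_sensor_F label5=HEX chirality=L role=melt_sensor
ACAAGAAAGGGATCTTCACTCGCGACCGCAAACCGAAGTCGGCGGCTTTTCTGCTGCAAAAACGCTGGACTGGCATG
>melt_sensor_Q label3=BHQ2 chirality=L role=melt_sensor
CATGCCAGTCCAGCGTTTTTGCAGCAGAAAAGCCGCCGACTTCGGTTTGCGGTCGCGAGTGAAGATCCCTTTCTTGT
>smitis_forward_primer chirality=D role=primer
GCCATTGAAGCGGTTACTTTG
>smitis_reverse_primer chirality=D role=primer
CATCCGACATTAACGCAAGTTC
>smitis_probe label5=FAM label3=IABkFQ chirality=D role=probe
ATGATTGAGCGTGGAACGGTGGGT
>smitis_synthetic_target chirality=D role=target
GCCATTGAAGCCGTTACTTTGAACGCAAAAGTGGCTATGATTGAGCGTGGAACGGTGGGTGGAACTTGCGTTAATGTCGGATG
>dT21_carrier chirality=D role=carrier
TTTTTTTTTTTTTTTTTTTTT
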