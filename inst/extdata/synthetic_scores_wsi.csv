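wsi_id,patient_id,modality,reader_id,assigned,reference
W01,P01,virtual,R1,0,0
W01,P01,virtual,R2,0,0
W01,P01,virtual,R3,0,0
W02,P02,virtual,R1,0,0
W02,P02,virtual,R2,1+,0
W02,P02,virtual,R3,0,0
W03,P03,virtual,R1,0,0
W03,P03,virtual,R2,1+,0
W03,P03,virtual,R3,0,0
W04,P04,virtual,R1,1+,1+
W04,P04,virtual,R2,0,1+
W04,P04,virtual,R3,2+,1+
W05,P05,virtual,R1,1+,1+
W05,P05,virtual,R2,1+,1+
W05,P05,virtual,R3,0,1+
W06,P06,virtual,R1,2+,1+
W06,P06,virtual,R2,1+,1+
W06,P06,virtual,R3,1+,1+
W07,P07,virtual,R1,2+,2+
W07,P07,virtual,R2,1+,2+
W07,P07,virtual,R3,3+,2+
W08,P08,virtual,R1,2+,2+
W08,P08,virtual,R2,2+,2+
W08,P08,virtual,R3,1+,2+
W09,P09,virtual,R1,3+,2+
W09,P09,virtual,R2,2+,2+
W09,P09,virtual,R3,2+,2+
W10,P10,virtual,R1,3+,3+
W10,P10,virtual,R2,2+,3+
W10,P10,virtual,R3,3+,3+
W11,P11,virtual,R1,2+,3+
W11,P11,virtual,R2,3+,3+
W11,P11,virtual,R3,2+,3+
W12,P12,virtual,R1,3+,3+
W12,P12,virtual,R2,2+,3+
W12,P12,virtual,R3,3+,3+
W01,P01,ihc,R1,0,0
W01,P01,ihc,R2,1+,0
W01,P01,ihc,R3,0,0
W02,P02,ihc,R1,1+,0
W02,P02,ihc,R2,0,0
W02,P02,ihc,R3,2+,0
W03,P03,ihc,R1,0,0
W03,P03,ihc,R2,1+,0
W03,P03,ihc,R3,0,0
W04,P04,ihc,R1,1+,1+
W04,P04,ihc,R2,0,1+
W04,P04,ihc,R3,2+,1+
W05,P05,ihc,R1,1+,1+
W05,P05,ihc,R2,1+,1+
W05,P05,ihc,R3,2+,1+
W06,P06,ihc,R1,0,1+
W06,P06,ihc,R2,1+,1+
W06,P06,ihc,R3,1+,1+
W07,P07,ihc,R1,2+,2+
W07,P07,ihc,R2,1+,2+
W07,P07,ihc,R3,3+,2+
W08,P08,ihc,R1,1+,2+
W08,P08,ihc,R2,2+,2+
W08,P08,ihc,R3,3+,2+
W09,P09,ihc,R1,1+,2+
W09,P09,ihc,R2,2+,2+
W09,P09,ihc,R3,2+,2+
W10,P10,ihc,R1,3+,3+
W10,P10,ihc,R2,2+,3+
W10,P10,ihc,R3,3+,3+
W11,P11,ihc,R1,2+,3+
W11,P11,ihc,R2,3+,3+
W11,P11,ihc,R3,2+,3+
W12,P12,ihc,R1,2+,3+
W12,P12,ihc,R2,3+,3+
W12,P12,ihc,R3,3+,3+
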