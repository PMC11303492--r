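explant_id	segment_id	mean_diameter
explant1	s1	8.2
explant1	s2	12.5
explant1	s3	9.8
explant1	s4	21.0
explant2	s1	14.1
explant2	s2	16.9
explant2	s3	11.3
explant3	s1	7.4
explant3	s2	18.6
explant3	s3	25.2
explant3	s4	10.0
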