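transcript_id	d4_r1	d4_r2	d30_r1	d30_r2
C01	100	100	100	100
C02	100	100	100	100
C03	100	100	100	100
C04	100	100	100	100
C05	100	100	100	100
C06	100	100	100	100
C07	100	100	100	100
C08	100	100	100	100
C09	100	100	100	100
C10	100	100	100	100
C11	100	100	100	100
C12	0	0	0	0
C13	0	0	0	0
C14	100	100	100	100
C15	100	100	100	100
C16	100	100	100	100
C17	100	100	100	100
C18	100	100	100	100
C19	100	100	100	100
C20	100	100	100	100
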