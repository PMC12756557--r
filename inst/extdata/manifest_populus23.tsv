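sample_id	taxon	section	source
Dmitrovka_444	P. balsamifera	Tacamahaca	Dmitrovka, Moscow Region
Dmitrovka_445	P. balsamifera	Tacamahaca	Dmitrovka, Moscow Region
Novokuznetsk_L1	P. laurifolia	Tacamahaca	Novokuznetsk
Novokuznetsk_L2	P. laurifolia	Tacamahaca	Novokuznetsk
Moscow_Lo1	P. longifolia	Tacamahaca	Moscow
Moscow_Lo2	P. longifolia	Tacamahaca	Moscow
Irkutsk_S1	P. suaveolens	Tacamahaca	Irkutsk
Irkutsk_S2	P. suaveolens	Tacamahaca	Irkutsk
Novokuznetsk_S3	P. suaveolens	Tacamahaca	Novokuznetsk
Moscow_W1	P. x wobstii	Tacamahaca	Moscow
Moscow_D1	P. deltoides	Aigeiros	Moscow
Sevastopol_D2	P. deltoides	Aigeiros	Sevastopol
Moscow_C1	P. x canadensis	Aigeiros	Moscow
Moscow_C2	P. x canadensis	Aigeiros	Moscow
Voronezh_548	P. x canadensis	Aigeiros	Voronezh
Novokuznetsk_N1	P. nigra	Aigeiros	Novokuznetsk
Novokuznetsk_N2	P. nigra	Aigeiros	Novokuznetsk
Voronezh_N3	P. nigra	Aigeiros	Voronezh
Bashkortostan_N4	P. nigra	Aigeiros	Bashkortostan
Moscow_P1	P. x petrovskoe	Aigeiros x Tacamahaca	Moscow
Moscow_P2	P. x petrovskoe	Aigeiros x Tacamahaca	Moscow
Moscow_R1	P. x rasumovskoe	Aigeiros x Tacamahaca	Moscow
Moscow_Si1	P. x sibirica	Aigeiros x Tacamahaca	Moscow
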