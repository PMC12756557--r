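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
SRA_sim_001	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_002	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_003	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_004	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_005	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_006	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_007	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_008	P. tremula	Populus	synthetic SRA placeholder
SRA_sim_009	P. davidiana	Populus	synthetic SRA placeholder
SRA_sim_010	P. davidiana	Populus	synthetic SRA placeholder
SRA_sim_011	P. davidiana	Populus	synthetic SRA placeholder
SRA_sim_012	P. davidiana	Populus	synthetic SRA placeholder
SRA_sim_013	P. davidiana	Populus	synthetic SRA placeholder
SRA_sim_014	P. davidiana	Populus	synthetic SRA placeholder
SRA_sim_015	P. rotundifolia	Populus	synthetic SRA placeholder
SRA_sim_016	P. rotundifolia	Populus	synthetic SRA placeholder
SRA_sim_017	P. rotundifolia	Populus	synthetic SRA placeholder
SRA_sim_018	P. rotundifolia	Populus	synthetic SRA placeholder
SRA_sim_019	P. tremuloides	Populus	synthetic SRA placeholder
SRA_sim_020	P. tremuloides	Populus	synthetic SRA placeholder
SRA_sim_021	P. tremuloides	Populus	synthetic SRA placeholder
SRA_sim_022	P. tremuloides	Populus	synthetic SRA placeholder
SRA_sim_023	P. tremuloides	Populus	synthetic SRA placeholder
SRA_sim_024	P. tremuloides	Populus	synthetic SRA placeholder
SRA_sim_025	P. grandidentata	Populus	synthetic SRA placeholder
SRA_sim_026	P. grandidentata	Populus	synthetic SRA placeholder
SRA_sim_027	P. grandidentata	Populus	synthetic SRA placeholder
SRA_sim_028	P. adenopoda	Populus	synthetic SRA placeholder
SRA_sim_029	P. adenopoda	Populus	synthetic SRA placeholder
SRA_sim_030	P. adenopoda	Populus	synthetic SRA placeholder
SRA_sim_031	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_032	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_033	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_034	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_035	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_036	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_037	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_038	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_039	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_040	P. trichocarpa	Tacamahaca	synthetic SRA placeholder
SRA_sim_041	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_042	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_043	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_044	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_045	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_046	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_047	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_048	P. balsamifera	Tacamahaca	synthetic SRA placeholder
SRA_sim_049	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_050	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_051	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_052	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_053	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_054	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_055	P. deltoides	Aigeiros	synthetic SRA placeholder
SRA_sim_056	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_057	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_058	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_059	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_060	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_061	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_062	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_063	P. nigra	Aigeiros	synthetic SRA placeholder
SRA_sim_064	P. simonii	Tacamahaca	synthetic SRA placeholder
SRA_sim_065	P. simonii	Tacamahaca	synthetic SRA placeholder
SRA_sim_066	P. simonii	Tacamahaca	synthetic SRA placeholder
SRA_sim_067	P. lasiocarpa	Leuce	synthetic SRA placeholder
SRA_sim_068	P. lasiocarpa	Leuce	synthetic SRA placeholder
SRA_sim_069	P. ussuriensis	Tacamahaca	synthetic SRA placeholder
SRA_sim_070	P. ussuriensis	Tacamahaca	synthetic SRA placeholder
SRA_sim_071	P. ussuriensis	Tacamahaca	synthetic SRA placeholder
SRA_sim_072	P. pseudomaximowiczii	Tacamahaca	synthetic SRA placeholder
SRA_sim_073	P. pseudomaximowiczii	Tacamahaca	synthetic SRA placeholder
SRA_sim_074	P. suaveolens	Tacamahaca	synthetic SRA placeholder
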