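sample_id	arm	grade	age_group	age_years	location	SETD2
GL001	tumor	IV	pediatric	NA	NA	mutated
GL002	tumor	IV	pediatric	NA	NA	mutated
GL003	tumor	IV	pediatric	NA	NA	mutated
GL004	tumor	IV	pediatric	NA	NA	mutated
GL005	tumor	IV	pediatric	NA	NA	mutated
GL006	tumor	IV	pediatric	NA	NA	mutated
GL007	tumor	IV	pediatric	NA	NA	mutated
GL008	tumor	IV	pediatric	NA	NA	mutated
GL009	tumor	IV	pediatric	NA	NA	mutated
GL010	tumor	IV	pediatric	NA	NA	wildtype
GL011	tumor	IV	pediatric	NA	NA	wildtype
GL012	tumor	IV	pediatric	NA	NA	wildtype
GL013	tumor	IV	pediatric	NA	NA	wildtype
GL014	tumor	IV	pediatric	NA	NA	wildtype
GL015	tumor	IV	pediatric	NA	NA	wildtype
GL016	tumor	IV	pediatric	NA	NA	wildtype
GL017	tumor	IV	pediatric	NA	NA	wildtype
GL018	tumor	IV	pediatric	NA	NA	wildtype
GL019	tumor	IV	pediatric	NA	NA	wildtype
GL020	tumor	IV	pediatric	NA	NA	wildtype
GL021	tumor	IV	pediatric	NA	NA	wildtype
GL022	tumor	IV	pediatric	NA	NA	wildtype
GL023	tumor	IV	pediatric	NA	NA	wildtype
GL024	tumor	IV	pediatric	NA	NA	wildtype
GL025	tumor	IV	pediatric	NA	NA	wildtype
GL026	tumor	IV	pediatric	NA	NA	wildtype
GL027	tumor	IV	pediatric	NA	NA	wildtype
GL028	tumor	IV	pediatric	NA	NA	wildtype
GL029	tumor	IV	pediatric	NA	NA	wildtype
GL030	tumor	IV	pediatric	NA	NA	wildtype
GL031	tumor	IV	pediatric	NA	NA	wildtype
GL032	tumor	IV	pediatric	NA	NA	wildtype
GL033	tumor	IV	pediatric	NA	NA	wildtype
GL034	tumor	IV	pediatric	NA	NA	wildtype
GL035	tumor	IV	pediatric	NA	NA	wildtype
GL036	tumor	IV	pediatric	NA	NA	wildtype
GL037	tumor	IV	pediatric	NA	NA	wildtype
GL038	tumor	IV	pediatric	NA	NA	wildtype
GL039	tumor	IV	pediatric	NA	NA	wildtype
GL040	tumor	IV	pediatric	NA	NA	wildtype
GL041	tumor	IV	pediatric	NA	NA	wildtype
GL042	tumor	IV	pediatric	NA	NA	wildtype
GL043	tumor	IV	pediatric	NA	NA	wildtype
GL044	tumor	IV	pediatric	NA	NA	wildtype
GL045	tumor	IV	pediatric	NA	NA	wildtype
GL046	tumor	IV	pediatric	NA	NA	wildtype
GL047	tumor	IV	pediatric	NA	NA	wildtype
GL048	tumor	IV	pediatric	NA	NA	wildtype
GL049	tumor	IV	pediatric	NA	NA	wildtype
GL050	tumor	IV	pediatric	NA	NA	wildtype
GL051	tumor	IV	pediatric	NA	NA	wildtype
GL052	tumor	IV	pediatric	NA	NA	wildtype
GL053	tumor	IV	pediatric	NA	NA	wildtype
GL054	tumor	IV	pediatric	NA	NA	wildtype
GL055	tumor	IV	pediatric	NA	NA	wildtype
GL056	tumor	IV	pediatric	NA	NA	wildtype
GL057	tumor	IV	pediatric	NA	NA	wildtype
GL058	tumor	IV	pediatric	NA	NA	wildtype
GL059	tumor	IV	pediatric	NA	NA	wildtype
GL060	tumor	IV	pediatric	NA	NA	wildtype
GL061	tumor	IV	adult	NA	NA	mutated
GL062	tumor	IV	adult	NA	NA	mutated
GL063	tumor	IV	adult	NA	NA	mutated
GL064	tumor	IV	adult	NA	NA	wildtype
GL065	tumor	IV	adult	NA	NA	wildtype
GL066	tumor	IV	adult	NA	NA	wildtype
GL067	tumor	IV	adult	NA	NA	wildtype
GL068	tumor	IV	adult	NA	NA	wildtype
GL069	tumor	IV	adult	NA	NA	wildtype
GL070	tumor	IV	adult	NA	NA	wildtype
GL071	tumor	IV	adult	NA	NA	wildtype
GL072	tumor	IV	adult	NA	NA	wildtype
GL073	tumor	IV	adult	NA	NA	wildtype
GL074	tumor	IV	adult	NA	NA	wildtype
GL075	tumor	IV	adult	NA	NA	wildtype
GL076	tumor	IV	adult	NA	NA	wildtype
GL077	tumor	IV	adult	NA	NA	wildtype
GL078	tumor	IV	adult	NA	NA	wildtype
GL079	tumor	IV	adult	NA	NA	wildtype
GL080	tumor	IV	adult	NA	NA	wildtype
GL081	tumor	IV	adult	NA	NA	wildtype
GL082	tumor	IV	adult	NA	NA	wildtype
GL083	tumor	IV	adult	NA	NA	wildtype
GL084	tumor	IV	adult	NA	NA	wildtype
GL085	tumor	IV	adult	NA	NA	wildtype
GL086	tumor	IV	adult	NA	NA	wildtype
GL087	tumor	IV	adult	NA	NA	wildtype
GL088	tumor	IV	adult	NA	NA	wildtype
GL089	tumor	IV	adult	NA	NA	wildtype
GL090	tumor	IV	adult	NA	NA	wildtype
GL091	tumor	IV	adult	NA	NA	wildtype
GL092	tumor	IV	adult	NA	NA	wildtype
GL093	tumor	IV	adult	NA	NA	wildtype
GL094	tumor	IV	adult	NA	NA	wildtype
GL095	tumor	IV	adult	NA	NA	wildtype
GL096	tumor	IV	adult	NA	NA	wildtype
GL097	tumor	IV	adult	NA	NA	wildtype
GL098	tumor	III	pediatric	NA	NA	mutated
GL099	tumor	III	pediatric	NA	NA	mutated
GL100	tumor	III	pediatric	NA	NA	wildtype
GL101	tumor	III	pediatric	NA	NA	wildtype
GL102	tumor	III	pediatric	NA	NA	wildtype
GL103	tumor	III	pediatric	NA	NA	wildtype
GL104	tumor	III	pediatric	NA	NA	wildtype
GL105	tumor	III	pediatric	NA	NA	wildtype
GL106	tumor	III	pediatric	NA	NA	wildtype
GL107	tumor	III	pediatric	NA	NA	wildtype
GL108	tumor	III	pediatric	NA	NA	wildtype
GL109	tumor	III	pediatric	NA	NA	wildtype
GL110	tumor	III	pediatric	NA	NA	wildtype
GL111	tumor	III	adult	NA	NA	mutated
GL112	tumor	III	adult	NA	NA	mutated
GL113	tumor	III	adult	NA	NA	wildtype
GL114	tumor	III	adult	NA	NA	wildtype
GL115	tumor	III	adult	NA	NA	wildtype
GL116	tumor	III	adult	NA	NA	wildtype
GL117	tumor	III	adult	NA	NA	wildtype
GL118	tumor	III	adult	NA	NA	wildtype
GL119	tumor	III	adult	NA	NA	wildtype
GL120	tumor	III	adult	NA	NA	wildtype
GL121	tumor	III	adult	NA	NA	wildtype
GL122	tumor	III	adult	NA	NA	wildtype
GL123	tumor	III	adult	NA	NA	wildtype
GL124	tumor	III	adult	NA	NA	wildtype
GL125	tumor	III	adult	NA	NA	wildtype
GL126	tumor	III	adult	NA	NA	wildtype
GL127	tumor	III	adult	NA	NA	wildtype
GL128	tumor	III	adult	NA	NA	wildtype
GL129	tumor	III	adult	NA	NA	wildtype
GL130	tumor	III	adult	NA	NA	wildtype
GL131	tumor	III	adult	NA	NA	wildtype
GL132	tumor	III	adult	NA	NA	wildtype
GL133	tumor	III	adult	NA	NA	wildtype
GL134	tumor	III	adult	NA	NA	wildtype
GL135	tumor	III	adult	NA	NA	wildtype
GL136	tumor	III	adult	NA	NA	wildtype
GL137	tumor	III	adult	NA	NA	wildtype
GL138	tumor	III	adult	NA	NA	wildtype
GL139	tumor	II	pediatric	NA	NA	wildtype
GL140	tumor	II	pediatric	NA	NA	wildtype
GL141	tumor	II	pediatric	NA	NA	wildtype
GL142	tumor	II	pediatric	NA	NA	wildtype
GL143	tumor	II	pediatric	NA	NA	wildtype
GL144	tumor	II	pediatric	NA	NA	wildtype
GL145	tumor	II	pediatric	NA	NA	wildtype
GL146	tumor	II	pediatric	NA	NA	wildtype
GL147	tumor	II	pediatric	NA	NA	wildtype
GL148	tumor	II	pediatric	NA	NA	wildtype
GL149	tumor	II	pediatric	NA	NA	wildtype
GL150	tumor	II	pediatric	NA	NA	wildtype
GL151	tumor	II	pediatric	NA	NA	wildtype
GL152	tumor	II	pediatric	NA	NA	wildtype
GL153	tumor	II	pediatric	NA	NA	wildtype
GL154	tumor	II	pediatric	NA	NA	wildtype
GL155	tumor	II	pediatric	NA	NA	wildtype
GL156	tumor	II	pediatric	NA	NA	wildtype
GL157	tumor	II	pediatric	NA	NA	wildtype
GL158	tumor	II	pediatric	NA	NA	wildtype
GL159	tumor	II	pediatric	NA	NA	wildtype
GL160	tumor	II	pediatric	NA	NA	wildtype
GL161	tumor	II	pediatric	NA	NA	wildtype
GL162	tumor	II	adult	NA	NA	wildtype
GL163	tumor	II	adult	NA	NA	wildtype
GL164	tumor	II	adult	NA	NA	wildtype
GL165	tumor	II	adult	NA	NA	wildtype
GL166	tumor	II	adult	NA	NA	wildtype
GL167	tumor	II	adult	NA	NA	wildtype
GL168	tumor	II	adult	NA	NA	wildtype
GL169	tumor	II	adult	NA	NA	wildtype
GL170	tumor	II	adult	NA	NA	wildtype
GL171	tumor	II	adult	NA	NA	wildtype
GL172	tumor	II	adult	NA	NA	wildtype
GL173	tumor	II	adult	NA	NA	wildtype
GL174	tumor	II	adult	NA	NA	wildtype
GL175	tumor	II	adult	NA	NA	wildtype
GL176	tumor	II	adult	NA	NA	wildtype
GL177	tumor	II	adult	NA	NA	wildtype
GL178	tumor	II	adult	NA	NA	wildtype
GL179	tumor	II	adult	NA	NA	wildtype
GL180	tumor	II	adult	NA	NA	wildtype
GL181	tumor	II	adult	NA	NA	wildtype
GL182	tumor	II	adult	NA	NA	wildtype
GL183	tumor	II	adult	NA	NA	wildtype
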