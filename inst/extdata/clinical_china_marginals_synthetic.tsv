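sample_id	er	her2	grade	nodal	lvi
CN001	positive	over-expressed	I	positive	positive
CN002	positive	over-expressed	I	positive	positive
CN003	positive	over-expressed	I	positive	positive
CN004	positive	over-expressed	I	positive	positive
CN005	positive	over-expressed	I	positive	positive
CN006	positive	over-expressed	I	positive	positive
CN007	positive	over-expressed	I	positive	positive
CN008	positive	over-expressed	I	positive	positive
CN009	positive	over-expressed	I	positive	positive
CN010	positive	over-expressed	I	positive	positive
CN011	positive	over-expressed	I	positive	positive
CN012	positive	over-expressed	I	positive	positive
CN013	positive	over-expressed	I	positive	positive
CN014	positive	over-expressed	I	positive	positive
CN015	positive	over-expressed	I	positive	positive
CN016	positive	over-expressed	I	positive	positive
CN017	positive	over-expressed	I	positive	positive
CN018	positive	over-expressed	I	positive	positive
CN019	positive	over-expressed	I	positive	positive
CN020	positive	over-expressed	I	positive	positive
CN021	positive	over-expressed	I	positive	positive
CN022	positive	over-expressed	I	positive	positive
CN023	positive	over-expressed	I	positive	positive
CN024	positive	over-expressed	I	positive	positive
CN025	positive	over-expressed	I	positive	positive
CN026	positive	over-expressed	I	positive	positive
CN027	positive	over-expressed	I	positive	positive
CN028	positive	over-expressed	II	positive	positive
CN029	positive	over-expressed	II	positive	positive
CN030	positive	over-expressed	II	positive	positive
CN031	positive	not	II	positive	positive
CN032	positive	not	II	positive	positive
CN033	positive	not	II	positive	positive
CN034	positive	not	II	positive	positive
CN035	positive	not	II	positive	positive
CN036	positive	not	II	positive	positive
CN037	positive	not	II	positive	positive
CN038	positive	not	II	positive	positive
CN039	positive	not	II	positive	positive
CN040	positive	not	II	positive	positive
CN041	positive	not	II	positive	positive
CN042	positive	not	II	positive	positive
CN043	positive	not	II	positive	positive
CN044	positive	not	II	positive	positive
CN045	positive	not	II	positive	positive
CN046	positive	not	II	positive	positive
CN047	positive	not	II	positive	negative
CN048	positive	not	II	positive	negative
CN049	positive	not	II	positive	negative
CN050	positive	not	II	positive	negative
CN051	positive	not	II	positive	negative
CN052	positive	not	II	positive	negative
CN053	positive	not	II	positive	negative
CN054	positive	not	II	positive	negative
CN055	positive	not	II	positive	negative
CN056	positive	not	II	positive	negative
CN057	positive	not	II	positive	negative
CN058	positive	not	II	positive	negative
CN059	positive	not	III	positive	negative
CN060	positive	not	III	positive	negative
CN061	positive	not	III	positive	negative
CN062	positive	not	III	negative	negative
CN063	positive	not	III	negative	negative
CN064	positive	not	III	negative	negative
CN065	positive	not	III	negative	negative
CN066	positive	not	III	negative	negative
CN067	positive	not	III	negative	negative
CN068	positive	not	III	negative	negative
CN069	positive	not	III	negative	negative
CN070	positive	not	III	negative	negative
CN071	positive	not	III	negative	negative
CN072	positive	not	III	negative	negative
CN073	positive	not	III	negative	negative
CN074	positive	not	III	negative	negative
CN075	negative	not	III	negative	negative
CN076	negative	not	III	negative	negative
CN077	negative	not	III	negative	negative
CN078	negative	not	III	negative	negative
CN079	negative	not	III	negative	negative
CN080	negative	not	III	negative	negative
CN081	negative	not	III	negative	negative
CN082	negative	not	III	negative	negative
CN083	negative	not	III	negative	negative
CN084	negative	not	III	negative	negative
CN085	negative	not	III	negative	negative
CN086	negative	not	III	negative	negative
CN087	negative	not	III	negative	negative
CN088	negative	not	III	negative	negative
CN089	negative	not	III	negative	negative
CN090	negative	not	III	negative	negative
CN091	negative	not	III	negative	negative
CN092	negative	not	III	negative	negative
CN093	negative	not	III	negative	negative
CN094	negative	not	III	negative	negative
CN095	negative	not	III	negative	negative
CN096	negative	not	III	negative	negative
CN097	negative	not	III	negative	negative
CN098	negative	not	III	negative	negative
CN099	negative	not	III	negative	negative
CN100	negative	not	III	negative	negative
CN101	negative	not	III	negative	negative
CN102	negative	not	III	negative	negative
CN103	negative	not	III	negative	negative
CN104	negative	not	III	negative	negative
CN105	negative	not	III	negative	negative
CN106	negative	not	III	negative	negative
CN107	negative	not	III	negative	negative
CN108	negative	not	III	negative	negative
CN109	negative	not	III	negative	negative
CN110	negative	not	III	negative	negative
CN111	negative	not	III	negative	negative
CN112	negative	not	III	negative	negative
CN113	negative	not	III	negative	negative
CN114	negative	not	III	negative	negative
CN115	negative	not	III	negative	negative
CN116	negative	not	III	negative	negative
CN117	negative	not	III	negative	negative
CN118	negative	not	III	negative	negative
CN119	negative	not	III	negative	negative
CN120	negative	not	III	negative	negative
CN121	negative	not	III	negative	negative
CN122	negative	not	III	negative	negative
CN123	negative	not	III	negative	negative
CN124	negative	not	III	negative	negative
CN125	negative	not	III	negative	negative
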