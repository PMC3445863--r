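sample_id	er	her2	grade	nodal	lvi
TW001	positive	over-expressed	I	positive	positive
TW002	positive	over-expressed	I	positive	positive
TW003	positive	over-expressed	I	positive	positive
TW004	positive	over-expressed	II	positive	positive
TW005	positive	over-expressed	II	positive	positive
TW006	positive	over-expressed	II	positive	positive
TW007	positive	over-expressed	II	positive	positive
TW008	positive	over-expressed	II	positive	positive
TW009	positive	over-expressed	II	positive	positive
TW010	positive	over-expressed	II	positive	positive
TW011	positive	over-expressed	II	positive	positive
TW012	positive	over-expressed	II	positive	positive
TW013	positive	over-expressed	II	positive	positive
TW014	positive	over-expressed	II	positive	positive
TW015	positive	over-expressed	II	positive	positive
TW016	positive	over-expressed	II	positive	positive
TW017	positive	over-expressed	II	positive	positive
TW018	positive	over-expressed	II	positive	positive
TW019	positive	over-expressed	II	positive	positive
TW020	positive	over-expressed	II	positive	positive
TW021	positive	over-expressed	II	positive	positive
TW022	positive	not	III	positive	positive
TW023	negative	not	III	positive	positive
TW024	negative	not	III	negative	positive
TW025	negative	not	III	negative	positive
TW026	negative	not	III	negative	positive
TW027	negative	not	III	negative	positive
TW028	negative	not	III	negative	negative
TW029	negative	not	III	negative	negative
TW030	negative	not	III	negative	negative
TW031	negative	not	III	negative	negative
TW032	negative	not	III	negative	negative
TW033	negative	not	III	negative	negative
TW034	negative	not	III	negative	negative
TW035	negative	not	III	negative	negative
TW036	negative	not	III	negative	negative
TW037	negative	not	III	negative	negative
TW038	negative	not	III	negative	negative
TW039	negative	not	III	negative	negative
TW040	negative	not	III	negative	negative
TW041	negative	not	III	negative	negative
TW042	negative	not	III	negative	negative
TW043	negative	not	III	negative	negative
TW044	negative	not	III	negative	NA
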