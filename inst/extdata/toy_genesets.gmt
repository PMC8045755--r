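CELL_CYCLE	toy cell-cycle set	GENE001	GENE002	GENE003	GENE004	GENE005	GENE006	GENE007	GENE008	GENE009	GENE010	GENE011	GENE012	GENE013	GENE014	GENE015
MUSCLE_CONTRACTION	toy muscle set	GENE016	GENE017	GENE018	GENE019	GENE020	GENE021	GENE022	GENE023	GENE024	GENE025	GENE026	GENE027	GENE028
DNA_REPAIR	toy repair set	GENE029	GENE030	GENE031	GENE032	GENE033	GENE034	GENE035	GENE036	GENE037	GENE038	GENE039	GENE040
ADHESION	toy adhesion set	GENE003	GENE041	GENE042	GENE043	GENE044	GENE045	GENE046	GENE047	GENE048	GENE049	GENE050	GENE051	GENE052
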