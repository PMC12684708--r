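sample	block	founder
S001	planted_1	3
S002	planted_1	3
S003	planted_1	1
S004	planted_1	2
S005	planted_1	3
S006	planted_1	1
S007	planted_1	1
S008	planted_1	2
S009	planted_1	2
S010	planted_1	1
S011	planted_1	1
S012	planted_1	3
S013	planted_1	1
S014	planted_1	3
S015	planted_1	3
S016	planted_1	1
S017	planted_1	1
S018	planted_1	1
S019	planted_1	1
S020	planted_1	2
S021	planted_1	3
S022	planted_1	1
S023	planted_1	2
S024	planted_1	1
S025	planted_1	3
S026	planted_1	3
S027	planted_1	3
S028	planted_1	1
S029	planted_1	2
S030	planted_1	1
S031	planted_1	3
S032	planted_1	2
S033	planted_1	3
S034	planted_1	3
S035	planted_1	3
S036	planted_1	3
S037	planted_1	1
S038	planted_1	2
S039	planted_1	1
S040	planted_1	2
S041	planted_1	2
S042	planted_1	3
S043	planted_1	2
S044	planted_1	1
S045	planted_1	1
S046	planted_1	1
S047	planted_1	1
S048	planted_1	1
S049	planted_1	2
S050	planted_1	1
S051	planted_1	1
S052	planted_1	3
S053	planted_1	2
S054	planted_1	2
S055	planted_1	1
S056	planted_1	3
S057	planted_1	3
S058	planted_1	1
S059	planted_1	3
S060	planted_1	2
S061	planted_1	2
S062	planted_1	1
S063	planted_1	1
S064	planted_1	1
S065	planted_1	1
S066	planted_1	1
S067	planted_1	2
S068	planted_1	1
S069	planted_1	1
S070	planted_1	3
S071	planted_1	2
S072	planted_1	1
S073	planted_1	1
S074	planted_1	2
S075	planted_1	2
S076	planted_1	1
S077	planted_1	2
S078	planted_1	1
S079	planted_1	3
S080	planted_1	1
S081	planted_1	1
S082	planted_1	1
S083	planted_1	2
S084	planted_1	1
S085	planted_1	2
S086	planted_1	1
S087	planted_1	1
S088	planted_1	3
S089	planted_1	3
S090	planted_1	2
S091	planted_1	1
S092	planted_1	1
S093	planted_1	1
S094	planted_1	1
S095	planted_1	1
S096	planted_1	2
S097	planted_1	3
S098	planted_1	1
S099	planted_1	1
S100	planted_1	1
S001	planted_2	2
S002	planted_2	3
S003	planted_2	1
S004	planted_2	2
S005	planted_2	3
S006	planted_2	3
S007	planted_2	1
S008	planted_2	1
S009	planted_2	1
S010	planted_2	1
S011	planted_2	3
S012	planted_2	1
S013	planted_2	3
S014	planted_2	1
S015	planted_2	3
S016	planted_2	1
S017	planted_2	1
S018	planted_2	2
S019	planted_2	2
S020	planted_2	2
S021	planted_2	1
S022	planted_2	1
S023	planted_2	2
S024	planted_2	1
S025	planted_2	3
S026	planted_2	2
S027	planted_2	2
S028	planted_2	1
S029	planted_2	1
S030	planted_2	1
S031	planted_2	1
S032	planted_2	3
S033	planted_2	1
S034	planted_2	2
S035	planted_2	2
S036	planted_2	2
S037	planted_2	3
S038	planted_2	3
S039	planted_2	1
S040	planted_2	1
S041	planted_2	3
S042	planted_2	3
S043	planted_2	1
S044	planted_2	1
S045	planted_2	1
S046	planted_2	1
S047	planted_2	2
S048	planted_2	3
S049	planted_2	1
S050	planted_2	1
S051	planted_2	2
S052	planted_2	1
S053	planted_2	2
S054	planted_2	3
S055	planted_2	1
S056	planted_2	1
S057	planted_2	1
S058	planted_2	3
S059	planted_2	1
S060	planted_2	1
S061	planted_2	2
S062	planted_2	1
S063	planted_2	2
S064	planted_2	1
S065	planted_2	1
S066	planted_2	1
S067	planted_2	3
S068	planted_2	1
S069	planted_2	2
S070	planted_2	2
S071	planted_2	1
S072	planted_2	1
S073	planted_2	1
S074	planted_2	3
S075	planted_2	3
S076	planted_2	1
S077	planted_2	2
S078	planted_2	1
S079	planted_2	2
S080	planted_2	1
S081	planted_2	3
S082	planted_2	2
S083	planted_2	1
S084	planted_2	2
S085	planted_2	1
S086	planted_2	2
S087	planted_2	1
S088	planted_2	2
S089	planted_2	1
S090	planted_2	1
S091	planted_2	1
S092	planted_2	3
S093	planted_2	3
S094	planted_2	1
S095	planted_2	1
S096	planted_2	1
S097	planted_2	2
S098	planted_2	1
S099	planted_2	1
S100	planted_2	2
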