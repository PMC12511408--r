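module_id	description	ko_ids
MF_lactose_deg	lactose degradation (synthetic example module)	K01190,K12111,K01220
MF_propionate_prod	propionate production (synthetic example module)	K01026,K00932,K01908,K13923
MF_butyrate_prod	butyrate production (synthetic example module)	K00929,K01034,K01035,K00634
MF_mucin_deg	mucin degradation (synthetic example module)	K01186,K01206,K12373
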