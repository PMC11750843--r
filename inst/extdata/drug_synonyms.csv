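ingredient,synonym
infliximab,REMICADE
infliximab,INFLECTRA
infliximab,RENFLEXIS
infliximab,AVSOLA
infliximab,IXIFI
infliximab,INFLIXIMAB-DYYB
infliximab,INFLIXIMAB-ABDA
azathioprine,IMURAN
azathioprine,AZASAN
azathioprine,IMUREL
azathioprine,AZAMUN
azathioprine,AZATHIOPRINE SODIUM
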