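reaction_id	added_by	starred
ASNSYNA-RXN	A	false
RXN-1381	A	false
DUDPKIN-RXN	A	true
CDPKIN-RXN	A	true
DTDPKIN-RXN	A,M	false
UDPKIN-RXN	A,M	false
GPPSYN-RXN	A,M	false
FPPSYN-RXN	A,M	false
RXN-8999	A,M	false
IGPSYN-RXN	A,M	false
HISTIDPHOS-RXN	A,M	false
PREPHENATE-TRANSAMINE-RXN	A,M	false
RXN-12460	M	false
GDPKIN-RXN	M	false
GLUCOKIN-RXN	M	false
RXN-17018	M	false
RXN-17897	M	false
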