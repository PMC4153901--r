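# mitoRearr gene-name normalization table, version 1
# alias (matched case-insensitively after stripping spaces/underscores)
# -> MitoZoa-style token and feature kind.
alias	token	kind
COX1	cox1	CDS
COXI	cox1	CDS
COI	cox1	CDS
CO1	cox1	CDS
MT-CO1	cox1	CDS
CYTOCHROMECOXIDASESUBUNITI	cox1	CDS
CYTOCHROMECOXIDASESUBUNIT1	cox1	CDS
COX2	cox2	CDS
COXII	cox2	CDS
COII	cox2	CDS
CO2	cox2	CDS
MT-CO2	cox2	CDS
CYTOCHROMECOXIDASESUBUNITII	cox2	CDS
CYTOCHROMECOXIDASESUBUNIT2	cox2	CDS
COX3	cox3	CDS
COXIII	cox3	CDS
COIII	cox3	CDS
CO3	cox3	CDS
MT-CO3	cox3	CDS
CYTOCHROMECOXIDASESUBUNITIII	cox3	CDS
CYTOCHROMECOXIDASESUBUNIT3	cox3	CDS
COB	cob	CDS
CYTB	cob	CDS
CYB	cob	CDS
MT-CYB	cob	CDS
CYTOCHROMEB	cob	CDS
ND1	nad1	CDS
NAD1	nad1	CDS
MT-ND1	nad1	CDS
NADHDEHYDROGENASESUBUNIT1	nad1	CDS
ND2	nad2	CDS
NAD2	nad2	CDS
MT-ND2	nad2	CDS
NADHDEHYDROGENASESUBUNIT2	nad2	CDS
ND3	nad3	CDS
NAD3	nad3	CDS
MT-ND3	nad3	CDS
NADHDEHYDROGENASESUBUNIT3	nad3	CDS
ND4	nad4	CDS
NAD4	nad4	CDS
MT-ND4	nad4	CDS
NADHDEHYDROGENASESUBUNIT4	nad4	CDS
ND4L	nad4L	CDS
NAD4L	nad4L	CDS
MT-ND4L	nad4L	CDS
NADHDEHYDROGENASESUBUNIT4L	nad4L	CDS
ND5	nad5	CDS
NAD5	nad5	CDS
MT-ND5	nad5	CDS
NADHDEHYDROGENASESUBUNIT5	nad5	CDS
ND6	nad6	CDS
NAD6	nad6	CDS
MT-ND6	nad6	CDS
NADHDEHYDROGENASESUBUNIT6	nad6	CDS
ATP6	atp6	CDS
ATPASE6	atp6	CDS
MT-ATP6	atp6	CDS
ATPSYNTHASEF0SUBUNIT6	atp6	CDS
ATP8	atp8	CDS
ATPASE8	atp8	CDS
MT-ATP8	atp8	CDS
ATPSYNTHASEF0SUBUNIT8	atp8	CDS
RRNS	rrnS	rRNA
12S	rrnS	rRNA
12SRRNA	rrnS	rRNA
12SRIBOSOMALRNA	rrnS	rRNA
S-RRNA	rrnS	rRNA
SMALLSUBUNITRIBOSOMALRNA	rrnS	rRNA
RRNL	rrnL	rRNA
16S	rrnL	rRNA
16SRRNA	rrnL	rRNA
16SRIBOSOMALRNA	rrnL	rRNA
L-RRNA	rrnL	rRNA
LARGESUBUNITRIBOSOMALRNA	rrnL	rRNA
CR	CR	CR
D-LOOP	CR	CR
DLOOP	CR	CR
CONTROLREGION	CR	CR
OL	OL	OL
O_L	OL	OL
L-STRANDORIGIN	OL	OL
ORIGINOFLIGHTSTRANDREPLICATION	OL	OL
ORIGINOFL-STRANDREPLICATION	OL	OL
SPACER	spacer	noncoding
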