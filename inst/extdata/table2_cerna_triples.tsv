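mrna	mirna	lncrna
ADAMTS14	hsa-miR-4667-5p	LINC00662
ARGFX	hsa-miR-378f	DIRC3
ARGFX	hsa-miR-378f	LINC00662
ARGFX	hsa-miR-378f	LINC01133
ARGFX	hsa-miR-378f	RMST
BCAS1	hsa-miR-3650	LINC00662
BCAS1	hsa-miR-3650	LINC01119
CARNS1	hsa-miR-3650	LINC00662
CARNS1	hsa-miR-3650	LINC01119
CCBE1	hsa-miR-5009-3p	LINC00662
CCBE1	hsa-miR-5009-3p	SNHG3
CDCA3	hsa-miR-4668-5p	LINC00326
CDCA3	hsa-miR-4668-5p	LINC00662
CDCA3	hsa-miR-4668-5p	LINC00920
CDCA3	hsa-miR-4668-5p	LINC01119
CYP2W1	hsa-miR-6856-5p	LINC00662
CYP2W1	hsa-miR-6856-5p	LINC01133
FAM103A1	hsa-miR-4700-3p	LINC00326
FAM103A1	hsa-miR-4700-3p	LINC00662
FAM103A1	hsa-miR-4700-3p	LINC01119
FAM103A1	hsa-miR-4799-5p	LINC00460
FAM103A1	hsa-miR-4799-5p	LINC00944
FAM103A1	hsa-miR-4799-5p	PWAR6
FAM103A1	hsa-miR-4799-5p	ZNF582-AS1
FAM120AOS	hsa-miR-4775	DIRC3
FAM120AOS	hsa-miR-4775	GAS5
FAM120AOS	hsa-miR-4775	LINC00662
FAM120AOS	hsa-miR-4775	LINC00920
FAM120AOS	hsa-miR-4775	LINC01419
FAM120AOS	hsa-miR-4775	PWAR6
FAM120AOS	hsa-miR-4775	RMST
GJB1	hsa-miR-4436b-3p	GAS5
HOXB3	hsa-miR-4495	LINC00662
HOXB3	hsa-miR-4653-5p	LINC00460
HOXB3	hsa-miR-4653-5p	LINC01029
HOXB3	hsa-miR-504-5p	GAS5
LRAT	hsa-miR-3680-5p	RMST
MAG	hsa-miR-6856-5p	LINC00662
MAG	hsa-miR-6856-5p	LINC01133
MCOLN3	hsa-miR-4668-5p	LINC00326
MCOLN3	hsa-miR-4668-5p	LINC00662
MCOLN3	hsa-miR-4668-5p	LINC00920
MCOLN3	hsa-miR-4668-5p	LINC01119
MOG	hsa-miR-6736-3p	LINC01119
MOG	hsa-miR-6736-3p	RMST
MORC1	hsa-miR-3973	PWAR6
MORC1	hsa-miR-3973	ZNF582-AS1
MYRF	hsa-miR-378f	DIRC3
MYRF	hsa-miR-378f	LINC00662
MYRF	hsa-miR-378f	LINC01133
MYRF	hsa-miR-378f	RMST
PLP1	hsa-miR-6844	DIRC3
PLP1	hsa-miR-6844	LINC00460
PLP1	hsa-miR-6844	LINC00662
PLP1	hsa-miR-6844	LINC00920
PLP1	hsa-miR-6844	LINC01133
PLP1	hsa-miR-6844	PWAR6
PLP1	hsa-miR-6844	RMST
PLP1	hsa-miR-6844	ZNF582-AS1
PRLR	hsa-miR-548a-3p	LINC00326
PRLR	hsa-miR-548a-3p	LINC00662
PRLR	hsa-miR-548a-3p	LINC00944
PRLR	hsa-miR-548a-3p	PWAR6
PRLR	hsa-miR-548a-3p	SNHG3
RASGRP3	hsa-miR-6783-5p	LINC00662
RASGRP3	hsa-miR-6783-5p	LINC01419
SH3TC2	hsa-miR-4495	LINC00662
SH3TC2	hsa-miR-4653-5p	LINC00460
SH3TC2	hsa-miR-4653-5p	LINC01029
SH3TC2	hsa-miR-4780	LINC00662
SLC26A9	hsa-miR-4764-3p	LINC00662
SLC26A9	hsa-miR-4764-3p	RMST
SLC26A9	hsa-miR-6856-5p	LINC00662
SLC26A9	hsa-miR-6856-5p	LINC01133
SYNPO2L	hsa-miR-4678	RMST
SYNPO2L	hsa-miR-5589-5p	LINC00460
SYNPO2L	hsa-miR-5589-5p	LINC00662
SYNPO2L	hsa-miR-5589-5p	LINC00944
SYNPO2L	hsa-miR-5589-5p	LINC01029
SYNPO2L	hsa-miR-5589-5p	LINC01119
SYNPO2L	hsa-miR-5589-5p	RMST
SYNPO2L	hsa-miR-6736-3p	LINC01119
SYNPO2L	hsa-miR-6736-3p	RMST
TNFSF14	hsa-miR-3650	LINC00662
TNFSF14	hsa-miR-3650	LINC01119
TNFSF14	hsa-miR-4775	DIRC3
TNFSF14	hsa-miR-4775	GAS5
TNFSF14	hsa-miR-4775	LINC00662
TNFSF14	hsa-miR-4775	LINC00920
TNFSF14	hsa-miR-4775	LINC01419
TNFSF14	hsa-miR-4775	PWAR6
TNFSF14	hsa-miR-4775	RMST
TRAPPC3L	hsa-miR-4483	LINC00662
TUBAL3	hsa-miR-6783-5p	LINC00662
TUBAL3	hsa-miR-6783-5p	LINC01419
VSIG2	hsa-miR-569	GAS5
VSIG2	hsa-miR-569	LINC01133
VSIG2	hsa-miR-569	PWAR6
VSIG2	hsa-miR-569	RMST
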