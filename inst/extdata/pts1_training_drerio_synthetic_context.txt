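# Curated Danio rerio PTS1 training set: one C-terminal 12-mer per line.
# The C-terminal tripeptides are the literature-curated zebrafish peroxisomal
# matrix-protein PTS1 motifs (acyl-CoA oxidases, hydroxyacid/amino-acid
# oxidases, urate-degradation enzymes, catalase, thioesterases, ...).
# The nine upstream context residues are SYNTHETIC: the full C-termini of
# these entries are not reproduced here, so the contexts were constructed
# once (composition-weighted, with a guaranteed minimum residue diversity
# per position) and frozen. Trailing comments give the protein each
# tripeptide was curated from. Curated tripeptides that fall outside the
# broad screening consensus [ASCNPHTG]-[RKHQNSL]-[LMIVF] (e.g. the Acot20
# SML, like QKL/FRL) are not included: the scorer only ever sees
# consensus-matching C-termini.
TGLLSVAAGSKL  # Acox1 (SKL)
LLHFEPGLTSKL  # Paox (SKL)
SRLPDLQWISKL  # Pnpla8 (SKL)
NGCIVDVGHSKL  # Acoxl isoform (SKL)
YDGARWAGMAKL  # Acox3 (AKL)
ESTDMAGLSAKL  # Acot14 (AKL)
RNTGHRLKKAKL  # Acot16 (AKL)
DKDIPGRAVARL  # Ddo (ARL)
GRVDPTTRDARL  # Amacr (ARL)
ITIADLKMPARL  # Gnpat (ARL)
SEAATAENTARL  # Mlsl (ARL)
HYKAQMDQESRL  # Hao2 (SRL)
QKTVKGLPLSRL  # Dao1 (SRL)
VWRAVAYMPSRL  # Dao2 (SRL)
YCYRGIIGKSRL  # Dao3 (SRL)
LDILMEPEASRL  # Far1 isoform (SRL)
IMWEEKLFNSRI  # Hao1 (SRI)
VYSANQKSDSSL  # Pipox (SSL)
MDSPTTGHVSNL  # Hacl1 (SNL)
DAQMVPMCVSNL  # Lactb2 (SNL)
DQSFTAHSAAKM  # Gstk1 (AKM)
EPATKLTVFARM  # Uox (ARM)
WPPLIARMSPKL  # Idh1 (PKL)
ALGKEVNCQSHL  # Ccs (SHL)
LVYHTSPERSKM  # Cat (SKM)
KIFLLIMVDTKL  # Urad (TKL)
QQNNIKRSRSKV  # Fndc5 (SKV)
GGMSKHSLQANM  # Acsl5 (ANM)
IETGKPIVVTRL  # Slc27a2a (TRL)
PPEGANETISRV  # Agxta (SRV)
LHRLLQCIEHKL  # G6pd (HKL)
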